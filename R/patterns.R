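#' Occupancy-pattern bitmask utilities
#'
#' An occupancy pattern is the exact subset of profiled factors bound at a
#' region, encoded as a bitmask over an ordered factor list: bit \code{i}
#' (value \code{2^(i-1)}) is set when factor \code{i} is bound. With K
#' factors there are \code{2^K - 1} nonempty patterns (31 for K = 5), of
#' which \code{2^K - 1 - K} involve two or more factors (26 for K = 5).
#'
#' @param k number of factors (2 to 16).
#' @return `pattern_masks` returns the integer masks of all nonempty
#'   patterns; `pattern_size` the number of set bits per mask.
#' @examples
#' length(pattern_masks(5))                       # 31
#' sum(pattern_size(pattern_masks(5)) >= 2)       # 26
#' @export
pattern_masks <- function(k) {
  stopifnot(k >= 2, k <= 16)
  seq_len(2L^as.integer(k) - 1L)
}

#' @rdname pattern_masks
#' @param mask integer bitmask(s).
#' @export
pattern_size <- function(mask) {
  vapply(as.integer(mask), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:15)) != 0L), integer(1))
}

#' Convert between factor subsets and bitmask labels
#'
#' Labels join bound factor names with "+" in factor order, e.g.
#' "GATA1+SCL" for a mask with bits 1 and 5 set over the default order.
#'
#' @param mask integer bitmask(s) over `factor_order`.
#' @param factor_order character vector of the K ordered factor labels.
#' @return character label(s).
#' @export
pattern_label <- function(mask, factor_order) {
  k <- length(factor_order)
  vapply(as.integer(mask), function(m) {
    if (m <= 0L || m >= 2L^k) stop("mask ", m, " out of range for ", k, " factors")
    paste(factor_order[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L], collapse = "+")
  }, character(1))
}

#' @rdname pattern_label
#' @param factors character vector (or "+"-joined string) of a subset of
#'   `factor_order`.
#' @export
pattern_mask <- function(factors, factor_order) {
  if (length(factors) == 1L && grepl("+", factors, fixed = TRUE))
    factors <- strsplit(factors, "+", fixed = TRUE)[[1]]
  idx <- match(factors, factor_order)
  if (anyNA(idx)) stop("unknown factor(s): ", paste(factors[is.na(idx)], collapse = ", "))
  as.integer(sum(bitwShiftL(1L, idx - 1L)))
}

has_bit <- function(mask, i) bitwAnd(as.integer(mask), bitwShiftL(1L, i - 1L)) != 0L
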