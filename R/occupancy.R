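#' Assign exact occupancy patterns to union regions
#'
#' Every union region (see [merge_union()]) receives the exact subset of
#' factors bound there, encoded as a bitmask over the ordered factor
#' list. Counting is region-level: a union region contributes once to its
#' pattern regardless of how many same-factor peaks it contains.
#'
#' @param peaksets list of [peak_set()] objects (2 to 16 factors,
#'   distinct labels).
#' @param min_overlap bp of peak/region overlap for a factor to count as
#'   bound (default 1).
#' @return object of class `OccupancyRegions`: list with `factor_order`
#'   (the K labels, in input order) and `regions` (GRanges with metadata
#'   `pattern` bitmask and `factors` CharacterList). Regions whose factor
#'   set is emptied by `min_overlap` filtering are dropped.
#' @export
assign_patterns <- function(peaksets, min_overlap = 1L) {
  factor_order <- vapply(peaksets, function(ps) ps$factor, character(1))
  if (anyDuplicated(factor_order)) stop("duplicate factor labels")
  k <- length(factor_order)
  stopifnot(k >= 2, k <= 16)
  regions <- merge_union(peaksets, min_overlap = min_overlap)
  masks <- vapply(as.list(S4Vectors::mcols(regions)$factors), function(f) {
    if (length(f) == 0) 0L else pattern_mask(f, factor_order)
  }, integer(1))
  if (any(masks == 0L)) {
    message("dropping ", sum(masks == 0L),
            " region(s) with no factor passing min_overlap")
    regions <- regions[masks != 0L]
    masks <- masks[masks != 0L]
  }
  S4Vectors::mcols(regions)$pattern <- masks
  structure(list(factor_order = factor_order, regions = regions),
            class = "OccupancyRegions")
}

#' @export
print.OccupancyRegions <- function(x, ...) {
  cat("OccupancyRegions: ", length(x$regions), " union regions over ",
      length(x$factor_order), " factors (",
      paste(x$factor_order, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Tabulate exact occupancy patterns
#'
#' Counts regions per exact pattern for all `2^K - 1` nonempty patterns;
#' patterns not realized are reported with count 0. The counts partition
#' the union regions.
#'
#' @param occ an [assign_patterns()] result.
#' @return data.frame of class `PatternTable` with columns `pattern`
#'   (bitmask), `label`, `n_factors`, `count`; attributes `factor_order`
#'   and `n_regions`.
#' @export
count_exact_patterns <- function(occ) {
  stopifnot(inherits(occ, "OccupancyRegions"))
  k <- length(occ$factor_order)
  masks <- pattern_masks(k)
  counts <- tabulate(S4Vectors::mcols(occ$regions)$pattern, nbins = 2L^k - 1L)
  tab <- data.frame(pattern = masks,
                    label = pattern_label(masks, occ$factor_order),
                    n_factors = pattern_size(masks),
                    count = counts,
                    stringsAsFactors = FALSE)
  attr(tab, "factor_order") <- occ$factor_order
  attr(tab, "n_regions") <- length(occ$regions)
  class(tab) <- c("PatternTable", "data.frame")
  tab
}

#' Count regions bound by at least a given factor subset
#'
#' An "at least" count sums the exact counts of every superset of the
#' query subset: regions bound by the subset possibly together with
#' additional factors. Published co-binding totals (e.g. "regions bound
#' simultaneously by both factors") are usually of this kind, whereas
#' pattern tables report exact patterns; both views are first-class here.
#'
#' @param table a [count_exact_patterns()] table.
#' @param subset factor label vector, "+"-joined string, or bitmask.
#' @return integer count.
#' @export
count_at_least <- function(table, subset) {
  factor_order <- attr(table, "factor_order")
  mask <- if (is.numeric(subset)) as.integer(subset) else pattern_mask(subset, factor_order)
  if (mask <= 0L || mask >= 2L^length(factor_order))
    stop("subset mask out of range")
  sum(table$count[bitwAnd(table$pattern, mask) == mask])
}

#' Per-factor marginal region counts
#'
#' @param table a [count_exact_patterns()] table.
#' @return named integer vector: per factor, the number of union regions
#'   whose pattern includes it.
#' @export
marginal_counts <- function(table) {
  factor_order <- attr(table, "factor_order")
  stats::setNames(vapply(seq_along(factor_order), function(i)
    count_at_least(table, bitwShiftL(1L, i - 1L)), numeric(1)), factor_order)
}

#' Serialize a pattern table
#'
#' @param table a [count_exact_patterns()] table.
#' @param path output path; `.json` writes JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_pattern_table <- function(table, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(factor_order = attr(table, "factor_order"),
                              n_regions = attr(table, "n_regions"),
                              patterns = table[, c("label", "n_factors", "count")]),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(table[, c("label", "n_factors", "count")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
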