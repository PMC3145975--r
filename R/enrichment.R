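#' Independence null model for combinatorial binding
#'
#' The null assumes a fixed universe of `universe_N` bindable regions and
#' independent binding by each factor with probability `p_i = n_i /
#' universe_N`, where `n_i` is the factor's marginal region count. Under
#' this model the chance that a region shows exactly pattern S is
#' `p_S = prod_{i in S} p_i * prod_{j not in S} (1 - p_j)`, so the exact
#' count for S is Binomial(N, p_S) with mean `N p_S` and variance
#' `N p_S (1 - p_S)`.
#'
#' @param marginals named numeric vector of per-factor region counts.
#' @param universe_N number of regions potentially available for binding
#'   (default 80,000, a published lower-end genome-wide estimate; always
#'   configurable).
#' @return object of class `NullModel` with `universe_N`, `marginals`
#'   and `p`.
#' @export
null_model <- function(marginals, universe_N = 80000) {
  stopifnot(length(marginals) >= 2, !is.null(names(marginals)),
            all(nzchar(names(marginals))))
  if (any(marginals <= 0)) stop("marginal counts must be positive")
  if (any(marginals > universe_N))
    stop("universe too small: some marginal exceeds universe_N")
  structure(list(universe_N = universe_N,
                 marginals = marginals,
                 p = marginals / universe_N),
            class = "NullModel")
}

#' Null model taken from a realized pattern table
#'
#' Marginals default to the region-level counts of the pattern table
#' itself (internally consistent with how observed counts are made);
#' `use_raw_peaks` substitutes raw per-factor peak counts instead.
#'
#' @param table a [count_exact_patterns()] table.
#' @param universe_N see [null_model()].
#' @param raw_peak_counts optional named vector of raw peak counts to use
#'   as marginals.
#' @return a [null_model()].
#' @export
null_model_from_table <- function(table, universe_N = 80000,
                                  raw_peak_counts = NULL) {
  m <- if (is.null(raw_peak_counts)) marginal_counts(table)
       else raw_peak_counts[attr(table, "factor_order")]
  null_model(m, universe_N)
}

#' Expected counts and variances for all occupancy patterns
#'
#' @param model a [null_model()].
#' @param min_factors report only patterns with at least this many bound
#'   factors (default 1, i.e. all nonempty patterns).
#' @return data.frame with pattern, label, n_factors, p (pattern
#'   probability), expected, variance.
#' @export
expected_pattern_counts <- function(model, min_factors = 1L) {
  stopifnot(inherits(model, "NullModel"))
  p <- model$p
  k <- length(p)
  masks <- pattern_masks(k)
  pS <- vapply(masks, function(m) {
    inS <- has_bit(m, seq_len(k))
    prod(p[inS]) * prod(1 - p[!inS])
  }, numeric(1))
  out <- data.frame(pattern = masks,
                    label = pattern_label(masks, names(model$marginals)),
                    n_factors = pattern_size(masks),
                    p = pS,
                    expected = model$universe_N * pS,
                    variance = model$universe_N * pS * (1 - pS),
                    stringsAsFactors = FALSE)
  out[out$n_factors >= min_factors, , drop = FALSE]
}

#' Z-scores of observed versus expected pattern counts
#'
#' `Z_S = (O_S - E_S) / sqrt(V_S)` under the independence null; the
#' variance is the per-region binomial variance (the model's
#' distributional form is a package choice, flagged in report headers,
#' since published pattern Z-scores rarely state theirs; the Monte-Carlo
#' oracle [monte_carlo_null()] makes the approximation auditable).
#'
#' @param observed a [count_exact_patterns()] table.
#' @param model a [null_model()] over the same factors.
#' @param min_factors restrict the report (default 2: the multi-factor
#'   patterns, 26 of them for K = 5).
#' @return data.frame of class `PatternStats`, sorted by decreasing
#'   |Z|: pattern, label, n_factors, observed, expected, variance,
#'   zscore.
#' @export
pattern_zscores <- function(observed, model, min_factors = 2L) {
  stopifnot(inherits(observed, "PatternTable"), inherits(model, "NullModel"))
  if (!identical(sort(attr(observed, "factor_order")),
                 sort(names(model$marginals))))
    stop("observed table and null model have different factor sets")
  exp_tab <- expected_pattern_counts(model, min_factors = 1L)
  # align on label (factor order may differ between table and model)
  idx <- match(observed$label, exp_tab$label)
  if (anyNA(idx)) { # orders differ: align via canonical sorted labels
    canon <- function(lab) vapply(strsplit(lab, "+", fixed = TRUE),
                                  function(x) paste(sort(x), collapse = "+"), character(1))
    idx <- match(canon(observed$label), canon(exp_tab$label))
  }
  out <- data.frame(pattern = observed$pattern,
                    label = observed$label,
                    n_factors = observed$n_factors,
                    observed = observed$count,
                    expected = exp_tab$expected[idx],
                    variance = exp_tab$variance[idx],
                    stringsAsFactors = FALSE)
  z <- (out$observed - out$expected) / sqrt(out$variance)
  degen <- out$variance == 0
  if (any(degen)) {
    z[degen] <- ifelse(out$observed[degen] == out$expected[degen], 0,
                       sign(out$observed[degen] - out$expected[degen]) * Inf)
    if (any(is.infinite(z[degen])))
      warning("zero-variance pattern(s) with observed != expected: infinite Z")
  }
  out$zscore <- z
  out <- out[out$n_factors >= min_factors, , drop = FALSE]
  out <- out[order(-abs(out$zscore), out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "universe_N") <- model$universe_N
  class(out) <- c("PatternStats", "data.frame")
  out
}

#' Monte-Carlo oracle for the independence null
#'
#' Simulates `reps` landscapes of `universe_N` regions, each bound
#' independently by factor i with probability `p_i`, and tabulates
#' exact-pattern counts per landscape. Serves as an independent check on
#' the closed-form expectations and variances.
#'
#' @param model a [null_model()].
#' @param reps number of simulated landscapes (>= 100).
#' @param seed optional integer seed for reproducibility.
#' @return data.frame: pattern, label, mc_mean, mc_sd over the nonempty
#'   patterns; attribute `reps`.
#' @export
monte_carlo_null <- function(model, reps = 5000L, seed = NULL) {
  stopifnot(inherits(model, "NullModel"), reps >= 100)
  if (!is.null(seed)) set.seed(seed)
  p <- as.numeric(model$p)
  k <- length(p)
  N <- model$universe_N
  npat <- 2L^k
  pow <- 2L^(0:(k - 1L))
  counts <- matrix(0L, nrow = reps, ncol = npat)
  chunk <- max(1L, floor(2e6 / N))
  r <- 0L
  while (r < reps) {
    c_now <- min(chunk, reps - r)
    pat <- matrix(0L, nrow = N, ncol = c_now)
    for (j in seq_len(k))
      pat <- pat + pow[j] * (matrix(stats::runif(N * c_now), N, c_now) < p[j])
    counts[r + seq_len(c_now), ] <-
      t(vapply(seq_len(c_now), function(jj) tabulate(pat[, jj] + 1L, nbins = npat),
               integer(npat)))
    r <- r + c_now
  }
  masks <- pattern_masks(k)
  out <- data.frame(pattern = masks,
                    label = pattern_label(masks, names(model$marginals)),
                    mc_mean = colMeans(counts[, masks + 1L, drop = FALSE]),
                    mc_sd = apply(counts[, masks + 1L, drop = FALSE], 2L, stats::sd),
                    stringsAsFactors = FALSE)
  attr(out, "reps") <- reps
  out
}

#' Serialize a pattern Z-score report
#'
#' TSV with a commented header recording the universe size and the
#' null's distributional form.
#'
#' @param stats a [pattern_zscores()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zscore_report <- function(stats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# universe_N=%s", attr(stats, "universe_N")),
               "# null: per-region independent binding; binomial E/V, normal-approximation Z"),
             con)
  utils::write.table(stats[, c("label", "n_factors", "observed", "expected",
                               "variance", "zscore")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
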