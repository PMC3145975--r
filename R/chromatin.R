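promoter_signal <- function(marks, pw) {
  # total mark score overlapping each promoter window
  if (is.null(marks) || nrow(marks) == 0) return(numeric(length(pw)))
  mg <- df_to_gr(marks)
  hits <- GenomicRanges::findOverlaps(pw, mg, ignore.strand = TRUE)
  sig <- numeric(length(pw))
  if (length(hits)) {
    s <- tapply(marks$score[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), sum)
    sig[as.integer(names(s))] <- as.numeric(s)
  }
  sig
}

#' Classify promoters as inactive, bivalent or active
#'
#' Promoters are classified from H3K4me3 (activating) and H3K27me3
#' (repressive) signal over the promoter window: K4+/K27- is `active`,
#' K4+/K27+ is `bivalent`, and K4- is `inactive` (with or without K27).
#' By default a mark is "present" when any called mark region with
#' positive score overlaps the window (`mode = "overlap"`); with
#' `mode = "quantile"` a mark is present when its summed window signal
#' reaches the given quantile of positive signals, for continuous
#' tracks. H3ac signal, when supplied, is reported alongside but does
#' not enter the three-way rule.
#'
#' @param genes a [gene_models()] table.
#' @param k4,k27 scored mark regions: data.frame chrom/start/end/score
#'   (0-based half-open) as from [read_scored_bed()].
#' @param h3ac optional acetylation mark regions, reported only.
#' @param mode "overlap" (presence = any overlapping called region) or
#'   "quantile" (presence = window signal >= the `quantile` of positive
#'   window signals for that mark).
#' @param quantile threshold quantile for `mode = "quantile"`.
#' @param upstream,downstream promoter window (bp).
#' @return data.frame: gene_id, k4_signal, k27_signal, (h3ac_signal,)
#'   state. Genes without any signal record have signal 0 and are
#'   inactive.
#' @export
classify_promoters <- function(genes, k4, k27, h3ac = NULL,
                               mode = c("overlap", "quantile"),
                               quantile = 0.75,
                               upstream = 1000L, downstream = 500L) {
  mode <- match.arg(mode)
  pw <- promoter_windows(genes, upstream, downstream)
  k4s <- promoter_signal(k4, pw)
  k27s <- promoter_signal(k27, pw)
  present <- function(sig) {
    if (mode == "overlap") sig > 0
    else sig >= stats::quantile(sig[sig > 0], quantile, names = FALSE)
  }
  k4p <- present(k4s)
  k27p <- present(k27s)
  state <- ifelse(k4p & !k27p, "active", ifelse(k4p & k27p, "bivalent", "inactive"))
  out <- data.frame(gene_id = genes$gene_id, k4_signal = k4s,
                    k27_signal = k27s, stringsAsFactors = FALSE)
  if (!is.null(h3ac)) out$h3ac_signal <- promoter_signal(h3ac, pw)
  out$state <- factor(state, levels = c("inactive", "bivalent", "active"))
  out
}

#' Fraction of promoters bound by the profiled factors, per state
#'
#' A promoter counts as bound when any union region overlaps its
#' window; per-factor columns require the overlapping region's pattern
#' to include that factor. The published qualitative expectation is a
#' monotone ordering: inactive < bivalent < active bound fractions.
#'
#' @param states a [classify_promoters()] result.
#' @param occ an [assign_patterns()] result.
#' @param genes the same [gene_models()] table used for `states`.
#' @param upstream,downstream promoter window (bp).
#' @return data.frame: state, factor ("any" plus each factor), n
#'   promoters, n_bound, fraction (NA with a message for an empty state
#'   class).
#' @export
bound_fraction_by_state <- function(states, occ, genes,
                                    upstream = 1000L, downstream = 500L) {
  stopifnot(inherits(occ, "OccupancyRegions"))
  pw <- promoter_windows(genes, upstream, downstream)
  gid <- genes$gene_id
  hits <- GenomicRanges::findOverlaps(pw, occ$regions, ignore.strand = TRUE)
  pat_by_gene <- integer(length(pw))
  if (length(hits)) {
    agg <- tapply(S4Vectors::mcols(occ$regions)$pattern[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits),
                  function(p) Reduce(bitwOr, as.integer(p), 0L))
    pat_by_gene[as.integer(names(agg))] <- as.integer(agg)
  }
  st <- states$state[match(gid, states$gene_id)]
  fac_cols <- c("any", occ$factor_order)
  rows <- list()
  for (s in levels(st)) {
    sel <- which(st == s)
    for (fc in fac_cols) {
      bound <- if (fc == "any") pat_by_gene[sel] != 0L
               else has_bit(pat_by_gene[sel], match(fc, occ$factor_order))
      n <- length(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        state = s, factor = fc, n = n, n_bound = sum(bound),
        fraction = if (n == 0) NA_real_ else sum(bound) / n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$n == 0))
    message("state class(es) with no promoters: fraction undefined (NA)")
  out
}

#' Expression summaries per promoter state
#'
#' @param states a [classify_promoters()] result.
#' @param expression numeric matrix or data.frame, genes x cell types,
#'   with gene ids as rownames.
#' @param cell_type column to summarize.
#' @return data.frame: state, n, median, q25, q75, iqr. Genes missing
#'   from the expression matrix are dropped with a message; an empty
#'   gene intersection or unknown cell type is an error.
#' @export
expression_by_state <- function(states, expression, cell_type) {
  expression <- as.matrix(expression)
  if (!cell_type %in% colnames(expression))
    stop("cell type not in expression matrix: ", cell_type)
  common <- intersect(states$gene_id, rownames(expression))
  if (length(common) == 0) stop("no genes shared between states and expression")
  dropped <- nrow(states) - length(common)
  if (dropped > 0) message(dropped, " gene(s) missing from expression matrix; dropped")
  x <- expression[common, cell_type]
  st <- states$state[match(common, states$gene_id)]
  out <- do.call(rbind, lapply(levels(st), function(s) {
    xs <- x[st == s]
    q <- if (length(xs)) stats::quantile(xs, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(state = s, n = length(xs), median = q[2], q25 = q[1], q75 = q[3],
               iqr = q[3] - q[1], stringsAsFactors = FALSE)
  }))
  out
}
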