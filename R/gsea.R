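#' Rank genes by cell-type-specific expression
#'
#' Scores each gene as `log2((x_target + pc) / (mean(x_others) + pc))`
#' and orders genes by decreasing score, breaking score ties by gene id
#' so the ranking is deterministic under row permutation of the input.
#' (Signal-to-noise is the classic alternative metric; with a single
#' profile per cell type only ratio-style metrics are available.)
#'
#' @param expression genes x cell-types matrix/data.frame, gene ids as
#'   rownames; at least 2 columns.
#' @param target target cell-type column.
#' @param pseudocount offset added to both numerator and denominator
#'   (default 1); with `pseudocount = 0` non-positive expression is an
#'   error.
#' @return data.frame of class `RankedGenes`: gene_id, score, in rank
#'   order.
#' @export
rank_genes <- function(expression, target, pseudocount = 1) {
  expression <- as.matrix(expression)
  stopifnot(ncol(expression) >= 2)
  if (!target %in% colnames(expression)) stop("unknown cell type: ", target)
  others <- setdiff(colnames(expression), target)
  if (pseudocount == 0 && any(expression <= 0))
    stop("non-positive expression requires a pseudocount")
  score <- log2((expression[, target] + pseudocount) /
                (rowMeans(expression[, others, drop = FALSE]) + pseudocount))
  out <- data.frame(gene_id = rownames(expression), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RankedGenes", "data.frame")
  out
}

# core running-sum statistic on a prepared hit indicator
running_sum_es <- function(score, hit, weight_p) {
  nh <- sum(hit)
  n <- length(hit)
  w <- abs(score)^weight_p
  denom <- sum(w[hit])
  inc <- if (denom > 0) ifelse(hit, w / denom, 0) else ifelse(hit, 1 / nh, 0)
  dec <- ifelse(hit, 0, 1 / (n - nh))
  rs <- cumsum(inc - dec)
  # extremum pick tolerant to accumulation rounding: first rank whose
  # deviation is within 1e-12 of the maximum
  a <- abs(rs)
  es <- rs[which(a >= max(a) - 1e-12)[1]]
  list(es = es, running_sum = rs)
}

#' Running-sum enrichment score of a gene set
#'
#' The classic weighted Kolmogorov-Smirnov statistic: walking down the
#' ranked list, set members ("hits") increment the running sum by
#' `|score|^p` normalized over the hits, non-members decrement it by
#' `1/(N - |S|)`; the enrichment score is the signed extremum. The sum
#' starts and ends at 0 and ES lies in [-1, 1].
#'
#' @param ranked a [rank_genes()] result.
#' @param gene_set character vector of gene ids; its intersection with
#'   the ranked list must be nonempty and proper.
#' @param weight_p hit weight exponent (default 1; 0 gives the
#'   unweighted KS statistic).
#' @return list with `es` and `running_sum` (vector over ranks).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(inherits(ranked, "data.frame"), "score" %in% names(ranked))
  hit <- ranked$gene_id %in% gene_set
  if (!any(hit)) stop("gene set has no overlap with the ranked list")
  if (all(hit)) stop("gene set covers the whole ranked list")
  running_sum_es(ranked$score, hit, weight_p)
}

#' Gene-set enrichment significance for pattern target lists
#'
#' For each gene set: null ES from `permutations` random same-size gene
#' sets (gene-set permutation; phenotype permutation is impossible with
#' one profile per cell type), NES = ES normalized by the mean |null ES|
#' of the same sign, nominal p from the same-sign null tail, and FDR q
#' from the pooled null-NES distribution as in the standard gene-set
#' permutation scheme, made monotone in |NES|.
#'
#' @param ranked a [rank_genes()] result.
#' @param gene_sets named list of gene-id vectors (e.g. the per-pattern
#'   target lists), or a [build_target_gene_lists()] result.
#' @param permutations random sets per gene set (>= 100).
#' @param weight_p see [enrichment_score()].
#' @param seed optional integer seed.
#' @return data.frame of class `GseaResults`: set, size, es, nes, p,
#'   fdr_q, sorted by decreasing NES; running sums kept in attribute
#'   `running_sums` (named list).
#' @export
gsea_significance <- function(ranked, gene_sets, permutations = 1000L,
                              weight_p = 1, seed = NULL) {
  stopifnot(permutations >= 100)
  if (inherits(gene_sets, "TargetGeneLists"))
    gene_sets <- split(gene_sets$gene_id, gene_sets$label)
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ranked)
  universe <- ranked$gene_id
  score <- ranked$score

  sizes <- vapply(gene_sets, function(s) sum(universe %in% s), integer(1))
  if (any(sizes >= n)) stop("gene set at least as large as the ranked list")
  usable <- sizes > 0
  if (!all(usable)) {
    warning(sum(!usable), " gene set(s) with no overlap with the ranked list; skipped")
    gene_sets <- gene_sets[usable]
    sizes <- sizes[usable]
  }
  if (length(gene_sets) == 0) stop("no usable gene sets")

  es_obs <- numeric(length(gene_sets))
  run_sums <- vector("list", length(gene_sets))
  null_es <- matrix(0, nrow = permutations, ncol = length(gene_sets))
  for (j in seq_along(gene_sets)) {
    hit <- universe %in% gene_sets[[j]]
    r <- running_sum_es(score, hit, weight_p)
    es_obs[j] <- r$es
    run_sums[[j]] <- r$running_sum
    sz <- sizes[j]
    for (b in seq_len(permutations)) {
      rh <- logical(n)
      rh[sample.int(n, sz)] <- TRUE
      null_es[b, j] <- running_sum_es(score, rh, weight_p)$es
    }
  }

  normalize <- function(es, pos_m, neg_m) {
    ifelse(es >= 0,
           ifelse(is.finite(pos_m) & pos_m > 0, es / pos_m, NA_real_),
           ifelse(is.finite(neg_m) & neg_m > 0, es / neg_m, NA_real_))
  }
  pos_m <- apply(null_es, 2, function(x) mean(x[x >= 0]))
  neg_m <- apply(null_es, 2, function(x) mean(abs(x[x < 0])))
  nes_obs <- normalize(es_obs, pos_m, neg_m)
  nes_null <- vapply(seq_along(es_obs), function(j)
    normalize(null_es[, j], pos_m[j], neg_m[j]), numeric(permutations))
  p_nom <- vapply(seq_along(es_obs), function(j) {
    same <- if (es_obs[j] >= 0) null_es[, j][null_es[, j] >= 0] else null_es[, j][null_es[, j] < 0]
    if (length(same) == 0) return(1 / permutations)
    (sum(abs(same) >= abs(es_obs[j])) + 1) / (length(same) + 1)
  }, numeric(1))

  pool <- as.numeric(nes_null)
  pool <- pool[is.finite(pool)]
  fdr_one <- function(nes) {
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      null_frac <- if (sum(pool >= 0)) sum(pool >= nes) / sum(pool >= 0) else 0
      obs_frac <- sum(nes_obs >= nes, na.rm = TRUE) / max(1, sum(nes_obs >= 0, na.rm = TRUE))
    } else {
      null_frac <- if (sum(pool < 0)) sum(pool <= nes) / sum(pool < 0) else 0
      obs_frac <- sum(nes_obs <= nes, na.rm = TRUE) / max(1, sum(nes_obs < 0, na.rm = TRUE))
    }
    min(1, null_frac / max(obs_frac, .Machine$double.eps))
  }
  q <- vapply(nes_obs, fdr_one, numeric(1))
  # monotone: q never decreases as |NES| falls, within each sign
  for (sgn in c(1, -1)) {
    idx <- which(sign(nes_obs) == sgn | (sgn == 1 & nes_obs == 0))
    if (length(idx) > 1) {
      o <- idx[order(abs(nes_obs[idx]))]
      q[o] <- cummin(replace(q[o], is.na(q[o]), 1))
    }
  }

  out <- data.frame(set = names(gene_sets), size = sizes, es = es_obs,
                    nes = nes_obs, p = p_nom, fdr_q = q,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$nes), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "running_sums") <- stats::setNames(run_sums, names(gene_sets))
  attr(out, "permutation_type") <- "gene_set"
  class(out) <- c("GseaResults", "data.frame")
  out
}

#' Write a GSEA report TSV
#'
#' @param results a [gsea_significance()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gsea_report <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# permutation_type=gene_set; NES normalized by same-sign null mean", con)
  utils::write.table(as.data.frame(results), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
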