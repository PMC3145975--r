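#' Configuration for the synthetic binding landscape
#'
#' The generator emulates a five-factor ChIP-seq study as a latent-site
#' mixture: a universe of candidate binding sites spread over the
#' genome, each emitting factor peaks independently with background
#' probabilities tuned so realized per-factor marginals hit their
#' targets; planted "complex" sites near the promoters of designated
#' target genes that emit all five factors with high probability;
#' planted pair sites co-emitting GATA1 and SCL; a suppression rule that
#' deletes most sites whose exact pattern would be GATA1+FLI1 only (the
#' underrepresented pattern); promoter-coupled binding with monotone
#' probability over chromatin state; histone marks emitted from latent
#' promoter states; an expression matrix in which planted target genes
#' are upregulated in the target cell type; and sequences with embedded
#' consensus motifs, including the composite E-box/GATA element in exact
#' GATA1+SCL sites. All randomness flows from `seed`.
#'
#' Default scale (2 x 5 Mb, 300 genes, ~250-870 peaks per factor in the
#' study's relative proportions at 1/10 scale, 40 complex sites, a
#' 10,000-site universe) runs the full pipeline in seconds.
#'
#' @param seed integer master seed.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param n_genes number of genes.
#' @param factors ordered factor labels (K of them).
#' @param marginal_targets named per-factor target peak counts.
#' @param n_sites number of candidate binding sites (the universe).
#' @param universe_N universe size used downstream for the null
#'   (defaults to `n_sites`).
#' @param n_complex planted all-factor complex sites (each tied to one
#'   target gene).
#' @param complex_emission per-factor emission probability at complex
#'   sites.
#' @param n_pair planted GATA1+SCL pair sites.
#' @param pair_emission,pair_other emission probabilities at pair sites
#'   for the pair factors / the others.
#' @param suppress_pattern factor subset whose exact pattern is
#'   suppressed; `suppress_prob` is the deletion probability.
#' @param suppress_prob see `suppress_pattern`.
#' @param peak_len min/max peak length (bp); `peak_jitter` peak-center
#'   jitter (bp).
#' @param peak_jitter see `peak_len`.
#' @param promoter_upstream,promoter_downstream promoter window (bp).
#' @param state_prior prior over promoter states inactive/bivalent/active.
#' @param promoter_bind_prob probability a gene's promoter carries a
#'   bound site, per state (monotone by construction).
#' @param promoter_emission per-factor emission probability at bound
#'   promoter sites (at least one factor forced).
#' @param mark_miss,mark_spurious histone-mark dropout / spurious-mark
#'   probabilities (0 gives noise-free marks).
#' @param cell_types expression matrix columns; `target_cell` is the
#'   cell type whose specific genes are planted.
#' @param target_cell see `cell_types`.
#' @param state_expr mean log2 expression per promoter state.
#' @param expr_noise_sd log2 expression noise sd.
#' @param mk_delta log2 upregulation of planted target genes in the
#'   target cell type.
#' @param gene_length min/max gene length (bp).
#' @param seq_length region sequence length for the motif stage (bp).
#' @param embed motif embedding probabilities: composite (in exact
#'   GATA1+SCL sites), gata, ebox, ets, runx (per bound factor).
#' @return object of class `LandscapeConfig` (a validated list).
#' @export
landscape_config <- function(seed = 1L,
                             chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
                             n_genes = 300L,
                             factors = c("GATA1", "GATA2", "RUNX1", "FLI1", "SCL"),
                             marginal_targets = c(GATA1 = 472, GATA2 = 248,
                                                  RUNX1 = 734, FLI1 = 869, SCL = 308),
                             n_sites = 10000L,
                             universe_N = n_sites,
                             n_complex = 40L, complex_emission = 0.95,
                             n_pair = 30L, pair_emission = 0.9, pair_other = 0.05,
                             suppress_pattern = c("GATA1", "FLI1"),
                             suppress_prob = 0.8,
                             peak_len = c(200L, 400L), peak_jitter = 50L,
                             promoter_upstream = 1000L, promoter_downstream = 500L,
                             state_prior = c(inactive = 0.3, bivalent = 0.2, active = 0.5),
                             promoter_bind_prob = c(inactive = 0.05, bivalent = 0.35,
                                                    active = 0.7),
                             promoter_emission = 0.45,
                             mark_miss = 0.05, mark_spurious = 0.02,
                             cell_types = c("MK", "CD4", "CD8", "CD14", "CD19",
                                            "CD56", "CD66b", "EB"),
                             target_cell = "MK",
                             state_expr = c(inactive = 4, bivalent = 5.5, active = 7),
                             expr_noise_sd = 0.8, mk_delta = 2,
                             gene_length = c(2000L, 20000L),
                             seq_length = 300L,
                             embed = list(composite = 0.8, gata = 0.6, ebox = 0.5,
                                          ets = 0.5, runx = 0.5)) {
  cfg <- as.list(environment())
  probs <- c(cfg$complex_emission, cfg$pair_emission, cfg$pair_other,
             cfg$suppress_prob, cfg$promoter_emission, cfg$mark_miss,
             cfg$mark_spurious, unlist(cfg$embed), cfg$promoter_bind_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(cfg$marginal_targets > 0),
            setequal(names(cfg$marginal_targets), cfg$factors),
            cfg$n_genes >= 1, cfg$n_sites >= 10,
            abs(sum(cfg$state_prior) - 1) < 1e-8,
            cfg$target_cell %in% cfg$cell_types,
            all(cfg$suppress_pattern %in% cfg$factors) ||
              length(cfg$suppress_pattern) == 0)
  cfg$marginal_targets <- cfg$marginal_targets[cfg$factors]
  class(cfg) <- "LandscapeConfig"
  cfg
}

#' A configuration with purely independent binding (the null)
#'
#' No complex or pair sites, no suppression, no promoter coupling:
#' every site emits each factor independently. Used to check the
#' calibration of the pattern Z-scores.
#'
#' @param seed integer seed.
#' @param marginal_targets per-factor targets (defaults give every
#'   multi-factor pattern an expected count comfortably above the normal
#'   approximation's validity floor).
#' @param n_sites universe size.
#' @param ... further overrides passed to [landscape_config()].
#' @return a [landscape_config()].
#' @export
null_landscape_config <- function(seed = 1L,
                                  marginal_targets = c(GATA1 = 3000, GATA2 = 2600,
                                                       RUNX1 = 3400, FLI1 = 3200,
                                                       SCL = 2800),
                                  n_sites = 10000L, ...) {
  landscape_config(seed = seed, marginal_targets = marginal_targets,
                   n_sites = n_sites, n_complex = 0L, n_pair = 0L,
                   suppress_prob = 0,
                   promoter_bind_prob = c(inactive = 0, bivalent = 0, active = 0),
                   ...)
}

#' Generate non-overlapping gene models
#'
#' Strand-balanced gene bodies rejection-sampled onto the chromosomes
#' without overlap, with latent promoter states drawn from the state
#' prior and `n_complex` target genes designated among the active ones
#' (topped up from bivalent if needed).
#'
#' @param config a [landscape_config()].
#' @return a [gene_models()] table with extra columns `state` and
#'   `mk_target`.
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "LandscapeConfig"))
  set.seed(config$seed + 1L)
  sizes <- config$chrom_sizes
  n <- config$n_genes
  n_by_chrom <- round(n * sizes / sum(sizes))
  n_by_chrom[length(n_by_chrom)] <- n - sum(n_by_chrom[-length(n_by_chrom)])
  rows <- list()
  for (ci in seq_along(sizes)) {
    ch <- names(sizes)[ci]
    placed_start <- numeric(0); placed_end <- numeric(0)
    tries <- 0L
    while (length(placed_start) < n_by_chrom[ci]) {
      tries <- tries + 1L
      if (tries > 200L * n_by_chrom[ci])
        stop("infeasible gene packing on ", ch)
      len <- round(stats::runif(1, config$gene_length[1], config$gene_length[2]))
      start <- round(stats::runif(1, 2000, sizes[ci] - len - 2000))
      # 2.5 kb clearance keeps neighbouring promoter windows (and the
      # histone-mark footprints emitted at the TSS) from overlapping
      if (any(start < placed_end + 2500 & start + len + 2500 > placed_start)) next
      placed_start <- c(placed_start, start)
      placed_end <- c(placed_end, start + len)
    }
    o <- order(placed_start)
    rows[[ci]] <- data.frame(chrom = ch, start = as.integer(placed_start[o]),
                             end = as.integer(placed_end[o]),
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$gene_id <- sprintf("G%04d", seq_len(nrow(df)))
  df$strand <- sample(rep(c("+", "-"), length.out = nrow(df)))
  df$state <- sample(names(config$state_prior), nrow(df), replace = TRUE,
                     prob = config$state_prior)
  df$mk_target <- FALSE
  pool <- which(df$state == "active")
  if (length(pool) < config$n_complex)
    pool <- c(pool, which(df$state == "bivalent"))
  if (config$n_complex > 0)
    df$mk_target[sample(pool, min(config$n_complex, length(pool)))] <- TRUE
  gene_models(df)
}

#' Generate the factor peak landscape with ground-truth labels
#'
#' Lays candidate sites on a jittered grid (far enough apart that peaks
#' from different sites never merge), converts some to planted pair
#' sites, adds promoter-coupled sites per gene with state-dependent
#' probability and complex sites at the target genes' promoters, draws
#' per-factor emissions per site type, applies the exact-pattern
#' suppression rule, and realizes each emission as a peak interval.
#' Background emission probabilities are tuned (by closed-form
#' accounting of the planted contributions) so realized marginals land
#' within binomial error of the configured targets.
#'
#' @param config a [landscape_config()].
#' @param genes a [generate_gene_models()] result.
#' @return list: `peaksets` (list of [peak_set()]), `truth` (data.frame
#'   site_id, chrom, center, type, pattern, gene_id), `config`.
#' @export
generate_peak_landscape <- function(config, genes) {
  stopifnot(inherits(config, "LandscapeConfig"))
  set.seed(config$seed + 2L)
  K <- length(config$factors)
  sizes <- config$chrom_sizes
  n_by_chrom <- round(config$n_sites * sizes / sum(sizes))
  n_by_chrom[length(n_by_chrom)] <- config$n_sites - sum(n_by_chrom[-length(n_by_chrom)])

  site_chrom <- character(0); site_center <- numeric(0)
  for (ci in seq_along(sizes)) {
    spacing <- sizes[ci] / n_by_chrom[ci]
    centers <- (seq_len(n_by_chrom[ci]) - 0.5) * spacing +
      stats::runif(n_by_chrom[ci], -spacing / 5, spacing / 5)
    site_chrom <- c(site_chrom, rep(names(sizes)[ci], n_by_chrom[ci]))
    site_center <- c(site_center, round(centers))
  }
  type <- rep("bg", config$n_sites)
  gene_of <- rep(NA_character_, config$n_sites)
  if (config$n_pair > 0)
    type[sample.int(config$n_sites, config$n_pair)] <- "pair"

  # promoter-coupled sites (state-dependent) and complex sites at target genes
  extra_chrom <- character(0); extra_center <- numeric(0)
  extra_type <- character(0); extra_gene <- character(0)
  pbind <- config$promoter_bind_prob[genes$state]
  prom_bound <- stats::runif(nrow(genes)) < pbind
  for (gi in which(prom_bound)) {
    extra_chrom <- c(extra_chrom, genes$chrom[gi])
    extra_center <- c(extra_center, genes$tss[gi])
    extra_type <- c(extra_type, "promoter")
    extra_gene <- c(extra_gene, genes$gene_id[gi])
  }
  for (gi in which(genes$mk_target)) {
    off <- round(stats::runif(1, 200, 800))
    ctr <- if (genes$strand[gi] == "+") genes$tss[gi] - off else genes$tss[gi] + off
    extra_chrom <- c(extra_chrom, genes$chrom[gi])
    extra_center <- c(extra_center, ctr)
    extra_type <- c(extra_type, "complex")
    extra_gene <- c(extra_gene, genes$gene_id[gi])
  }
  # drop grid sites close to an extra site so union regions stay site-pure
  if (length(extra_center)) {
    keep <- rep(TRUE, length(site_center))
    for (ci in names(sizes)) {
      gi <- which(extra_chrom == ci)
      si <- which(site_chrom == ci)
      if (!length(gi) || !length(si)) next
      near <- vapply(site_center[si], function(x)
        any(abs(extra_center[gi] - x) < 600), logical(1))
      keep[si[near]] <- FALSE
    }
    site_chrom <- c(site_chrom[keep], extra_chrom)
    site_center <- c(site_center[keep], extra_center)
    type <- c(type[keep], extra_type)
    gene_of <- c(gene_of[keep], extra_gene)
  }
  n_all <- length(site_center)

  # background emission probabilities from marginal accounting
  n_bg <- sum(type == "bg")
  pe <- config$promoter_emission
  pe_eff <- pe + (1 - pe)^K / K            # one factor forced when none emits
  exp_prom <- sum(type == "promoter") * pe_eff
  pair_mask_factors <- c("GATA1", "SCL")
  exp_complex <- sum(type == "complex") * config$complex_emission
  p_bg <- vapply(config$factors, function(f) {
    exp_pair <- sum(type == "pair") *
      if (f %in% pair_mask_factors) config$pair_emission else config$pair_other
    max(1e-4, (config$marginal_targets[[f]] - exp_complex - exp_pair - exp_prom) / n_bg)
  }, numeric(1))

  emit <- matrix(FALSE, n_all, K, dimnames = list(NULL, config$factors))
  bg_idx <- type == "bg"
  for (j in seq_len(K))
    emit[bg_idx, j] <- stats::runif(sum(bg_idx)) < p_bg[j]
  pair_idx <- type == "pair"
  for (j in seq_len(K)) {
    pp <- if (config$factors[j] %in% pair_mask_factors) config$pair_emission else config$pair_other
    emit[pair_idx, j] <- stats::runif(sum(pair_idx)) < pp
  }
  cx_idx <- type == "complex"
  for (j in seq_len(K))
    emit[cx_idx, j] <- stats::runif(sum(cx_idx)) < config$complex_emission
  pr_idx <- which(type == "promoter")
  for (j in seq_len(K))
    emit[pr_idx, j] <- stats::runif(length(pr_idx)) < pe
  none <- pr_idx[rowSums(emit[pr_idx, , drop = FALSE]) == 0]
  if (length(none))
    emit[cbind(none, sample.int(K, length(none), replace = TRUE))] <- TRUE

  # suppression of the designated exact pattern
  if (length(config$suppress_pattern) && config$suppress_prob > 0) {
    sup_mask <- pattern_mask(config$suppress_pattern, config$factors)
    site_mask <- as.integer(emit %*% 2^(seq_len(K) - 1L))
    hit <- which(site_mask == sup_mask)
    kill <- hit[stats::runif(length(hit)) < config$suppress_prob]
    emit[kill, ] <- FALSE
  }

  site_mask <- as.integer(emit %*% 2^(seq_len(K) - 1L))
  truth <- data.frame(site_id = sprintf("S%05d", seq_len(n_all)),
                      chrom = site_chrom, center = site_center, type = type,
                      pattern = site_mask, gene_id = gene_of,
                      stringsAsFactors = FALSE)

  peaksets <- vector("list", K)
  for (j in seq_len(K)) {
    idx <- which(emit[, j])
    if (length(idx)) {
      len <- round(stats::runif(length(idx), config$peak_len[1], config$peak_len[2]))
      ctr <- site_center[idx] +
        round(stats::runif(length(idx), -config$peak_jitter, config$peak_jitter))
      start <- pmax(0L, as.integer(round(ctr - len / 2)))
      end <- pmin(as.integer(sizes[site_chrom[idx]]), start + len)
      df <- data.frame(chrom = site_chrom[idx], start = start, end = end,
                       name = truth$site_id[idx], stringsAsFactors = FALSE)
    } else {
      df <- data.frame(chrom = character(), start = integer(), end = integer())
    }
    peaksets[[j]] <- suppressMessages(peak_set(config$factors[j], df))
  }
  list(peaksets = peaksets, truth = truth, config = config)
}

#' Generate histone marks and the expression matrix
#'
#' Histone marks are emitted from the genes' latent promoter states
#' (active: H3K4me3; bivalent: H3K4me3 + H3K27me3; inactive: no
#' H3K4me3, H3K27me3 in half the cases; H3ac accompanies active
#' promoters) with dropout `mark_miss` and spurious additions
#' `mark_spurious`. Expression is log-normal around the state mean, and
#' planted target genes gain `mk_delta` log2 units in the target cell
#' type only.
#'
#' @param config a [landscape_config()].
#' @param genes a [generate_gene_models()] result.
#' @return list: `k4`, `k27`, `h3ac` (scored mark data.frames),
#'   `expression` (genes x cell-types matrix, linear scale).
#' @export
generate_histone_and_expression <- function(config, genes) {
  stopifnot(inherits(config, "LandscapeConfig"), length(config$cell_types) >= 2)
  set.seed(config$seed + 3L)
  n <- nrow(genes)
  miss <- function(p_base) stats::runif(n) < p_base * (1 - config$mark_miss)
  has_k4 <- (genes$state %in% c("active", "bivalent") & miss(1)) |
    (stats::runif(n) < config$mark_spurious)
  has_k27 <- (genes$state == "bivalent" & miss(1)) |
    (genes$state == "inactive" & miss(0.5)) |
    (stats::runif(n) < config$mark_spurious)
  has_ac <- genes$state == "active" & miss(0.9)
  mark_df <- function(sel) {
    # mark footprint: +/-200 bp around the TSS, well inside the promoter
    # window and clear of neighbouring genes' windows
    d <- data.frame(chrom = genes$chrom[sel],
                    start = pmax(0L, genes$tss[sel] - 200L),
                    end = genes$tss[sel] + 200L,
                    stringsAsFactors = FALSE)
    d$score <- round(stats::runif(sum(sel), 5, 50), 2)
    rownames(d) <- NULL
    d
  }
  expr_log2 <- matrix(config$state_expr[genes$state] +
                        stats::rnorm(n * length(config$cell_types),
                                     sd = config$expr_noise_sd),
                      nrow = n, dimnames = list(genes$gene_id, config$cell_types))
  expr_log2[genes$mk_target, config$target_cell] <-
    expr_log2[genes$mk_target, config$target_cell] + config$mk_delta
  list(k4 = mark_df(has_k4), k27 = mark_df(has_k27), h3ac = mark_df(has_ac),
       expression = round(2^expr_log2, 3))
}

#' Generate region sequences with embedded motifs
#'
#' Each bound site gets an i.i.d. random DNA sequence; consensus-motif
#' instances are embedded according to the site's exact pattern: the
#' composite E-box/GATA element (gap 6 bp) in exact GATA1+SCL sites,
#' and single GATA / E-box / ETS / RUNX instances per bound factor
#' elsewhere, each with its configured probability. Embedding positions
#' are recorded.
#'
#' @param config a [landscape_config()].
#' @param truth the `truth` table from [generate_peak_landscape()].
#' @return list: `sequences` (named DNAStringSet over bound sites) and
#'   `embeddings` (data.frame site_id, motif, start).
#' @export
generate_sequences <- function(config, truth) {
  stopifnot(inherits(config, "LandscapeConfig"))
  set.seed(config$seed + 4L)
  bound <- truth[truth$pattern != 0L, , drop = FALSE]
  L <- config$seq_length
  fmask <- function(...) pattern_mask(c(...), config$factors)
  pair_mask <- fmask("GATA1", "SCL")
  emb_rows <- list()
  seqs <- character(nrow(bound))
  for (i in seq_len(nrow(bound))) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    used <- integer(0)
    place <- function(instance, motif_name) {
      w <- nchar(instance)
      for (try in 1:20) {
        pos <- sample.int(L - w + 1L, 1L)
        if (!any(pos:(pos + w - 1L) %in% used)) {
          s[pos:(pos + w - 1L)] <<- strsplit(instance, "")[[1]]
          used <<- c(used, pos:(pos + w - 1L))
          emb_rows[[length(emb_rows) + 1L]] <<- data.frame(
            site_id = bound$site_id[i], motif = motif_name, start = pos,
            stringsAsFactors = FALSE)
          return(invisible(NULL))
        }
      }
    }
    m <- bound$pattern[i]
    if (m == pair_mask) {
      if (stats::runif(1) < config$embed$composite)
        place(paste0("CAGCTG", paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                                     collapse = ""), "AGATAA"), "EBOX_GATA")
    } else {
      if (bitwAnd(m, fmask("GATA1", "GATA2")) != 0L && stats::runif(1) < config$embed$gata)
        place("AGATAA", "GATA")
      if (bitwAnd(m, fmask("SCL")) != 0L && stats::runif(1) < config$embed$ebox)
        place("CAGCTG", "EBOX")
      if (bitwAnd(m, fmask("FLI1")) != 0L && stats::runif(1) < config$embed$ets)
        place("GGAA", "ETS")
      if (bitwAnd(m, fmask("RUNX1")) != 0L && stats::runif(1) < config$embed$runx)
        place("TGTGGT", "RUNX")
    }
    seqs[i] <- paste(s, collapse = "")
  }
  embeddings <- if (length(emb_rows)) do.call(rbind, emb_rows)
                else data.frame(site_id = character(), motif = character(),
                                start = integer(), stringsAsFactors = FALSE)
  list(sequences = stats::setNames(Biostrings::DNAStringSet(seqs), bound$site_id),
       embeddings = embeddings)
}

#' Generate a complete synthetic landscape, optionally writing files
#'
#' Runs all generators from one config; with `dir` set, writes the
#' standard-format inputs every pipeline stage reads: per-factor BED
#' peak files, GTF and BED12 gene models, scored BED histone marks, the
#' expression TSV, region FASTA, and a `truth.json` with the
#' ground-truth labels.
#'
#' @param config a [landscape_config()].
#' @param dir optional output directory (created if needed).
#' @return list: `config`, `genes`, `peaksets`, `truth`, `marks`,
#'   `expression`, `sequences`, `embeddings`, and `paths` when `dir` is
#'   given.
#' @export
generate_landscape <- function(config = landscape_config(), dir = NULL) {
  genes <- generate_gene_models(config)
  land <- generate_peak_landscape(config, genes)
  he <- generate_histone_and_expression(config, genes)
  sq <- generate_sequences(config, land$truth)
  out <- list(config = config, genes = genes, peaksets = land$peaksets,
              truth = land$truth, k4 = he$k4, k27 = he$k27, h3ac = he$h3ac,
              expression = he$expression, sequences = sq$sequences,
              embeddings = sq$embeddings)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (ps in land$peaksets) {
      paths[[paste0("peaks_", ps$factor)]] <-
        write_bed(ps, file.path(dir, paste0("peaks_", ps$factor, ".bed")))
    }
    paths$gtf <- write_gene_models_gtf(genes, file.path(dir, "genes.gtf"))
    paths$bed12 <- write_gene_models_bed12(genes, file.path(dir, "genes.bed12"))
    for (mk in c("k4", "k27", "h3ac"))
      paths[[mk]] <- write_bed(out[[mk]], file.path(dir, paste0(mk, ".bed")))
    expr_path <- file.path(dir, "expression.tsv")
    utils::write.table(data.frame(gene_id = rownames(he$expression),
                                  he$expression, check.names = FALSE),
                       expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$expression <- expr_path
    fa <- file.path(dir, "sequences.fa")
    Biostrings::writeXStringSet(sq$sequences, fa)
    paths$fasta <- fa
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(list(genes = genes, sites = land$truth,
                              embeddings = sq$embeddings),
                         truth_path, auto_unbox = TRUE, digits = NA)
    paths$truth <- truth_path
    out$paths <- paths
  }
  out
}
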