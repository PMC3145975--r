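# Independent brute-force oracles. These deliberately avoid the package's
# GRanges-based code paths: unions and patterns are computed from per-base
# coverage vectors, gene assignment by exhaustive search over all genes,
# the running-sum statistic by a plain loop, and motif matching by per-
# position IUPAC set comparison.

# ---- per-base union/pattern oracle (genomes small enough for vectors) ----
oracle_union_patterns <- function(peaksets, chrom_sizes) {
  k <- length(peaksets)
  out <- list()
  for (ch in names(chrom_sizes)) {
    L <- chrom_sizes[[ch]]
    cov <- matrix(FALSE, nrow = L, ncol = k)
    for (j in seq_len(k)) {
      df <- as.data.frame(peaksets[[j]])
      df <- df[df$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(df))) {
        lo <- max(1L, df$start[r] + 1L); hi <- min(L, df$end[r])
        if (lo <= hi) cov[lo:hi, j] <- TRUE
      }
    }
    any_cov <- rowSums(cov) > 0
    r <- rle(any_cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      rows <- starts[i]:ends[i]
      mask <- sum(2L^(which(colSums(cov[rows, , drop = FALSE]) > 0) - 1L))
      out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                            start = starts[i] - 1L,
                                            end = ends[i],
                                            pattern = as.integer(mask),
                                            stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# ---- exhaustive nearest-gene assignment for one region ----
oracle_assign <- function(chrom, start, end, genes, upstream = 1000L,
                          downstream = 500L, cap = 100000L) {
  last <- end - 1L
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  prom <- character(0); body <- character(0)
  for (i in seq_len(nrow(g))) {
    t <- g$tss[i]
    win <- if (g$strand[i] == "+") c(t - upstream, t + downstream - 1L)
           else c(t - downstream + 1L, t + upstream)
    win[1] <- max(0L, win[1])
    if (start <= win[2] && last >= win[1]) prom <- c(prom, g$gene_id[i])
    if (start <= g$end[i] - 1L && last >= g$start[i]) body <- c(body, g$gene_id[i])
  }
  if (length(prom))
    return(data.frame(gene_id = sort(prom), category = "promoter", distance = 0L))
  if (length(body))
    return(data.frame(gene_id = sort(body), category = "intragenic", distance = 0L))
  res <- list()
  for (side in c("left", "right")) {
    if (side == "left") sel <- g$tss < start else sel <- g$tss > last
    if (!any(sel)) next
    gg <- g[sel, , drop = FALSE]
    d <- pmax(start - gg$tss, gg$tss - last)
    o <- order(d, gg$gene_id)
    if (d[o[1]] <= cap)
      res[[length(res) + 1L]] <- data.frame(gene_id = gg$gene_id[o[1]],
                                            category = "intergenic",
                                            distance = d[o[1]])
  }
  if (length(res)) unique(do.call(rbind, res))
  else data.frame(gene_id = character(), category = character(), distance = integer())
}

# ---- plain-loop running sum ----
oracle_es <- function(scores, hit, p = 1) {
  n <- length(scores); nh <- sum(hit)
  w <- abs(scores)^p
  denom <- sum(w[hit])
  rs <- numeric(n); cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) cur <- cur + (if (denom > 0) w[i] / denom else 1 / nh)
    else cur <- cur - 1 / (n - nh)
    rs[i] <- cur
  }
  a <- abs(rs)
  rs[which(a >= max(a) - 1e-12)[1]]
}

# ---- per-position IUPAC motif scan ----
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))
COMPL <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
           W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N")

iupac_match_at <- function(seq_chars, pat_chars, pos) {
  w <- length(pat_chars)
  if (pos + w - 1L > length(seq_chars)) return(FALSE)
  all(mapply(function(s, p) s %in% IUPAC_SETS[[p]],
             seq_chars[pos:(pos + w - 1L)], pat_chars))
}

oracle_simple_starts <- function(seq, iupac) {
  sc <- strsplit(toupper(seq), "")[[1]]
  pc <- strsplit(toupper(iupac), "")[[1]]
  rc <- rev(unname(COMPL[pc]))
  hits <- integer(0)
  for (pos in seq_len(length(sc) - length(pc) + 1L)) {
    if (iupac_match_at(sc, pc, pos) || iupac_match_at(sc, rc, pos))
      hits <- c(hits, pos)
  }
  hits
}

oracle_composite_count <- function(seq, p1, p2, smin, smax) {
  sc <- strsplit(toupper(seq), "")[[1]]
  L <- length(sc)
  feet <- matrix(integer(0), ncol = 2)
  strand_scan <- function(chars) {
    c1 <- strsplit(p1, "")[[1]]; c2 <- strsplit(p2, "")[[1]]
    s1 <- which(vapply(seq_len(L - length(c1) + 1L), function(i)
      iupac_match_at(chars, c1, i), logical(1)))
    s2 <- which(vapply(seq_len(L - length(c2) + 1L), function(i)
      iupac_match_at(chars, c2, i), logical(1)))
    out <- matrix(integer(0), ncol = 2)
    for (a in s1) for (b in s2) {
      gap <- b - (a + length(c1) - 1L) - 1L
      if (gap >= smin && gap <= smax)
        out <- rbind(out, c(a, b + length(c2) - 1L))
    }
    out
  }
  plus <- strand_scan(sc)
  rc <- rev(unname(COMPL[sc]))
  minus <- strand_scan(rc)
  if (nrow(minus))
    minus <- cbind(L - minus[, 2] + 1L, L - minus[, 1] + 1L)
  feet <- rbind(plus, minus)
  nrow(unique(feet))
}

# ---- small, fast landscape configs for unit tests ----
make_small_config <- function(seed, ...) {
  landscape_config(seed = seed,
                   chrom_sizes = c(chrA = 5e5, chrB = 5e5),
                   n_genes = 60L, n_sites = 800L,
                   marginal_targets = c(GATA1 = 60, GATA2 = 35, RUNX1 = 90,
                                        FLI1 = 100, SCL = 40),
                   n_complex = 8L, n_pair = 6L,
                   gene_length = c(1500L, 6000L),
                   ...)
}

make_tiny_config <- function(seed, ...) {
  landscape_config(seed = seed,
                   chrom_sizes = c(chrA = 60000, chrB = 40000),
                   n_genes = 10L, n_sites = 60L,
                   marginal_targets = c(GATA1 = 18, GATA2 = 10, RUNX1 = 22,
                                        FLI1 = 25, SCL = 12),
                   n_complex = 3L, n_pair = 3L,
                   gene_length = c(800L, 3000L),
                   peak_len = c(100L, 200L), peak_jitter = 20L,
                   ...)
}

random_peak_df <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000,
                           len = c(50, 300)) {
  start <- sample.int(max_pos - len[2], n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample(len[1]:len[2], n, replace = TRUE),
             stringsAsFactors = FALSE)
}
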