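IUPAC_OK <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

check_iupac <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(chars, IUPAC_OK)
  if (length(bad)) stop("invalid IUPAC character(s): ", paste(bad, collapse = ", "))
  paste(chars, collapse = "")
}

#' Consensus motifs (simple and composite)
#'
#' A simple motif is one IUPAC string. A composite motif is two IUPAC
#' parts that must occur in order on the same strand with a spacer gap
#' within `[spacer_min, spacer_max]` bp — e.g. the E-box/GATA composite
#' element bound by SCL/GATA complexes.
#'
#' @param name motif name.
#' @param iupac IUPAC consensus string.
#' @return object of class `ConsensusMotif`.
#' @export
consensus_motif <- function(name, iupac) {
  structure(list(name = name, iupac = check_iupac(iupac)),
            class = "ConsensusMotif")
}

#' @rdname consensus_motif
#' @param part1,part2 the two IUPAC parts, 5' to 3'.
#' @param spacer_min,spacer_max allowed gap range between part1's end
#'   and part2's start (bp), `spacer_min <= spacer_max`.
#' @export
composite_motif <- function(name, part1, part2, spacer_min, spacer_max) {
  stopifnot(spacer_min >= 0, spacer_min <= spacer_max)
  structure(list(name = name, part1 = check_iupac(part1),
                 part2 = check_iupac(part2),
                 spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max)),
            class = c("CompositeMotif", "ConsensusMotif"))
}

#' @export
print.ConsensusMotif <- function(x, ...) {
  if (inherits(x, "CompositeMotif"))
    cat("CompositeMotif ", x$name, ": ", x$part1, " -(", x$spacer_min, "..",
        x$spacer_max, ")- ", x$part2, "\n", sep = "")
  else cat("ConsensusMotif ", x$name, ": ", x$iupac, "\n", sep = "")
  invisible(x)
}

#' Default consensus motif library
#'
#' Conventional consensus strings for the GATA (WGATAR), E-box (CANNTG),
#' ETS (GGAW) and RUNX (TGYGGT) families, plus the composite
#' E-box/(2..10 bp)/GATA element.
#'
#' @return named list of motifs.
#' @export
default_motif_library <- function() {
  list(GATA = consensus_motif("GATA", "WGATAR"),
       EBOX = consensus_motif("EBOX", "CANNTG"),
       ETS = consensus_motif("ETS", "GGAW"),
       RUNX = consensus_motif("RUNX", "TGYGGT"),
       EBOX_GATA = composite_motif("EBOX_GATA", "CANNTG", "WGATAR", 2L, 10L))
}

# match starts of an IUPAC pattern on the forward strand of one sequence
iupac_starts <- function(pattern, seq) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), seq,
                                fixed = "subject")
  BiocGenerics::start(m)
}

scan_one_simple <- function(motif, seq) {
  fw <- iupac_starts(motif$iupac, seq)
  rc <- iupac_starts(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif$iupac))), seq)
  # a position matching on both strands is one (palindromic) site
  starts <- sort(unique(c(fw, rc)))
  strand <- ifelse(starts %in% fw, ifelse(starts %in% rc, "=", "+"), "-")
  data.frame(start = starts, end = starts + nchar(motif$iupac) - 1L,
             strand = strand, stringsAsFactors = FALSE)
}

scan_one_composite <- function(motif, seq) {
  pair_hits <- function(s) {
    p1 <- iupac_starts(motif$part1, s)
    p2 <- iupac_starts(motif$part2, s)
    if (!length(p1) || !length(p2)) return(NULL)
    e1 <- p1 + nchar(motif$part1) - 1L
    out <- list()
    for (i in seq_along(p1)) {
      gap <- p2 - e1[i] - 1L
      ok <- which(gap >= motif$spacer_min & gap <= motif$spacer_max)
      for (j in ok)
        out[[length(out) + 1L]] <- c(p1[i], p2[j] + nchar(motif$part2) - 1L)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  L <- length(seq)
  plus <- pair_hits(seq)
  minus_rc <- pair_hits(Biostrings::reverseComplement(seq))
  rows <- list()
  if (!is.null(plus))
    for (i in seq_len(nrow(plus)))
      rows[[length(rows) + 1L]] <- data.frame(start = plus[i, 1], end = plus[i, 2],
                                              strand = "+", stringsAsFactors = FALSE)
  if (!is.null(minus_rc))
    for (i in seq_len(nrow(minus_rc)))
      rows[[length(rows) + 1L]] <- data.frame(start = L - minus_rc[i, 2] + 1L,
                                              end = L - minus_rc[i, 1] + 1L,
                                              strand = "-", stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  # identical footprints on both strands collapse to one site
  df <- df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

#' Scan sequences for consensus-motif matches
#'
#' Counts matches on both strands (IUPAC-aware); overlapping matches at
#' different offsets count separately, while a palindromic match seen on
#' both strands at one footprint counts once. Composite motifs require
#' part1 then part2 in order on the same strand with the spacer within
#' range.
#'
#' @param sequences named character vector, DNAStringSet, or FASTA file
#'   path.
#' @param motif a [consensus_motif()] or [composite_motif()].
#' @return data.frame: seq_id, count; match positions (1-based,
#'   per-sequence) in attribute `positions`, a named list.
#' @export
scan_consensus <- function(sequences, motif) {
  stopifnot(inherits(motif, "ConsensusMotif"))
  seqs <- if (methods::is(sequences, "DNAStringSet")) sequences
          else if (is.character(sequences) && length(sequences) == 1 &&
                   file.exists(sequences)) Biostrings::readDNAStringSet(sequences)
          else Biostrings::DNAStringSet(toupper(sequences))
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%05d", seq_along(seqs))
  pos <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (inherits(motif, "CompositeMotif")) scan_one_composite(motif, s)
    else scan_one_simple(motif, s)
  })
  names(pos) <- names(seqs)
  out <- data.frame(seq_id = names(seqs),
                    count = vapply(pos, nrow, integer(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "positions") <- pos
  out
}

#' Motif enrichment between two sequence sets
#'
#' Counts sequences with at least one motif match in a target and a
#' background set, and tests the 2x2 table with Fisher's exact test
#' (two-sided). Fold enrichment is the ratio of with-match fractions; a
#' degenerate table gets a Haldane continuity correction for the fold
#' and odds ratio.
#'
#' @param target,background sequence inputs as in [scan_consensus()];
#'   both non-empty.
#' @param motif the motif to test.
#' @return list: n_target, n_background, target_with, background_with,
#'   target_frac, background_frac, fold, odds_ratio, p_value.
#' @export
motif_enrichment_test <- function(target, background, motif) {
  tc <- scan_consensus(target, motif)
  bc <- scan_consensus(background, motif)
  if (nrow(tc) == 0 || nrow(bc) == 0) stop("target and background must be non-empty")
  a <- sum(tc$count > 0); n1 <- nrow(tc)
  c_ <- sum(bc$count > 0); n2 <- nrow(bc)
  tab <- matrix(c(a, n1 - a, c_, n2 - c_), nrow = 2,
                dimnames = list(c("with", "without"), c("target", "background")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  degenerate <- a == 0 || c_ == 0 || a == n1 || c_ == n2
  fold <- if (degenerate) ((a + 0.5) / (n1 + 1)) / ((c_ + 0.5) / (n2 + 1))
          else (a / n1) / (c_ / n2)
  or <- if (degenerate) ((a + 0.5) * (n2 - c_ + 0.5)) / ((n1 - a + 0.5) * (c_ + 0.5))
        else unname(ft$estimate)
  list(n_target = n1, n_background = n2, target_with = a, background_with = c_,
       target_frac = a / n1, background_frac = c_ / n2,
       fold = fold, odds_ratio = or, p_value = ft$p.value)
}

#' Motif enrichment report over a motif library
#'
#' @param target,background sequence sets.
#' @param motifs named list of motifs (default [default_motif_library()]).
#' @return data.frame: motif, target_frac, background_frac, fold, p.
#' @export
motif_report <- function(target, background, motifs = default_motif_library()) {
  rows <- lapply(names(motifs), function(nm) {
    r <- motif_enrichment_test(target, background, motifs[[nm]])
    data.frame(motif = nm, target_frac = r$target_frac,
               background_frac = r$background_frac, fold = r$fold,
               p = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
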