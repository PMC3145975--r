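#' @importFrom GenomicRanges GRanges reduce findOverlaps promoters start end strand width seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
NULL

# All user-facing coordinates are 0-based half-open (BED dialect); GRanges
# used internally are 1-based inclusive. These two helpers are the only
# place the conversion happens.
df_to_gr <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else rep("*", nrow(df))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = strand)
  if ("score" %in% names(df)) S4Vectors::mcols(gr)$score <- df$score
  if ("name" %in% names(df)) S4Vectors::mcols(gr)$name <- df$name
  gr
}

gr_to_df <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  m <- S4Vectors::mcols(gr)
  if ("name" %in% colnames(m)) df$name <- m$name
  if ("score" %in% colnames(m)) df$score <- m$score
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s != "*")) df$strand <- s
  df
}

#' Construct a peak set
#'
#' A `PeakSet` holds one factor's binding intervals, sorted by
#' (chromosome, start) with same-factor overlapping intervals merged: in
#' the pattern logic a factor either binds a region or it does not, so
#' stacked peaks collapse to one footprint.
#'
#' @param factor factor label, e.g. "GATA1".
#' @param intervals data.frame with columns chrom, start, end (0-based
#'   half-open) and optionally score, strand; or a GRanges.
#' @param merge merge overlapping same-factor intervals (default TRUE).
#' @return object of class `PeakSet` with elements `factor` and `ranges`
#'   (a sorted GRanges).
#' @export
peak_set <- function(factor, intervals, merge = TRUE) {
  stopifnot(is.character(factor), length(factor) == 1L, nzchar(factor))
  gr <- if (methods::is(intervals, "GRanges")) intervals else {
    if (nrow(intervals) > 0 && any(intervals$start >= intervals$end))
      stop("invalid interval(s): start >= end")
    if (nrow(intervals) > 0 && any(intervals$start < 0))
      stop("invalid interval(s): start < 0")
    df_to_gr(intervals)
  }
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr), ignore.strand = TRUE)
  n_in <- length(gr)
  if (merge && n_in > 0) {
    merged <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
    if (length(merged) < n_in)
      message(factor, ": merged away ", n_in - length(merged), " overlapping record(s)")
    gr <- merged
  }
  if (length(gr) > 0 && is.null(S4Vectors::mcols(gr)$name))
    S4Vectors::mcols(gr)$name <- sprintf("%s_%05d", factor, seq_along(gr))
  structure(list(factor = factor, ranges = gr), class = "PeakSet")
}

#' @export
length.PeakSet <- function(x) length(x$ranges)

#' @export
print.PeakSet <- function(x, ...) {
  cat("PeakSet <", x$factor, ">: ", length(x), " intervals on ",
      length(unique(as.character(GenomicRanges::seqnames(x$ranges)))),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.PeakSet <- function(x, ...) gr_to_df(x$ranges)

#' Read peak calls from a BED file
#'
#' Accepts BED3+ (whitespace- or tab-delimited); `track`, `browser` and
#' `#` comment lines are skipped. Malformed lines (fewer than 3 fields,
#' non-integer coordinates, start >= end, negative start) raise an error
#' naming the offending line number. Overlapping same-factor records are
#' merged at load (count reported via `message`).
#'
#' @param path BED file path.
#' @param factor factor label to attach.
#' @param merge merge overlapping records (default TRUE).
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, factor, merge = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !grepl("^(track|browser|#)", lines)
  if (!any(keep)) {
    warning("no BED records in ", path, "; returning empty PeakSet")
    return(peak_set(factor, data.frame(chrom = character(), start = integer(),
                                       end = integer())))
  }
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", lineno[which(nf < 3)[1]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("line ", lineno[bad[1]], ": non-integer coordinates")
  bad <- which(start < 0)
  if (length(bad)) stop("line ", lineno[bad[1]], ": negative start")
  bad <- which(start >= end)
  if (length(bad)) stop("line ", lineno[bad[1]], ": start >= end")
  df <- data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
  if (any(nf >= 4)) df$name <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, character(1))
  if (any(nf >= 5)) df$score <- suppressWarnings(as.numeric(vapply(fields, function(f) if (length(f) >= 5) f[5] else NA_character_, character(1))))
  if (any(nf >= 6)) df$strand <- vapply(fields, function(f) if (length(f) >= 6) f[6] else "*", character(1))
  peak_set(factor, df, merge = merge)
}

#' Read a scored BED file of histone-mark regions
#'
#' Like [read_peaks()] but keeps scores (column 5; defaults to 1 when
#' absent) and does not merge, since mark signal is summed over a
#' promoter window downstream.
#'
#' @param path scored BED path.
#' @return data.frame with chrom, start, end, score.
#' @export
read_scored_bed <- function(path) {
  ps <- read_peaks(path, factor = "mark", merge = FALSE)
  df <- as.data.frame(ps)
  if (is.null(df$score) || all(is.na(df$score))) df$score <- 1
  df$score[is.na(df$score)] <- 1
  df[, c("chrom", "start", "end", "score")]
}

#' Write intervals to a BED file
#'
#' Tab-separated BED output; `read_peaks(write_bed(x))` reproduces the
#' coordinates and chromosome names exactly.
#'
#' @param records a `PeakSet`, GRanges or data.frame with chrom/start/end
#'   (0-based half-open) and optional name, score, strand columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  df <- if (inherits(records, "PeakSet")) as.data.frame(records)
        else if (methods::is(records, "GRanges")) gr_to_df(records)
        else as.data.frame(records)
  cols <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% names(df)) cols <- c(cols, extra) else break
  }
  df <- df[, cols, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df) > 0)
    writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
  invisible(path)
}

#' Merge peak sets into union regions annotated with bound factors
#'
#' Computes the maximal regions covered by at least one peak from any
#' factor (the unit of pattern counting), then annotates each region with
#' every factor having at least `min_overlap` bp of peak intersection
#' with it. Regions partition the union of all input peaks.
#'
#' @param peaksets list of [peak_set()] objects.
#' @param min_overlap minimum bp of factor-peak overlap with the union
#'   region for the factor to count as bound there (default 1, i.e. any
#'   overlap).
#' @return GRanges of union regions with metadata column `factors`, a
#'   CharacterList of bound factor labels per region.
#' @export
merge_union <- function(peaksets, min_overlap = 1L) {
  stopifnot(length(peaksets) >= 1, min_overlap >= 1)
  all_gr <- do.call(c, lapply(peaksets, function(ps) {
    gr <- ps$ranges
    S4Vectors::mcols(gr) <- NULL
    GenomicRanges::strand(gr) <- "*"
    gr
  }))
  regions <- GenomicRanges::reduce(all_gr, ignore.strand = TRUE)
  fac <- vector("list", length(regions))
  for (i in seq_len(length(regions))) fac[[i]] <- character(0)
  for (ps in peaksets) {
    hits <- GenomicRanges::findOverlaps(ps$ranges, regions,
                                        minoverlap = min_overlap,
                                        ignore.strand = TRUE)
    for (j in unique(S4Vectors::subjectHits(hits)))
      fac[[j]] <- c(fac[[j]], ps$factor)
  }
  S4Vectors::mcols(regions)$factors <- IRanges::CharacterList(fac)
  regions
}
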