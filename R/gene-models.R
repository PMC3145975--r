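#' Construct a gene-model table
#'
#' Gene models are the minimal records the annotation stages need: one
#' span per gene with strand, from which the TSS, TES and a strand-aware
#' promoter window are derived.
#'
#' @param df data.frame with columns gene_id, chrom, start, end (0-based
#'   half-open gene span) and strand ("+"/"-").
#' @return data.frame of class `gene_models` with added `tss` and `tes`
#'   columns (0-based positions of the first/last transcribed base).
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) stop("gene models need columns: ", paste(need, collapse = ", "))
  stopifnot(all(df$start < df$end), all(df$strand %in% c("+", "-")),
            !anyDuplicated(df$gene_id))
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tes <- ifelse(df$strand == "+", df$end - 1L, df$start)
  df <- df[order(df$chrom, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

genes_gr <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start + 1L, genes$end),
                         strand = genes$strand, gene_id = genes$gene_id)
}

#' Strand-aware promoter windows
#'
#' The promoter is the window from `upstream` bp 5' of the TSS to
#' `downstream` bp 3' of it (default -1000/+500, a common convention;
#' configurable because published analyses rarely state theirs).
#'
#' @param genes a [gene_models()] table.
#' @param upstream,downstream window extent in bp around the TSS.
#' @return GRanges of promoter windows with `gene_id` metadata, clamped
#'   at position 0.
#' @export
promoter_windows <- function(genes, upstream = 1000L, downstream = 500L) {
  gr <- genes_gr(genes)
  pw <- suppressWarnings(GenomicRanges::promoters(gr, upstream = upstream,
                                                  downstream = downstream))
  GenomicRanges::start(pw) <- pmax(GenomicRanges::start(pw), 1L)
  pw
}

#' Read gene models from GTF or BED12
#'
#' GTF input (records with a `gene_id` attribute; `gene` features
#' preferred, otherwise the per-gene envelope of all features) or BED12
#' (name column as gene id). GTF's 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention on read.
#'
#' @param path file path.
#' @param format "gtf" or "bed12"; guessed from the extension by default.
#' @return a [gene_models()] table.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed12"
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    if ("type" %in% colnames(S4Vectors::mcols(gr)) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    df <- data.frame(gene_id = gr$gene_id,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
    if (anyDuplicated(df$gene_id)) {   # envelope per gene_id
      sp <- split(df, df$gene_id)
      df <- do.call(rbind, lapply(sp, function(g)
        data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
                   start = min(g$start), end = max(g$end), strand = g$strand[1])))
    }
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    df <- data.frame(gene_id = gr$name,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  }
  gene_models(df)
}

#' Write gene models as GTF and BED12
#'
#' @param genes a [gene_models()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(genes, path) {
  lines <- sprintf('%s\tcombind\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   genes$chrom, genes$start + 1L, genes$end, genes$strand,
                   genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gene_models_gtf
#' @export
write_gene_models_bed12 <- function(genes, path) {
  w <- genes$end - genes$start
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
                   genes$chrom, genes$start, genes$end, genes$gene_id,
                   genes$strand, genes$start, genes$end, w)
  writeLines(lines, path)
  invisible(path)
}
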