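as_region_gr <- function(regions) {
  gr <- if (inherits(regions, "OccupancyRegions")) regions$regions
        else if (methods::is(regions, "GRanges")) regions
        else df_to_gr(regions)
  if (is.null(S4Vectors::mcols(gr)$name))
    S4Vectors::mcols(gr)$name <- sprintf("R%06d", seq_along(gr))
  gr
}

#' Classify regions as promoter, intragenic or intergenic
#'
#' A region overlapping any promoter window is `promoter`; otherwise a
#' region overlapping any gene body (TSS to TES, introns and exons
#' alike) is `intragenic`; anything else is `intergenic`. Precedence is
#' promoter > intragenic, so the three categories partition the regions.
#'
#' @param regions an [assign_patterns()] result, GRanges, or data.frame
#'   with chrom/start/end (0-based half-open).
#' @param genes a [gene_models()] table.
#' @param upstream,downstream promoter window around the TSS (bp).
#' @return character vector of categories, one per region.
#' @export
classify_location <- function(regions, genes, upstream = 1000L, downstream = 500L) {
  gr <- as_region_gr(regions)
  pw <- promoter_windows(genes, upstream, downstream)
  gb <- genes_gr(genes)
  cat <- rep("intergenic", length(gr))
  cat[S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, gb, ignore.strand = TRUE))] <- "intragenic"
  cat[S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, pw, ignore.strand = TRUE))] <- "promoter"
  cat
}

#' Map regions to candidate target genes
#'
#' The allocation rule: regions in promoters or gene bodies are
#' allocated to that gene (all overlapped genes when several), and the
#' remaining (intergenic) regions to the nearest gene on each side by
#' TSS distance, each only if within `max_distance` bp (default 100 kb);
#' an intergenic region far from all TSSs gets no gene. Distances are
#' measured from the nearest region edge to the TSS; ties within a side
#' break toward the alphabetically first gene id.
#'
#' @inheritParams classify_location
#' @param max_distance cap on intergenic region-to-TSS distance (bp).
#' @return data.frame with region_id, gene_id, category, distance (0 for
#'   promoter/intragenic assignments). Regions with no assigned gene are
#'   absent; use [classify_location()] for the full partition.
#' @export
map_region_to_genes <- function(regions, genes, upstream = 1000L,
                                downstream = 500L, max_distance = 100000L) {
  gr <- as_region_gr(regions)
  ids <- S4Vectors::mcols(gr)$name
  pw <- promoter_windows(genes, upstream, downstream)
  gb <- genes_gr(genes)

  prom_hits <- GenomicRanges::findOverlaps(gr, pw, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(prom_hits)
  res <- list(data.frame(region_id = ids[qh],
                         gene_id = genes$gene_id[S4Vectors::subjectHits(prom_hits)],
                         category = rep("promoter", length(qh)),
                         distance = rep(0L, length(qh)),
                         stringsAsFactors = FALSE))

  is_prom <- seq_along(gr) %in% qh
  body_hits <- GenomicRanges::findOverlaps(gr, gb, ignore.strand = TRUE)
  keep <- !is_prom[S4Vectors::queryHits(body_hits)]
  nb <- sum(keep)
  res[[2]] <- data.frame(region_id = ids[S4Vectors::queryHits(body_hits)][keep],
                         gene_id = genes$gene_id[S4Vectors::subjectHits(body_hits)][keep],
                         category = rep("intragenic", nb),
                         distance = rep(0L, nb),
                         stringsAsFactors = FALSE)

  is_genic <- is_prom | seq_along(gr) %in% S4Vectors::queryHits(body_hits)
  inter_idx <- which(!is_genic)
  if (length(inter_idx)) {
    rchrom <- as.character(GenomicRanges::seqnames(gr))[inter_idx]
    rstart <- GenomicRanges::start(gr)[inter_idx] - 1L   # back to 0-based
    rlast <- GenomicRanges::end(gr)[inter_idx] - 1L      # last covered base
    by_chrom <- split(seq_along(inter_idx), rchrom)
    inter_rows <- vector("list", length(inter_idx) * 2L)
    nrow_used <- 0L
    for (ch in names(by_chrom)) {
      gsel <- genes$chrom == ch
      if (!any(gsel)) next
      tss <- genes$tss[gsel]
      gid <- genes$gene_id[gsel]
      for (jj in by_chrom[[ch]]) {
        left <- tss < rstart[jj]
        right <- tss > rlast[jj]
        for (side in list(left, right)) {
          if (!any(side)) next
          d <- pmax(rstart[jj] - tss[side], tss[side] - rlast[jj])
          o <- order(d, gid[side])
          if (d[o[1]] <= max_distance) {
            nrow_used <- nrow_used + 1L
            inter_rows[[nrow_used]] <- data.frame(
              region_id = ids[inter_idx[jj]], gene_id = gid[side][o[1]],
              category = "intergenic", distance = d[o[1]],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (nrow_used) res[[3]] <- do.call(rbind, inter_rows[seq_len(nrow_used)])
  }
  out <- do.call(rbind, res)
  out <- unique(out)
  out <- out[order(out$region_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-pattern target gene lists
#'
#' Maps every union region to its candidate genes and unions the genes
#' per exact occupancy pattern, yielding up to `2^K - 1` target gene
#' lists (31 for five factors). A gene may appear in several lists.
#'
#' @param occ an [assign_patterns()] result.
#' @inheritParams map_region_to_genes
#' @return data.frame of class `TargetGeneLists` with columns pattern,
#'   label, gene_id (unique pairs); attribute `factor_order`.
#' @export
build_target_gene_lists <- function(occ, genes, upstream = 1000L,
                                    downstream = 500L, max_distance = 100000L) {
  stopifnot(inherits(occ, "OccupancyRegions"))
  gr <- as_region_gr(occ)
  asg <- map_region_to_genes(gr, genes, upstream, downstream, max_distance)
  pat <- S4Vectors::mcols(gr)$pattern
  names(pat) <- S4Vectors::mcols(gr)$name
  out <- unique(data.frame(pattern = pat[asg$region_id],
                           gene_id = asg$gene_id,
                           stringsAsFactors = FALSE))
  out$label <- pattern_label(out$pattern, occ$factor_order)
  out <- out[order(out$pattern, out$gene_id), c("pattern", "label", "gene_id")]
  rownames(out) <- NULL
  attr(out, "factor_order") <- occ$factor_order
  class(out) <- c("TargetGeneLists", "data.frame")
  out
}

#' Extract one pattern's gene list
#'
#' @param lists a [build_target_gene_lists()] result.
#' @param pattern factor subset (labels, "+"-joined string or bitmask).
#' @return character vector of gene ids (possibly empty).
#' @export
target_list <- function(lists, pattern) {
  mask <- if (is.numeric(pattern)) as.integer(pattern)
          else pattern_mask(pattern, attr(lists, "factor_order"))
  lists$gene_id[lists$pattern == mask]
}

#' Write target gene lists as one TSV (pattern label, gene)
#'
#' @param lists a [build_target_gene_lists()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_gene_lists <- function(lists, path) {
  utils::write.table(lists[, c("label", "gene_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
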