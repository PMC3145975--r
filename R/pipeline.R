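#' Assemble a pipeline configuration
#'
#' Either `synthetic` (a [landscape_config()]) or `inputs` (paths to
#' real files) must be present. Inputs are per-factor peak BEDs, gene
#' models (GTF/BED12), optional scored mark BEDs (k4, k27, h3ac), an
#' optional expression TSV (first column gene ids) and an optional
#' region FASTA.
#'
#' @param synthetic a [landscape_config()], or NULL.
#' @param inputs named list: `peaks` (named factor -> path), `genes`,
#'   optionally `k4`, `k27`, `h3ac`, `expression`, `sequences`.
#' @param universe_N bindable-region universe for the null (default
#'   80,000; a synthetic config's own universe takes precedence).
#' @param target_cell expression column for the ranking stage.
#' @param upstream,downstream promoter window (bp).
#' @param max_distance intergenic assignment cap (bp, default 100 kb).
#' @param permutations GSEA permutations.
#' @param seed mandatory integer seed.
#' @param outdir output directory.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL,
                            universe_N = 80000, target_cell = "MK",
                            upstream = 1000L, downstream = 500L,
                            max_distance = 100000L, permutations = 1000L,
                            seed, outdir) {
  if (is.null(synthetic) && is.null(inputs))
    stop("either synthetic config or real inputs required")
  if (missing(seed)) stop("seed is mandatory")
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "LandscapeConfig"))
    universe_N <- synthetic$universe_N
    target_cell <- synthetic$target_cell
  }
  structure(list(synthetic = synthetic, inputs = inputs,
                 universe_N = universe_N, target_cell = target_cell,
                 upstream = upstream, downstream = downstream,
                 max_distance = max_distance, permutations = permutations,
                 seed = as.integer(seed), outdir = outdir),
            class = "PipelineConfig")
}

#' Validate pipeline inputs
#'
#' Checks file existence, format plausibility (first data line of each
#' BED) and chromosome-name concordance between peaks and gene models.
#' Warnings and errors are distinguished by level.
#'
#' @param config a [pipeline_config()].
#' @return data.frame with columns level ("error"/"warning") and
#'   message; zero rows when everything is concordant.
#' @export
validate_inputs <- function(config) {
  issues <- list()
  add <- function(level, msg)
    issues[[length(issues) + 1L]] <<- data.frame(level = level, message = msg,
                                                 stringsAsFactors = FALSE)
  if (is.null(config$inputs)) {
    if (is.null(config$synthetic)) add("error", "no inputs and no synthetic config")
    return(if (length(issues)) do.call(rbind, issues)
           else data.frame(level = character(), message = character()))
  }
  ins <- config$inputs
  paths <- c(unlist(ins$peaks), ins$genes, ins$k4, ins$k27, ins$h3ac,
             ins$expression, ins$sequences)
  for (p in paths) if (!file.exists(p)) add("error", paste("missing file:", p))
  if (!any(vapply(issues, function(x) x$level == "error", logical(1)) %||% FALSE)) {
    gene_chroms <- tryCatch(unique(read_gene_models(ins$genes)$chrom),
                            error = function(e) {
                              add("error", paste("gene models unreadable:", conditionMessage(e)))
                              character(0)
                            })
    for (f in names(ins$peaks)) {
      ps <- tryCatch(suppressWarnings(suppressMessages(read_peaks(ins$peaks[[f]], f))),
                     error = function(e) {
                       add("error", paste0(f, " peaks: ", conditionMessage(e)))
                       NULL
                     })
      if (!is.null(ps) && length(ps) > 0 && length(gene_chroms)) {
        pk_chroms <- unique(as.character(GenomicRanges::seqnames(ps$ranges)))
        orphan <- setdiff(pk_chroms, gene_chroms)
        if (length(orphan))
          add("warning", paste0(f, ": ", length(orphan),
                                " chromosome(s) absent from gene models: ",
                                paste(orphan, collapse = ",")))
      }
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(level = character(), message = character())
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Run the full co-occupancy pipeline
#'
#' Stages: load or simulate inputs; union regions and exact occupancy
#' patterns; independence-null Z-scores; peak-to-gene annotation and
#' the per-pattern target gene lists; promoter chromatin states, bound
#' fractions and expression by state (when marks are available); GSEA
#' of the target lists against the target cell type (when expression is
#' available, otherwise skipped with a notice); motif enrichment in the
#' exact GATA1+SCL subset (when sequences with pattern labels are
#' available); and the network model with SIF/GraphML/DOT exports. All
#' tables are written under `outdir`; identical config and seed give an
#' identical bundle.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with every stage's in-memory result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  log_lines <- c(sprintf("combind %s", as.character(utils::packageVersion("combind"))),
                 sprintf("seed: %d", config$seed))

  if (!is.null(config$synthetic)) {
    land <- generate_landscape(config$synthetic)
    peaksets <- land$peaksets
    genes <- land$genes
    marks <- land[c("k4", "k27", "h3ac")]
    expression <- land$expression
    sequences <- land$sequences
    seq_patterns <- stats::setNames(land$truth$pattern[land$truth$pattern != 0L],
                                    land$truth$site_id[land$truth$pattern != 0L])
  } else {
    issues <- validate_inputs(config)
    if (any(issues$level == "error"))
      stop("input validation failed:\n",
           paste(issues$message[issues$level == "error"], collapse = "\n"))
    ins <- config$inputs
    peaksets <- lapply(names(ins$peaks), function(f) read_peaks(ins$peaks[[f]], f))
    genes <- read_gene_models(ins$genes)
    marks <- list(k4 = if (!is.null(ins$k4)) read_scored_bed(ins$k4),
                  k27 = if (!is.null(ins$k27)) read_scored_bed(ins$k27),
                  h3ac = if (!is.null(ins$h3ac)) read_scored_bed(ins$h3ac))
    expression <- if (!is.null(ins$expression)) {
      df <- utils::read.delim(ins$expression, check.names = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE]); rownames(m) <- df[[1]]; m
    }
    sequences <- if (!is.null(ins$sequences)) Biostrings::readDNAStringSet(ins$sequences)
    seq_patterns <- NULL
  }

  cfg_json <- jsonlite::toJSON(list(universe_N = config$universe_N,
                                    seed = config$seed,
                                    upstream = config$upstream,
                                    downstream = config$downstream,
                                    max_distance = config$max_distance,
                                    permutations = config$permutations,
                                    synthetic_seed = config$synthetic$seed %||% NA),
                               auto_unbox = TRUE)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  log_lines <- c(log_lines, sprintf("config_md5: %s", cfg_hash))

  out <- list(config = config)
  op <- function(name) file.path(config$outdir, name)

  occ <- assign_patterns(peaksets)
  tab <- count_exact_patterns(occ)
  write_pattern_table(tab, op("pattern_counts.tsv"))
  write_pattern_table(tab, op("pattern_counts.json"))
  out$occupancy <- occ; out$pattern_table <- tab

  model <- null_model_from_table(tab, universe_N = config$universe_N)
  zs <- pattern_zscores(tab, model)
  write_zscore_report(zs, op("pattern_zscores.tsv"))
  out$null_model <- model; out$zscores <- zs

  loc <- classify_location(occ, genes, config$upstream, config$downstream)
  rid <- S4Vectors::mcols(as_region_gr(occ))$name
  utils::write.table(data.frame(region_id = rid, category = loc),
                     op("region_locations.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  asg <- map_region_to_genes(occ, genes, config$upstream, config$downstream,
                             config$max_distance)
  utils::write.table(asg, op("region_gene_assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lists <- build_target_gene_lists(occ, genes, config$upstream,
                                   config$downstream, config$max_distance)
  write_target_gene_lists(lists, op("target_gene_lists.tsv"))
  out$locations <- loc; out$assignments <- asg; out$target_lists <- lists

  if (!is.null(marks$k4) && !is.null(marks$k27)) {
    states <- classify_promoters(genes, marks$k4, marks$k27, marks$h3ac,
                                 upstream = config$upstream,
                                 downstream = config$downstream)
    utils::write.table(states, op("promoter_states.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bf <- bound_fraction_by_state(states, occ, genes, config$upstream,
                                  config$downstream)
    utils::write.table(bf, op("bound_fraction_by_state.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$states <- states; out$bound_fractions <- bf
    if (!is.null(expression)) {
      es <- expression_by_state(states, expression, config$target_cell)
      utils::write.table(es, op("expression_by_state.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      out$expression_by_state <- es
    }
  } else log_lines <- c(log_lines, "notice: chromatin stage skipped (no marks)")

  gsea <- NULL
  if (!is.null(expression)) {
    ranked <- rank_genes(expression, config$target_cell)
    gsea <- gsea_significance(ranked, lists, permutations = config$permutations,
                              seed = config$seed)
    write_gsea_report(gsea, op("gsea_results.tsv"))
    out$ranked <- ranked; out$gsea <- gsea
  } else log_lines <- c(log_lines, "notice: GSEA stage skipped (no expression)")

  if (!is.null(sequences) && !is.null(seq_patterns) &&
      all(c("GATA1", "SCL") %in% occ$factor_order)) {
    pair_mask <- pattern_mask(c("GATA1", "SCL"), occ$factor_order)
    tgt <- sequences[names(sequences) %in% names(seq_patterns)[seq_patterns == pair_mask]]
    bgr <- sequences[names(sequences) %in% names(seq_patterns)[seq_patterns != pair_mask]]
    if (length(tgt) > 0 && length(bgr) > 0) {
      mr <- motif_report(tgt, bgr)
      utils::write.table(mr, op("motif_enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      out$motifs <- mr
    }
  } else if (!is.null(sequences))
    log_lines <- c(log_lines, "notice: motif stage skipped (no pattern labels for sequences)")

  sig <- if (!is.null(gsea)) gsea$set[gsea$fdr_q < 0.25 & gsea$nes > 0]
         else utils::head(zs$label[zs$zscore > 0], 6)
  sig <- intersect(sig, unique(lists$label))
  if (length(sig)) {
    net <- suppressWarnings(build_network(sig, lists))
    export_network(net, op("network.sif"), "sif")
    export_network(net, op("network.graphml"), "graphml")
    export_network(net, op("network.dot"), "dot")
    write_network_summary(net, op("network_summary.json"))
    out$network <- net
  } else log_lines <- c(log_lines, "notice: no significant patterns; network stage skipped")

  writeLines(log_lines, op("run_log.txt"))
  invisible(out)
}
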