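#' Build the core-circuit / pattern / effector-gene network
#'
#' Nodes are typed TF, pattern and gene; directed edges are TF->pattern
#' membership (one per bit of the pattern's bitmask), pattern->gene
#' targeting (deduplicated per pattern-gene pair) and TF->TF core-circuit
#' links including self-loops. Core edges are supplied as configuration:
#' the densely connected, autoregulatory core circuit is established
#' connectivity, not something re-inferred here (self-binding detection
#' from the occupancy data is available separately as a check, see
#' [detect_self_binding()]).
#'
#' @param significant_patterns pattern labels or bitmasks (subset of the
#'   nonempty patterns) to include as nodes.
#' @param target_gene_lists a [build_target_gene_lists()] result.
#' @param core_edges data.frame with columns `from`, `to` of TF labels
#'   (default: complete digraph over the factors incl. self-loops).
#' @param factor_order the ordered factor labels (default taken from
#'   `target_gene_lists`).
#' @return object of class `NetworkModel`: list with `nodes`
#'   (data.frame id, type) and `edges` (data.frame from, to, type).
#'   Patterns with empty gene lists are omitted with a warning.
#' @export
build_network <- function(significant_patterns, target_gene_lists,
                          core_edges = NULL, factor_order = NULL) {
  if (is.null(factor_order)) factor_order <- attr(target_gene_lists, "factor_order")
  stopifnot(!is.null(factor_order))
  masks <- vapply(significant_patterns, function(p)
    if (is.numeric(p)) as.integer(p) else pattern_mask(p, factor_order), integer(1))
  if (any(masks <= 0 | masks >= 2^length(factor_order)))
    stop("pattern outside the nonempty patterns over the factor list")
  if (is.null(core_edges))
    core_edges <- expand.grid(from = factor_order, to = factor_order,
                              stringsAsFactors = FALSE)
  edges <- list(data.frame(from = core_edges$from, to = core_edges$to,
                           type = "core", stringsAsFactors = FALSE))
  pat_nodes <- character(0)
  gene_nodes <- character(0)
  for (m in masks) {
    lab <- pattern_label(m, factor_order)
    genes <- unique(target_gene_lists$gene_id[target_gene_lists$pattern == m])
    if (length(genes) == 0) {
      warning("pattern ", lab, " has an empty gene list; node omitted")
      next
    }
    pat_nodes <- c(pat_nodes, lab)
    tfs <- factor_order[has_bit(m, seq_along(factor_order))]
    edges[[length(edges) + 1L]] <- data.frame(from = tfs, to = lab,
                                              type = "membership",
                                              stringsAsFactors = FALSE)
    edges[[length(edges) + 1L]] <- data.frame(from = lab, to = genes,
                                              type = "targeting",
                                              stringsAsFactors = FALSE)
    gene_nodes <- union(gene_nodes, genes)
  }
  nodes <- rbind(data.frame(id = factor_order, type = "TF", stringsAsFactors = FALSE),
                 if (length(pat_nodes)) data.frame(id = pat_nodes, type = "pattern"),
                 if (length(gene_nodes)) data.frame(id = sort(gene_nodes), type = "gene"))
  model <- structure(list(nodes = nodes, edges = unique(do.call(rbind, edges))),
                     class = "NetworkModel")
  model
}

#' @export
print.NetworkModel <- function(x, ...) {
  cat("NetworkModel: ", nrow(x$nodes), " nodes (",
      paste(table(x$nodes$type), names(table(x$nodes$type)), collapse = ", "),
      "), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Per-gene pattern-degree distribution
#'
#' How many pattern nodes target each gene; in the published network
#' most effector genes hang off a single pattern node.
#'
#' @param model a [build_network()] result.
#' @return list: `degrees` (named integer per gene) and
#'   `fraction_single` (genes with pattern-degree 1).
#' @export
pattern_degree <- function(model) {
  targ <- model$edges[model$edges$type == "targeting", , drop = FALSE]
  deg <- table(targ$to)
  list(degrees = stats::setNames(as.integer(deg), names(deg)),
       fraction_single = if (length(deg)) mean(deg == 1) else NA_real_)
}

#' Count self-binding transcription factors in the occupancy data
#'
#' Optional check of the core circuit's autoregulatory loops: a TF
#' self-binds when one of its own peaks lies in the promoter or body of
#' its gene.
#'
#' @param occ an [assign_patterns()] result.
#' @param genes a [gene_models()] table whose gene ids include the
#'   factor labels.
#' @inheritParams classify_location
#' @return named logical vector per factor.
#' @export
detect_self_binding <- function(occ, genes, upstream = 1000L, downstream = 500L) {
  gr <- as_region_gr(occ)
  asg <- map_region_to_genes(gr, genes, upstream, downstream)
  asg <- asg[asg$category != "intergenic", , drop = FALSE]
  pat <- stats::setNames(S4Vectors::mcols(gr)$pattern,
                         S4Vectors::mcols(gr)$name)
  out <- stats::setNames(logical(length(occ$factor_order)), occ$factor_order)
  for (i in seq_along(occ$factor_order)) {
    f <- occ$factor_order[i]
    rids <- asg$region_id[asg$gene_id == f]
    out[f] <- any(has_bit(pat[rids], i))
  }
  out
}

#' Export / import a network model
#'
#' SIF (`from<TAB>edge-type<TAB>to`), GraphML (with node `type` and edge
#' `type` attributes) and DOT writers; SIF and GraphML re-import
#' reproduces the node and edge multisets exactly (SIF alone cannot
#' carry isolated nodes' types, so orphan-free models round-trip).
#'
#' @param model a [build_network()] result.
#' @param path output file.
#' @param format one of "sif", "graphml", "dot".
#' @return `path`, invisibly.
#' @export
export_network <- function(model, path, format = c("sif", "graphml", "dot")) {
  format <- match.arg(format)
  e <- model$edges
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", e$from, e$type, e$to), path)
  } else if (format == "dot") {
    lines <- c("digraph network {",
               sprintf('  "%s" [type="%s"];', model$nodes$id, model$nodes$type),
               sprintf('  "%s" -> "%s" [type="%s"];', e$from, e$to, e$type),
               "}")
    writeLines(lines, path)
  } else {
    doc <- xml2::xml_new_root("graphml",
      xmlns = "http://graphml.graphdrawing.org/xmlns")
    k1 <- xml2::xml_add_child(doc, "key", id = "d0", `for` = "node",
                              attr.name = "type", attr.type = "string")
    k2 <- xml2::xml_add_child(doc, "key", id = "d1", `for` = "edge",
                              attr.name = "type", attr.type = "string")
    g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
    for (i in seq_len(nrow(model$nodes))) {
      nd <- xml2::xml_add_child(g, "node", id = model$nodes$id[i])
      xml2::xml_set_text(xml2::xml_add_child(nd, "data", key = "d0"),
                         model$nodes$type[i])
    }
    for (i in seq_len(nrow(e))) {
      ed <- xml2::xml_add_child(g, "edge", source = e$from[i], target = e$to[i])
      xml2::xml_set_text(xml2::xml_add_child(ed, "data", key = "d1"), e$type[i])
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t")
    edges <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                        to = vapply(parts, `[`, character(1), 3L),
                        type = vapply(parts, `[`, character(1), 2L),
                        stringsAsFactors = FALSE)[, c("from", "to", "type")]
    ids <- unique(c(edges$from, edges$to))
    nodes <- data.frame(id = ids, type = NA_character_, stringsAsFactors = FALSE)
  } else {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    nd <- xml2::xml_find_all(doc, ".//node")
    nodes <- data.frame(id = xml2::xml_attr(nd, "id"),
                        type = xml2::xml_text(xml2::xml_find_first(nd, "./data")),
                        stringsAsFactors = FALSE)
    ed <- xml2::xml_find_all(doc, ".//edge")
    edges <- data.frame(from = xml2::xml_attr(ed, "source"),
                        to = xml2::xml_attr(ed, "target"),
                        type = xml2::xml_text(xml2::xml_find_first(ed, "./data")),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "NetworkModel")
}

#' Coverage of a ranked specific-gene list by the network
#'
#' How many of the top-k most cell-type-specific genes appear as gene
#' nodes of the model (the published model covered 67 of the top 200).
#'
#' @param model a [build_network()] result.
#' @param specific_genes character vector: the top-k ranked genes.
#' @return list: `count`, `k`, `fraction`.
#' @export
coverage_stat <- function(model, specific_genes) {
  in_model <- specific_genes %in% model$nodes$id[model$nodes$type == "gene"]
  list(count = sum(in_model), k = length(specific_genes),
       fraction = mean(in_model))
}

#' Degree summary of a network model as JSON
#'
#' @param model a [build_network()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_network_summary <- function(model, path) {
  pd <- pattern_degree(model)
  jsonlite::write_json(list(
    n_nodes = nrow(model$nodes),
    n_edges = nrow(model$edges),
    nodes_by_type = as.list(table(model$nodes$type)),
    edges_by_type = as.list(table(model$edges$type)),
    fraction_single_pattern_genes = pd$fraction_single),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
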