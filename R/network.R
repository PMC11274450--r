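## Regulatory-network construction from user differential-expression
## results: select DEGs, pull out the differentially expressed TFs known to
## the chosen evidence sources, predict their targets by multi-source
## support, restrict to DEGs, and export the directed TF-target graph.

#' Select differentially expressed genes from a DEG table
#'
#' @param deg A [deg_table()].
#' @param lfc_threshold Minimum `|log2fc|` (default 1).
#' @param p_threshold P-value ceiling, exclusive (default 0.05).
#' @return Sorted character vector of gene symbols with
#'   `|log2fc| >= lfc_threshold` and `pvalue < p_threshold`.
#' @export
filter_degs <- function(deg, lfc_threshold = 1, p_threshold = 0.05) {
  stopifnot(inherits(deg, "deg_table"))
  sort(deg$gene[abs(deg$log2fc) >= lfc_threshold &
                  deg$pvalue < p_threshold])
}

#' Differentially expressed TFs known to the evidence sources
#'
#' Intersects a DEG gene set with the union of TF symbols appearing as
#' regulators in at least one of the given sources.
#'
#' @param deg_genes Character vector of DEG symbols (from [filter_degs()]).
#' @param sources Named list of [source_table()] objects.
#' @return Sorted character vector of DE-TF symbols (possibly empty).
#' @export
extract_de_tfs <- function(deg_genes, sources) {
  tf_universe <- unique(unlist(lapply(sources, function(s) s$edges$tf),
                               use.names = FALSE))
  sort(intersect(normalize_symbols(deg_genes), tf_universe))
}

#' Build a TF-target regulatory network from DE-TFs and DEGs
#'
#' For every DE-TF, candidate targets are the genes supported by at least
#' `required_support` of the selected sources (knockdown sources filtered
#' by `|log2fc| >= knocktf_lfc_threshold` first); edges are kept only to
#' targets in `deg_genes`. Self-loops (a TF regulating itself) are retained
#' and flagged. TFs left without any edge are dropped from the graph but
#' listed in `isolated_tfs`.
#'
#' @param de_tfs Character vector of DE-TF symbols ([extract_de_tfs()]).
#' @param deg_genes Character vector of DEG symbols ([filter_degs()]).
#' @param sources Named list of [source_table()] objects.
#' @param required_support Integer in `[1, length(sources)]`, or `"all"`
#'   (default): number of sources that must support an edge.
#' @param deg Optional [deg_table()] supplying per-node `log2fc` and
#'   `pvalue` attributes.
#' @param knocktf_lfc_threshold `|log2fc|` filter for knockdown sources
#'   (default 0.5).
#' @param knocktf_down_only Keep only negative-log2fc knockdown edges
#'   (default `FALSE`).
#' @return Object of class `regulatory_network`: `nodes` (data frame
#'   `gene`, `role` in tf/target/both, `log2fc`, `pvalue`), `edges` (data
#'   frame `tf`, `target`, `n_support`, `sources`, `self_loop`), and
#'   `isolated_tfs`.
#' @export
build_network <- function(de_tfs, deg_genes, sources,
                          required_support = "all", deg = NULL,
                          knocktf_lfc_threshold = 0.5,
                          knocktf_down_only = FALSE) {
  if (identical(required_support, "all")) {
    required_support <- length(sources)
  }
  required_support <- as.integer(required_support)
  if (is.na(required_support) || required_support < 1 ||
      required_support > length(sources)) {
    abort_regulink(
      sprintf("required_support must lie in [1, %d]", length(sources)),
      "regulink_config_error"
    )
  }
  de_tfs <- sort(unique(normalize_symbols(de_tfs)))
  deg_genes <- unique(normalize_symbols(deg_genes))

  edge_rows <- list()
  isolated <- character(0)
  for (tf in de_tfs) {
    q <- prediction_query(tf, "targets_of_tf", sources = names(sources),
                          knocktf_lfc_threshold = knocktf_lfc_threshold,
                          knocktf_down_only = knocktf_down_only)
    per_source <- lapply(sources, function(s)
      suppressMessages(source_gene_set(s, q)))
    support <- table(unlist(per_source, use.names = FALSE))
    targets <- names(support)[support >= required_support]
    targets <- sort(intersect(targets, deg_genes))
    if (!length(targets)) {
      isolated <- c(isolated, tf)
      next
    }
    supp_sources <- vapply(targets, function(g) {
      paste(sort(names(per_source)[vapply(per_source, function(s)
        g %in% s, logical(1))]), collapse = ",")
    }, character(1))
    edge_rows[[tf]] <- data.frame(
      tf = tf, target = targets,
      n_support = as.integer(support[targets]),
      sources = unname(supp_sources),
      self_loop = targets == tf,
      stringsAsFactors = FALSE
    )
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(tf = character(), target = character(),
               n_support = integer(), sources = character(),
               self_loop = logical(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL

  node_genes <- sort(unique(c(edges$tf, edges$target)))
  role <- ifelse(node_genes %in% edges$tf & node_genes %in% edges$target,
                 "both",
                 ifelse(node_genes %in% edges$tf, "tf", "target"))
  nodes <- data.frame(gene = node_genes, role = as.character(role),
                      log2fc = rep(NA_real_, length(node_genes)),
                      pvalue = rep(NA_real_, length(node_genes)),
                      stringsAsFactors = FALSE)
  if (!is.null(deg)) {
    idx <- match(nodes$gene, deg$gene)
    nodes$log2fc <- deg$log2fc[idx]
    nodes$pvalue <- deg$pvalue[idx]
  }
  structure(list(nodes = nodes, edges = edges, isolated_tfs = isolated,
                 required_support = required_support),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d node(s), %d edge(s), support >= %d\n",
              nrow(x$nodes), nrow(x$edges), x$required_support))
  if (length(x$isolated_tfs)) {
    cat(sprintf("  TF(s) without surviving targets: %s\n",
                paste(x$isolated_tfs, collapse = ", ")))
  }
  invisible(x)
}

#' End-to-end network construction from a DEG table
#'
#' Runs [filter_degs()], [extract_de_tfs()] and [build_network()] with one
#' call.
#'
#' @param deg A [deg_table()].
#' @param sources Named list of [source_table()] objects.
#' @param lfc_threshold,p_threshold DEG selection thresholds (defaults 1
#'   and 0.05).
#' @param ... Passed to [build_network()].
#' @return A `regulatory_network`.
#' @export
deg_network <- function(deg, sources, lfc_threshold = 1,
                        p_threshold = 0.05, ...) {
  deg_genes <- filter_degs(deg, lfc_threshold, p_threshold)
  de_tfs <- extract_de_tfs(deg_genes, sources)
  build_network(de_tfs, deg_genes, sources, deg = deg, ...)
}

#' Convert a regulatory network to an igraph graph
#' @param net A `regulatory_network`.
#' @return An [igraph::igraph] directed graph with node attributes `role`,
#'   `log2fc`, `pvalue` and edge attributes `n_support`, `sources`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("tf", "target", "n_support", "sources")],
    directed = TRUE,
    vertices = net$nodes
  )
}

#' Export a regulatory network
#'
#' @param net A `regulatory_network`.
#' @param path Output path.
#' @param format `"tsv"` for a sorted edge list (columns `tf`, `target`,
#'   `n_support`, `sources`, `tf_log2fc`, `target_log2fc`) or `"graphml"`
#'   (attribute-preserving; see [read_network_graphml()]).
#' @return The path, invisibly. An empty network writes a header-only TSV
#'   with a warning.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "regulatory_network"))
  if (format == "tsv") {
    if (nrow(net$edges) == 0) {
      warning("exporting an empty network", call. = FALSE)
    }
    idx_tf <- match(net$edges$tf, net$nodes$gene)
    idx_tg <- match(net$edges$target, net$nodes$gene)
    out <- data.frame(tf = net$edges$tf, target = net$edges$target,
                      n_support = net$edges$n_support,
                      sources = net$edges$sources,
                      tf_log2fc = net$nodes$log2fc[idx_tf],
                      target_log2fc = net$nodes$log2fc[idx_tg],
                      stringsAsFactors = FALSE)
    out <- out[order(out$tf, out$target), , drop = FALSE]
    return(write_tsv(out, path))
  }
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a regulatory network from GraphML
#'
#' Inverse of `export_network(format = "graphml")`.
#'
#' @param path GraphML file written by [export_network()].
#' @return A `regulatory_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vs <- igraph::as_data_frame(g, what = "vertices")
  es <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(gene = vs$name, role = vs$role,
                      log2fc = as.numeric(vs$log2fc),
                      pvalue = as.numeric(vs$pvalue),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- data.frame(tf = es$from, target = es$to,
                      n_support = as.integer(es$n_support),
                      sources = es$sources,
                      self_loop = es$from == es$to,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, isolated_tfs = character(0),
                 required_support = if (nrow(edges)) min(edges$n_support) else 1L),
            class = "regulatory_network")
}

#' Plot a regulatory network
#'
#' Convenience force-directed drawing (TFs highlighted); the exported graph
#' is the analysis artifact, the picture is for inspection.
#'
#' @param x A `regulatory_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @return `x`, invisibly.
#' @export
plot.regulatory_network <- function(x, ...) {
  if (nrow(x$edges) == 0) {
    warning("empty network; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  g <- as_igraph(x)
  cols <- ifelse(igraph::V(g)$role == "target", "grey80", "tomato")
  igraph::plot.igraph(g, layout = igraph::layout_with_fr(g),
                      vertex.color = cols, vertex.size = 8,
                      vertex.label.cex = 0.7, edge.arrow.size = 0.3, ...)
  invisible(x)
}

#' TF differential-expression report
#'
#' The DEG-table rows of the differentially expressed TFs (the "TF results"
#' view of a network run).
#'
#' @param deg A [deg_table()].
#' @param sources Named list of [source_table()] objects.
#' @param lfc_threshold,p_threshold DEG thresholds.
#' @return Data frame of DEG rows restricted to DE-TFs.
#' @export
tf_deg_report <- function(deg, sources, lfc_threshold = 1,
                          p_threshold = 0.05) {
  de_tfs <- extract_de_tfs(filter_degs(deg, lfc_threshold, p_threshold),
                           sources)
  out <- as.data.frame(deg[deg$gene %in% de_tfs, , drop = FALSE])
  rownames(out) <- NULL
  out
}
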