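## Combined miRNA->gene / gene-gene regulatory network and hub detection.

#' Build the combined regulatory network
#'
#' Gene-gene interaction edges are filtered at `score_cutoff` on their
#' combined score and restricted to candidate target genes; only genes with
#' at least one surviving interaction edge are kept, together with the miRNAs
#' predicted to regulate them. Regulatory (miRNA->gene) and interaction
#' (gene-gene) edges are merged into one graph; parallel edges are collapsed.
#'
#' @param target_sets Named list (miRNA id -> character vector of target gene
#'   ids) or a data.frame with columns `mirna_id`, `gene_id`.
#' @param ppi data.frame with columns `gene_a`, `gene_b`, `combined_score`
#'   (scores in `[0, 1]`).
#' @param score_cutoff Minimum combined score kept (default 0.4).
#' @return A `regulatory_network` object: an igraph graph with vertex
#'   attribute `type` (`mirna`/`gene`) and edge attributes `type`
#'   (`regulatory`/`interaction`) and `combined_score`, plus the node table
#'   and edge table.
#' @export
build_network <- function(target_sets, ppi, score_cutoff = 0.4) {
  if (is.data.frame(target_sets)) {
    target_sets <- lapply(split(target_sets$gene_id, target_sets$mirna_id),
                          unique)
  }
  all_targets <- unique(unlist(target_sets))
  keep <- ppi$combined_score >= score_cutoff &
    ppi$gene_a %in% all_targets & ppi$gene_b %in% all_targets &
    ppi$gene_a != ppi$gene_b
  ppi <- ppi[keep, , drop = FALSE]
  # collapse parallel / reversed duplicates, keep the best score
  if (nrow(ppi)) {
    key <- ifelse(ppi$gene_a < ppi$gene_b,
                  paste(ppi$gene_a, ppi$gene_b),
                  paste(ppi$gene_b, ppi$gene_a))
    ord <- order(key, -ppi$combined_score)
    ppi <- ppi[ord, , drop = FALSE][!duplicated(sort(key)), , drop = FALSE]
    ab <- t(vapply(strsplit(sort(unique(key)), " "), identity, character(2)))
    ppi <- data.frame(gene_a = ab[, 1], gene_b = ab[, 2],
                      combined_score = ppi$combined_score,
                      stringsAsFactors = FALSE)
  }
  genes <- sort(unique(c(ppi$gene_a, ppi$gene_b)))
  reg <- do.call(rbind, lapply(names(target_sets), function(mi) {
    g <- intersect(unique(target_sets[[mi]]), genes)
    if (length(g)) data.frame(mirna_id = mi, gene_id = g,
                              stringsAsFactors = FALSE)
  }))
  if (is.null(reg)) reg <- data.frame(mirna_id = character(),
                                      gene_id = character())
  mirnas <- sort(unique(reg$mirna_id))

  nodes <- data.frame(
    id = c(mirnas, genes),
    type = c(rep("mirna", length(mirnas)), rep("gene", length(genes))),
    stringsAsFactors = FALSE
  )
  edges <- rbind(
    if (nrow(reg)) data.frame(from = reg$mirna_id, to = reg$gene_id,
                              type = "regulatory",
                              combined_score = NA_real_,
                              stringsAsFactors = FALSE),
    if (nrow(ppi)) data.frame(from = ppi$gene_a, to = ppi$gene_b,
                              type = "interaction",
                              combined_score = ppi$combined_score,
                              stringsAsFactors = FALSE)
  )
  if (is.null(edges)) edges <- data.frame(from = character(),
                                          to = character(),
                                          type = character(),
                                          combined_score = numeric())
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = nodes)
  structure(list(graph = graph, nodes = nodes, edges = edges,
                 score_cutoff = score_cutoff),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  n_g <- sum(x$nodes$type == "gene")
  n_m <- sum(x$nodes$type == "mirna")
  cat(sprintf(
    "Regulatory network: %d nodes (%d genes + %d miRNAs), %d edges (%d regulatory, %d interaction)\n",
    nrow(x$nodes), n_g, n_m, nrow(x$edges),
    sum(x$edges$type == "regulatory"), sum(x$edges$type == "interaction")))
  invisible(x)
}

#' Degrees of network nodes
#'
#' Total degree counts both regulatory and interaction edges;
#' `mode = "interaction"` counts interaction edges only.
#'
#' @param net A [build_network()] result.
#' @param mode `"total"` (default) or `"interaction"`.
#' @return Named numeric vector of degrees over all nodes.
#' @export
network_degrees <- function(net, mode = c("total", "interaction")) {
  mode <- match.arg(mode)
  g <- net$graph
  if (mode == "interaction") {
    g <- igraph::subgraph_from_edges(
      g, igraph::E(g)[igraph::E(g)$type == "interaction"],
      delete.vertices = FALSE)
  }
  igraph::degree(g)
}

#' Identify hub genes and hub miRNAs
#'
#' Hub genes are the `ceiling(fraction * number of gene nodes)` gene nodes
#' of highest degree (ties broken lexicographically by node id for
#' determinism); hub miRNAs are all miRNAs with a regulatory edge to at least
#' one hub gene.
#'
#' @param net A [build_network()] result.
#' @param fraction Top-degree fraction (default 0.05).
#' @param mode Degree mode, see [network_degrees()].
#' @return A list with `hub_genes`, `hub_mirnas` and the gene `degree` table.
#' @export
find_hubs <- function(net, fraction = 0.05, mode = "total") {
  stopifnot(inherits(net, "regulatory_network"), nrow(net$nodes) > 0)
  deg <- network_degrees(net, mode = mode)
  gene_ids <- net$nodes$id[net$nodes$type == "gene"]
  gdeg <- deg[gene_ids]
  n_hub <- ceiling(fraction * length(gene_ids))
  ord <- order(-gdeg, gene_ids)
  hub_genes <- gene_ids[ord][seq_len(n_hub)]
  reg <- net$edges[net$edges$type == "regulatory", , drop = FALSE]
  hub_mirnas <- sort(unique(reg$from[reg$to %in% hub_genes]))
  list(
    hub_genes = hub_genes,
    hub_mirnas = hub_mirnas,
    degree = data.frame(id = gene_ids[ord], degree = unname(gdeg[ord]),
                        is_hub = gene_ids[ord] %in% hub_genes,
                        stringsAsFactors = FALSE)
  )
}

#' Export / import a regulatory network
#'
#' Writes `<prefix>_edges.tsv`, `<prefix>_nodes.tsv` and `<prefix>.graphml`;
#' re-importing the TSV pair reproduces the graph exactly.
#'
#' @param net A [build_network()] result.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
export_network <- function(net, prefix) {
  stopifnot(inherits(net, "regulatory_network"))
  edge_path <- paste0(prefix, "_edges.tsv")
  node_path <- paste0(prefix, "_nodes.tsv")
  graphml_path <- paste0(prefix, ".graphml")
  deg <- if (nrow(net$nodes)) network_degrees(net) else numeric(0)
  nodes <- net$nodes
  nodes$degree <- if (nrow(nodes)) unname(deg[nodes$id]) else numeric(0)
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  igraph::write_graph(net$graph, graphml_path, format = "graphml")
  invisible(c(edges = edge_path, nodes = node_path, graphml = graphml_path))
}

#' @rdname export_network
#' @param prefix Path prefix used by [export_network()].
#' @export
import_network <- function(prefix) {
  edges <- utils::read.table(paste0(prefix, "_edges.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = c(from = "character",
                                            to = "character"))
  nodes <- utils::read.table(paste0(prefix, "_nodes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = c(id = "character"))
  graph <- igraph::graph_from_data_frame(
    edges, directed = FALSE, vertices = nodes[, c("id", "type")])
  structure(list(graph = graph, nodes = nodes[, c("id", "type")],
                 edges = edges, score_cutoff = NA_real_),
            class = "regulatory_network")
}
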