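# Regulatory-network assembly over DEGs, minimal-network pruning (every
# target regulated by >= 2 TFs), expression-direction overlay, and
# hypergeometric pathway over-representation.

#' Construct a regulatory network object
#'
#' @param nodes data.frame with columns `gene_id`, `is_tf`, `direction`
#'   (`up`/`down`/`NA`), `fold_change`.
#' @param edges data.frame with columns `tf`, `target`, `p_value` (plus any
#'   extra attributes such as `n_sites`).
#' @param minimal whether pruning has been applied.
#' @return An object of class `reg_network`.
#' @export
reg_network <- function(nodes, edges, minimal = FALSE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (anyDuplicated(nodes$gene_id)) stop("duplicate nodes")
  if (nrow(edges)) {
    if (anyDuplicated(edges[, c("tf", "target")]))
      stop("duplicate edges")
    bad <- !edges$tf %in% nodes$gene_id[nodes$is_tf]
    if (any(bad)) stop("edge source(s) not TF nodes: ",
                       paste(unique(edges$tf[bad]), collapse = ", "))
    if (!all(edges$target %in% nodes$gene_id))
      stop("edge target(s) missing from node table")
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, minimal = minimal),
            class = "reg_network")
}

empty_edges <- function() {
  data.frame(tf = character(0), target = character(0),
             p_value = numeric(0), stringsAsFactors = FALSE)
}

#' Assemble the regulatory network from predicted interactions
#'
#' Restricts the interaction set to pairs whose regulator and target are
#' both differentially expressed, and overlays each node's expression
#' direction and fold change from the DEG table. TF-TF edges are retained;
#' interactions touching a non-DEG gene are dropped and counted in the
#' `"log"` attribute.
#'
#' @param interactions an `interaction_set` (or data.frame with `tf`,
#'   `target`, `p_value`).
#' @param degs a `deg_set` or its `genes` data.frame.
#' @param tfs character vector of TF gene IDs.
#' @return A `reg_network` (not yet pruned).
#' @export
build_network <- function(interactions, degs, tfs) {
  if (inherits(degs, "deg_set")) degs <- degs$genes
  inter <- as.data.frame(interactions)
  keep <- inter$tf %in% degs$gene_id & inter$target %in% degs$gene_id
  dropped <- sum(!keep)
  inter <- inter[keep, , drop = FALSE]
  gene_ids <- sort(unique(c(inter$tf, inter$target)))
  idx <- match(gene_ids, degs$gene_id)
  nodes <- data.frame(gene_id = gene_ids,
                      is_tf = gene_ids %in% tfs,
                      direction = degs$direction[idx],
                      fold_change = degs$fold_change[idx],
                      stringsAsFactors = FALSE)
  net <- reg_network(nodes, inter, minimal = FALSE)
  attr(net, "log") <- log_line("build_network: ", nrow(inter), " edges (",
                               dropped, " non-DEG interactions dropped)")
  net
}

#' Prune a regulatory network to its minimal form
#'
#' Iterates to a fixed point: every non-TF target regulated by fewer than
#' two distinct TFs is removed together with its incoming edges, and TF
#' nodes left without any incident edge are removed; removals are repeated
#' until the network is stable. TF nodes are exempt from the in-degree rule.
#'
#' @param net a `reg_network`.
#' @return The minimal `reg_network` (`minimal = TRUE`).
#' @export
prune_minimal <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  nodes <- net$nodes; edges <- net$edges
  repeat {
    non_tf <- nodes$gene_id[!nodes$is_tf]
    indeg <- table(factor(edges$target, levels = non_tf))
    drop_targets <- names(indeg)[indeg < 2]
    edges2 <- edges[!edges$target %in% drop_targets, , drop = FALSE]
    nodes2 <- nodes[!nodes$gene_id %in% drop_targets, , drop = FALSE]
    # TF nodes survive only while they touch at least one remaining edge
    keep_node <- !nodes2$is_tf |
      nodes2$gene_id %in% c(edges2$tf, edges2$target)
    nodes2 <- nodes2[keep_node, , drop = FALSE]
    if (nrow(nodes2) == nrow(nodes) && nrow(edges2) == nrow(edges)) break
    nodes <- nodes2; edges <- edges2
  }
  reg_network(nodes, edges, minimal = TRUE)
}

#' Network size summary
#'
#' Nodes that are both TF and target count as TFs and are excluded from the
#' target count.
#'
#' @param net a `reg_network`.
#' @return Named list `n_tfs`, `n_targets`, `n_edges`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  list(n_tfs = sum(net$nodes$is_tf),
       n_targets = sum(!net$nodes$is_tf),
       n_edges = nrow(net$edges))
}

#' @export
print.reg_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("reg_network%s: %d TFs, %d targets, %d edges\n",
              if (x$minimal) " (minimal)" else "", s$n_tfs, s$n_targets,
              s$n_edges))
  invisible(x)
}

#' @export
summary.reg_network <- function(object, ...) {
  print(object)
  if (nrow(object$nodes)) {
    dirs <- table(factor(object$nodes$direction, c("up", "down")))
    cat(sprintf("  expression overlay: %d up, %d down\n",
                dirs[["up"]], dirs[["down"]]))
    outdeg <- table(object$edges$tf)
    if (length(outdeg))
      cat("  TF out-degrees:",
          paste(sprintf("%s=%d", names(outdeg), outdeg), collapse = " "),
          "\n")
  }
  invisible(network_summary(object))
}

#' Plot a regulatory network
#'
#' TFs as squares, targets as circles, node colour by expression direction
#' (up = red, down = green).
#'
#' @param x a `reg_network`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.reg_network <- function(x, ...) {
  g <- as_igraph(x)
  if (igraph::vcount(g) == 0) {
    graphics::plot.new(); graphics::title("empty network")
    return(invisible(x))
  }
  shape <- ifelse(igraph::V(g)$is_tf, "square", "circle")
  col <- ifelse(is.na(igraph::V(g)$direction), "grey80",
                ifelse(igraph::V(g)$direction == "up", "tomato",
                       "palegreen3"))
  plot(g, vertex.shape = shape, vertex.color = col, vertex.size = 12,
       edge.arrow.size = 0.4, ...)
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("tf", "target",
                  intersect("p_value", names(net$edges))), drop = FALSE],
    directed = TRUE, vertices = net$nodes)
  g
}

#' Hypergeometric pathway over-representation
#'
#' Upper-tail hypergeometric p-value of the overlap between the network
#' gene list and each pathway, within a stated gene universe, with
#' Benjamini-Hochberg adjusted q-values reported alongside.
#'
#' @param network_genes character vector of selected genes.
#' @param pathway_sets named list of pathway gene vectors.
#' @param universe character vector containing all candidate genes
#'   (a superset of `network_genes`; pathways are intersected with it).
#' @return data.frame with `pathway`, `n_pathway`, `n_overlap`, `p_value`,
#'   `q_value`.
#' @export
pathway_overrepresentation <- function(network_genes, pathway_sets,
                                       universe) {
  if (!length(universe)) stop("empty gene universe")
  universe <- unique(universe)
  if (!all(network_genes %in% universe))
    stop("network genes must be contained in the universe")
  sel <- unique(network_genes)
  rows <- lapply(names(pathway_sets), function(pw) {
    genes <- intersect(unique(pathway_sets[[pw]]), universe)
    k <- length(intersect(sel, genes))
    p <- stats::phyper(k - 1, length(genes),
                       length(universe) - length(genes),
                       length(sel), lower.tail = FALSE)
    data.frame(pathway = pw, n_pathway = length(genes), n_overlap = k,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Write a network as SIF
#'
#' One `regulator  regulates  target` line per edge.
#'
#' @param net a `reg_network`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_sif <- function(net, path) {
  lines <- if (nrow(net$edges))
    sprintf("%s\tregulates\t%s", net$edges$tf, net$edges$target)
  else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read a SIF network file
#'
#' Node attributes (direction, fold change) are not stored in SIF; is_tf is
#' inferred from edge sources.
#'
#' @param path a SIF file as written by [write_sif()].
#' @return A `reg_network`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(reg_network(data.frame(gene_id = character(0), is_tf = logical(0),
                                  direction = character(0),
                                  fold_change = numeric(0),
                                  stringsAsFactors = FALSE),
                       empty_edges()))
  }
  parts <- do.call(rbind, strsplit(lines, "\t"))
  edges <- data.frame(tf = parts[, 1], target = parts[, 3],
                      p_value = NA_real_, stringsAsFactors = FALSE)
  ids <- sort(unique(c(edges$tf, edges$target)))
  nodes <- data.frame(gene_id = ids, is_tf = ids %in% edges$tf,
                      direction = NA_character_, fold_change = NA_real_,
                      stringsAsFactors = FALSE)
  reg_network(nodes, edges)
}

#' Write a network as GraphML
#'
#' Node attributes `is_tf`, `direction`, `fold_change` and edge attribute
#' `p_value` are preserved.
#'
#' @param net a `reg_network`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network written by [write_graphml()]
#'
#' @param path file path.
#' @param minimal value of the minimal flag to set.
#' @return A `reg_network`.
#' @export
read_graphml <- function(path, minimal = FALSE) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(
    gene_id = igraph::V(g)$name,
    is_tf = as.logical(igraph::V(g)$is_tf),
    direction = if ("direction" %in%
                      igraph::vertex_attr_names(g))
      as.character(igraph::V(g)$direction) else NA_character_,
    fold_change = if ("fold_change" %in%
                        igraph::vertex_attr_names(g))
      as.numeric(igraph::V(g)$fold_change) else NA_real_,
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- if (nrow(el))
    data.frame(tf = el[, 1], target = el[, 2],
               p_value = if ("p_value" %in% igraph::edge_attr_names(g))
                 igraph::E(g)$p_value else NA_real_,
               stringsAsFactors = FALSE)
  else empty_edges()
  reg_network(nodes, edges, minimal = minimal)
}

#' Read pathway sets from a GMT file
#'
#' Standard GMT: one pathway per line, `name <tab> description <tab>
#' gene...`.
#'
#' @param path file path.
#' @return Named list of gene-ID vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  out
}
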