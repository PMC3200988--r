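# Cross-condition network algebra: composite networks by edge union, and
# classification of a focal network's relationships as common to, or
# specific against, a set of comparison networks. Edge identity throughout
# is the directed (regulator, target) gene pair; p-values and expression
# directions are attributes, not identity.

edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character(0))
  paste(net$edges$tf, net$edges$target, sep = "\r")
}

#' Union of regulatory networks (composite network)
#'
#' Pools several networks of one condition into a composite network: the
#' edge set is the union of the input edge sets (duplicates collapsed,
#' keeping the smallest p-value) and node attributes are merged. Nodes whose
#' expression direction disagrees across inputs are flagged with direction
#' `NA` and listed in the `"direction_conflicts"` attribute.
#'
#' @param networks list of `reg_network` objects (>= 1).
#' @return A composite `reg_network`.
#' @export
union_composite <- function(networks) {
  stopifnot(length(networks) >= 1)
  lapply(networks, function(n) stopifnot(inherits(n, "reg_network")))
  edges <- do.call(rbind, lapply(networks, function(n) {
    e <- n$edges
    if (!"p_value" %in% names(e)) e$p_value <- NA_real_
    e[, c("tf", "target", "p_value"), drop = FALSE]
  }))
  if (nrow(edges)) {
    key <- paste(edges$tf, edges$target, sep = "\r")
    edges <- edges[order(key, edges$p_value, na.last = TRUE), , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$tf, edges$target, sep = "\r")), ,
                   drop = FALSE]
    edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  } else {
    edges <- empty_edges()
  }
  nodes <- do.call(rbind, lapply(networks, function(n) n$nodes))
  conflicts <- character(0)
  if (nrow(nodes)) {
    merged <- lapply(split(nodes, nodes$gene_id), function(g) {
      dir <- unique(g$direction[!is.na(g$direction)])
      data.frame(gene_id = g$gene_id[1], is_tf = any(g$is_tf),
                 direction = if (length(dir) == 1) dir else NA_character_,
                 fold_change = g$fold_change[1],
                 conflict = length(dir) > 1, stringsAsFactors = FALSE)
    })
    nodes <- do.call(rbind, merged)
    conflicts <- nodes$gene_id[nodes$conflict]
    nodes$conflict <- NULL
    nodes <- nodes[order(nodes$gene_id), , drop = FALSE]
  }
  out <- reg_network(nodes, edges, minimal = FALSE)
  attr(out, "direction_conflicts") <- conflicts
  out
}

#' Classify focal-network edges as common or specific
#'
#' An edge of the focal network is *common* when the same directed
#' (regulator, target) gene pair occurs in at least one of the comparison
#' networks, and *specific* when it occurs in none of them. TF nodes are
#' classified analogously (shared when the gene is a TF in any comparison
#' network). A warning is raised when the focal network shares no node with
#' any comparison network, which usually indicates a gene-ID namespace
#' mismatch.
#'
#' @param focal the `reg_network` under study.
#' @param others named list of comparison `reg_network`s.
#' @return An object of class `network_comparison`: list with `common` and
#'   `specific` edge data.frames (each with a `which_others` column for
#'   common edges), `shared_tfs`, `specific_tfs`, and `counts`.
#' @export
classify_edges <- function(focal, others) {
  stopifnot(inherits(focal, "reg_network"))
  lapply(others, function(n) stopifnot(inherits(n, "reg_network")))
  if (is.null(names(others)) && length(others))
    names(others) <- paste0("other", seq_along(others))
  if (length(others)) {
    overlap <- vapply(others, function(o)
      length(intersect(focal$nodes$gene_id, o$nodes$gene_id)),
      integer(1))
    if (nrow(focal$nodes) && all(overlap == 0))
      warning("no node overlap between focal and comparison networks; ",
              "check gene-ID namespaces")
  }
  fkeys <- edge_keys(focal)
  okeys <- lapply(others, edge_keys)
  membership <- vapply(fkeys, function(k)
    paste(names(others)[vapply(okeys, function(ok) k %in% ok, logical(1))],
          collapse = ","), character(1))
  is_common <- nzchar(membership) & length(others) > 0
  if (!length(fkeys)) is_common <- logical(0)
  common <- focal$edges[is_common, , drop = FALSE]
  if (nrow(common)) common$which_others <- membership[is_common]
  specific <- focal$edges[!is_common, , drop = FALSE]
  rownames(common) <- rownames(specific) <- NULL

  focal_tfs <- focal$nodes$gene_id[focal$nodes$is_tf]
  other_tfs <- unique(unlist(lapply(others, function(o)
    o$nodes$gene_id[o$nodes$is_tf])))
  shared_tfs <- sort(intersect(focal_tfs, other_tfs))
  specific_tfs <- sort(setdiff(focal_tfs, other_tfs))

  structure(list(common = common, specific = specific,
                 shared_tfs = shared_tfs, specific_tfs = specific_tfs,
                 counts = list(n_focal = length(fkeys),
                               n_common = nrow(common),
                               n_specific = nrow(specific))),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("network_comparison: %d focal edges = %d common + %d specific\n",
              x$counts$n_focal, x$counts$n_common, x$counts$n_specific))
  cat(sprintf("  TFs: %d shared (%s), %d specific (%s)\n",
              length(x$shared_tfs), paste(x$shared_tfs, collapse = ", "),
              length(x$specific_tfs),
              paste(x$specific_tfs, collapse = ", ")))
  invisible(x)
}

#' Write a comparison report (TSV + summary JSON)
#'
#' @param cmp a `network_comparison`.
#' @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_comparison <- function(cmp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- rbind(
    if (nrow(cmp$common))
      data.frame(tf = cmp$common$tf, target = cmp$common$target,
                 status = "common", which_others = cmp$common$which_others,
                 stringsAsFactors = FALSE),
    if (nrow(cmp$specific))
      data.frame(tf = cmp$specific$tf, target = cmp$specific$target,
                 status = "specific", which_others = "",
                 stringsAsFactors = FALSE))
  if (is.null(rows))
    rows <- data.frame(tf = character(0), target = character(0),
                       status = character(0), which_others = character(0))
  paths <- c(report = file.path(dir, "comparison.tsv"),
             summary = file.path(dir, "comparison_summary.json"))
  utils::write.table(rows, paths[["report"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(c(cmp$counts,
                         list(shared_tfs = cmp$shared_tfs,
                              specific_tfs = cmp$specific_tfs)),
                       paths[["summary"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
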