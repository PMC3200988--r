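# Normalization and quality pipeline: absent-probe removal, per-probe
# z-normalization, UPGMA sample clustering on Euclidean distance, and
# removal of tumour samples that cluster with the non-malignant controls.

#' Remove probes called Absent in every sample
#'
#' Drops probes whose MAS5-style detection flag is `A` in all samples;
#' probes with at least one `P` or `M` call are retained in their original
#' order.
#'
#' @param x an [expr_mat()] with detection flags.
#' @return The filtered `expr_mat`, with a `"log"` attribute recording the
#'   number of probes removed.
#' @export
filter_absent <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  if (is.null(x$detection))
    stop("filter_absent requires detection flags; none present")
  keep <- rowSums(x$detection != "A") > 0
  out <- subset_expr(x, probes = rownames(x$values)[keep])
  attr(out, "log") <- log_line("filter_absent: removed ", sum(!keep),
                               " of ", length(keep), " probes")
  out
}

#' Per-probe z-normalization
#'
#' Standardizes each probe row to mean 0, standard deviation 1 across
#' samples, using the population (divide-by-n) standard deviation.
#' Constant rows cannot be standardized and are set to all zeros with a
#' warning, so probe sets stay comparable across datasets.
#'
#' @param x an [expr_mat()] with at least two samples.
#' @return The `expr_mat` on `z` scale.
#' @export
z_normalize <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  if (ncol(x$values) < 2) stop("z-normalization needs >= 2 samples")
  m <- x$values
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  const <- sd_pop <= .Machine$double.eps * pmax(1, abs(mu))
  if (any(const)) {
    warning(sum(const), " constant probe row(s) set to zero during z-normalization")
    sd_pop[const] <- 1
  }
  z <- (m - mu) / sd_pop
  z[const, ] <- 0
  x$values <- z
  x$scale <- "z"
  x
}

#' UPGMA clustering of samples
#'
#' Average-linkage (UPGMA) hierarchical clustering of samples using
#' Euclidean distance between their probe vectors, plus the flat
#' two-cluster partition obtained by cutting the tree at its root.
#'
#' @param x an [expr_mat()], normally on `z` scale, with >= 3 samples.
#' @return A list with components `tree` (an [stats::hclust] object over
#'   samples) and `partition` (named integer vector of cluster labels 1/2).
#' @export
upgma_cluster <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  if (ncol(x$values) < 3) stop("clustering needs >= 3 samples")
  if (anyNA(x$values)) stop("expression matrix contains NaN/NA values")
  d <- stats::dist(t(x$values), method = "euclidean")
  tree <- stats::hclust(d, method = "average")
  partition <- stats::cutree(tree, k = 2)
  list(tree = tree, partition = partition)
}

#' Export a sample dendrogram as Newick
#'
#' @param tree an [stats::hclust] object as returned by [upgma_cluster()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_dendrogram <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Remove tumour samples that cluster with the controls
#'
#' Given a two-group sample partition, drops every tumour sample assigned to
#' the cluster holding the majority of control samples, then repeats
#' z-normalization on the survivors. Controls are never dropped. An even
#' 50/50 split of controls across the two clusters is ambiguous and raises
#' an error asking for manual review.
#'
#' @param x an [expr_mat()] (any scale; the returned matrix is re-normalized
#'   from these values).
#' @param partition named cluster labels covering every sample, as returned
#'   by [upgma_cluster()].
#' @return A list with `matrix` (the z-normalized `expr_mat` of surviving
#'   samples) and `excluded` (data.frame of dropped sample IDs and reason).
#' @export
remove_outliers <- function(x, partition) {
  stopifnot(inherits(x, "expr_mat"))
  if (!all(colnames(x$values) %in% names(partition)))
    stop("partition must label every sample")
  part <- partition[colnames(x$values)]
  ctrl <- control_ids(x)
  tab <- table(part[ctrl])
  if (length(tab) > 1 && tab[1] == tab[2])
    stop("controls split evenly across clusters; manual review required")
  ctrl_cluster <- as.integer(names(which.max(tab)))
  drop <- intersect(tumor_ids(x), names(part)[part == ctrl_cluster])
  keep <- setdiff(colnames(x$values), drop)
  out <- subset_expr(x, samples = keep)
  out <- z_normalize(out)
  list(matrix = out,
       excluded = data.frame(sample_id = drop,
                             reason = rep("clusters_with_controls",
                                          length(drop)),
                             stringsAsFactors = FALSE))
}

#' Run the full quality pipeline
#'
#' Absent-probe filtering, z-normalization, UPGMA clustering and outlier
#' removal in sequence, mirroring the usual microarray quality review for
#' two-class tumour/control designs.
#'
#' @param x an [expr_mat()] on signal scale with detection flags.
#' @return A list with `matrix` (clean z-scale `expr_mat`), `signal`
#'   (the same probes/samples on the original scale, for downstream fold
#'   changes), `excluded` (data.frame), and `tree` (sample dendrogram).
#' @export
preprocess <- function(x) {
  filt <- filter_absent(x)
  z <- z_normalize(filt)
  cl <- upgma_cluster(z)
  res <- remove_outliers(z, cl$partition)
  keep <- colnames(res$matrix$values)
  list(matrix = res$matrix,
       signal = subset_expr(filt, samples = keep),
       excluded = res$excluded,
       tree = cl$tree)
}
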