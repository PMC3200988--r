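# End-to-end orchestration: preprocess -> iterative SAM DEG selection ->
# promoter analysis -> network assembly/pruning (-> comparison), either in
# memory (run_study) or from a file-based configuration (run_pipeline) with
# a manifest recording seeds, parameters and per-stage funnel counts.

#' Pipeline configuration
#'
#' Collects the input paths, stage parameters and master seed of a full
#' run. The configuration round-trips losslessly through YAML
#' ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param expression,classes,annotation,detection,promoters,pwms,tf_mapping
#'   input file paths (`detection` optional, see [read_expression()]).
#' @param pathway_sets optional GMT file for the enrichment test.
#' @param others optional named character vector of comparison network
#'   files (GraphML) for the comparison stage.
#' @param out_dir output directory.
#' @param n_iter training iterations.
#' @param n_perm SAM permutations.
#' @param fold_min minimum linear fold change.
#' @param p_interaction interaction p-value cutoff.
#' @param threshold_frac PWM site-score threshold fraction.
#' @param n_shuffle background shuffles per promoter.
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, classes, annotation, promoters,
                            pwms, tf_mapping, detection = NULL,
                            pathway_sets = NULL, others = NULL,
                            out_dir = "regnet_out", n_iter = 10,
                            n_perm = 100, fold_min = 2,
                            p_interaction = 0.005, threshold_frac = 0.8,
                            n_shuffle = 10, seed = 1) {
  cfg <- as.list(environment())
  if (p_interaction <= 0 || p_interaction > 1)
    stop("p_interaction must lie in (0, 1]")
  if (fold_min <= 1) stop("fold_min must exceed 1")
  paths <- unlist(cfg[c("expression", "classes", "annotation", "promoters",
                        "pwms", "tf_mapping", "detection", "pathway_sets")])
  paths <- c(paths, cfg$others)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the analysis in memory
#'
#' The core pipeline on in-memory objects: quality preprocessing, the
#' iterative SAM framework, TF identification and promoter-based
#' interaction prediction, network assembly and minimal pruning. Used by
#' [run_pipeline()] and directly convenient on [simulate_study()] output.
#'
#' @param expr an [expr_mat()] on signal scale with detection flags.
#' @param promoters named promoter sequences (character or `DNAStringSet`).
#' @param pwms named list of [pwm()]s.
#' @param tf_map data.frame (`gene_id`, `pwm_id`).
#' @param n_iter,n_perm,fold_min,p_interaction,threshold_frac,n_shuffle,seed
#'   stage parameters as in [pipeline_config()].
#' @return A list with `pre`, `degs`, `tfs`, `interactions`, `network`,
#'   `minimal`, and `summary` (per-stage funnel counts).
#' @export
run_study <- function(expr, promoters, pwms, tf_map, n_iter = 10,
                      n_perm = 100, fold_min = 2, p_interaction = 0.005,
                      threshold_frac = 0.8, n_shuffle = 10, seed = 1) {
  pre <- preprocess(expr)
  degs <- deg_signature(pre$signal, n_iter = n_iter,
                        seed = child_seed(seed, "deg"),
                        sam_args = list(n_perm = n_perm,
                                        fold_min = fold_min))
  tfs <- identify_tfs(degs, tf_map)
  interactions <- predict_interactions(
    tfs, promoters, degs, pwms, tf_map, p_cutoff = p_interaction,
    threshold_frac = threshold_frac, n_shuffle = n_shuffle,
    seed = child_seed(seed, "promoter"))
  network <- build_network(interactions, degs, tfs)
  minimal <- prune_minimal(network)
  list(pre = pre, degs = degs, tfs = tfs, interactions = interactions,
       network = network, minimal = minimal,
       summary = list(
         n_probes_in = nrow(expr$values),
         n_probes_kept = nrow(pre$matrix$values),
         n_samples_excluded = nrow(pre$excluded),
         n_degs = nrow(degs$genes),
         n_tfs = length(tfs),
         n_interactions = nrow(interactions),
         network = network_summary(network),
         minimal = network_summary(minimal)))
}

#' Run the full pipeline from a configuration
#'
#' Executes preprocess, DEG selection, promoter analysis and network
#' assembly from files, writes each stage's outputs under the configured
#' output directory, optionally compares against other networks, and writes
#' a manifest JSON recording the configuration hash, seeds and per-stage
#' summaries. Any stage error is re-raised with the stage name; outputs of
#' completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return The [run_study()] result, extended with `comparison` when other
#'   networks were supplied and `manifest` (also written to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inputs <- stage("read", {
    list(expr = read_expression(config$expression, config$classes,
                                config$annotation, config$detection),
         promoters = Biostrings::readDNAStringSet(config$promoters),
         pwms = read_jaspar(config$pwms),
         tf_map = utils::read.delim(config$tf_mapping,
                                    colClasses = "character"))
  })
  res <- list()
  res$pre <- stage("preprocess", preprocess(inputs$expr))
  utils::write.table(res$pre$excluded,
                     file.path(config$out_dir, "excluded_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_dendrogram(res$pre$tree,
                   file.path(config$out_dir, "sample_dendrogram.nwk"))
  res$degs <- stage("deg", deg_signature(
    res$pre$signal, n_iter = config$n_iter,
    seed = child_seed(config$seed, "deg"),
    sam_args = list(n_perm = config$n_perm, fold_min = config$fold_min)))
  write_degs(res$degs, config$out_dir)
  res$tfs <- stage("promoter", identify_tfs(res$degs, inputs$tf_map))
  res$interactions <- stage("promoter", predict_interactions(
    res$tfs, inputs$promoters, res$degs, inputs$pwms, inputs$tf_map,
    p_cutoff = config$p_interaction,
    threshold_frac = config$threshold_frac,
    n_shuffle = config$n_shuffle,
    seed = child_seed(config$seed, "promoter")))
  write_interactions(res$interactions,
                     file.path(config$out_dir, "interactions.tsv"))
  res$network <- stage("network",
                       build_network(res$interactions, res$degs, res$tfs))
  res$minimal <- stage("network", prune_minimal(res$network))
  write_sif(res$minimal, file.path(config$out_dir, "minimal_network.sif"))
  write_graphml(res$minimal,
                file.path(config$out_dir, "minimal_network.graphml"))
  if (!is.null(config$pathway_sets)) {
    res$enrichment <- stage("network", pathway_overrepresentation(
      res$minimal$nodes$gene_id, read_gmt(config$pathway_sets),
      unique(inputs$expr$probe_gene)))
    utils::write.table(res$enrichment,
                       file.path(config$out_dir, "pathway_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stages <- c("preprocess", "deg", "promoter", "network")
  if (!is.null(config$others)) {
    others <- lapply(config$others, read_graphml)
    res$comparison <- stage("compare", classify_edges(res$minimal, others))
    write_comparison(res$comparison, config$out_dir)
    stages <- c(stages, "compare")
  }
  summary <- list(
    n_probes_in = nrow(inputs$expr$values),
    n_probes_kept = nrow(res$pre$matrix$values),
    n_samples_excluded = nrow(res$pre$excluded),
    n_degs = nrow(res$degs$genes),
    n_tfs = length(res$tfs),
    n_interactions = nrow(res$interactions),
    network = network_summary(res$network),
    minimal = network_summary(res$minimal))
  if (!is.null(res$comparison)) summary$comparison <- res$comparison$counts
  manifest <- list(
    package_version = as.character(utils::packageVersion("minregnet")),
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    stages_complete = stages,
    summary = summary)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$summary <- summary
  res$manifest <- manifest
  res
}

# Order-stable hash of the configuration (names sorted, serialized to
# JSON); good enough to detect config drift between runs.
config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  j <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  # tiny polynomial rolling hash over the serialized bytes; avoids a
  # digest dependency
  bytes <- utf8ToInt(as.character(j))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
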