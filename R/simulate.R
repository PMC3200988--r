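# Synthetic-study generator. Emulates a two-class (tumour vs non-malignant)
# microarray study with a planted regulatory structure: log2-normal signal
# with exact planted fold changes, many-to-one probe->gene mapping, MAS5-
# style absent flags, mislabeled outlier tumours drawn from the control
# distribution, per-TF binding motifs embedded in target promoters, and a
# ground-truth table so every downstream stage has a recovery test.

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' recovery experiments: a 40-tumour / 10-control cohort over 1000 genes
#' with 10% planted DEGs at four-fold change and log2-scale noise 0.3, a
#' six-TF planted network with four targets per TF and two motif sites per
#' edge in 1 kb promoters.
#'
#' @param n_tumor,n_control sample counts (tumour includes outliers).
#' @param n_genes number of genes.
#' @param probes_per_gene inclusive integer range; each gene draws its probe
#'   count uniformly from it.
#' @param frac_deg fraction of genes planted as differentially expressed.
#' @param deg_fold linear fold change of planted DEGs (>= `min_fold`).
#' @param frac_up fraction of planted DEGs that are up-regulated.
#' @param min_fold minimum linear fold change the downstream filter uses
#'   (planted DEGs must satisfy it).
#' @param noise_sd per-probe Gaussian noise standard deviation on the log2
#'   scale.
#' @param n_tfs number of TF genes (planted among the DEGs).
#' @param edges_per_tf planted regulatory edges per TF; targets are shared
#'   so that each target is regulated by two TFs when `n_tfs >= 2`.
#' @param promoter_length promoter length in bases.
#' @param motif_length motif length in bases.
#' @param motif_sites_per_edge planted binding sites per regulatory edge.
#' @param site_threshold_frac scan threshold (fraction of the maximum
#'   log-odds score) that planted sites are guaranteed to exceed; keep equal
#'   to the `threshold_frac` used when scanning.
#' @param frac_absent fraction of probes flagged Absent in all samples
#'   (drawn from non-DEG genes).
#' @param n_outliers number of tumour samples simulated as mislabeled
#'   (drawn from the control distribution).
#' @param background base frequencies of promoter background sequence.
#' @param seed RNG seed; a fixed seed makes all outputs byte-identical.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_tumor = 40, n_control = 10, n_genes = 1000,
                       probes_per_gene = c(1, 3), frac_deg = 0.1,
                       deg_fold = 4, frac_up = 0.25, min_fold = 2,
                       noise_sd = 0.3, n_tfs = 6, edges_per_tf = 4,
                       promoter_length = 1000, motif_length = 10,
                       motif_sites_per_edge = 2, site_threshold_frac = 0.8,
                       frac_absent = 0.05,
                       n_outliers = 2, background = rep(0.25, 4),
                       seed = 1) {
  cfg <- as.list(environment())
  if (min_fold <= 1) stop("min_fold must exceed 1")
  if (deg_fold < min_fold)
    stop("planted deg_fold must be at least min_fold")
  if (motif_length <= 0) stop("motif length must be positive")
  if (promoter_length < motif_length)
    stop("promoter_length must be at least the motif length")
  if (frac_deg < 0 || frac_deg > 1 || frac_absent < 0 || frac_absent > 1)
    stop("fractions must lie in [0, 1]")
  if (any(c(n_tumor, n_control, n_genes, n_tfs, edges_per_tf,
            n_outliers) < 0))
    stop("counts must be non-negative")
  if (n_tumor < 4 || n_control < 2)
    stop("need n_tumor >= 4 and n_control >= 2")
  if (abs(sum(background) - 1) > 1e-8)
    stop("background must sum to 1")
  structure(cfg, class = "sim_config")
}

#' Generate a PWM library for the planted TFs
#'
#' One count matrix per TF gene, with a clearly detectable motif (average
#' information content at least 1 bit per column): each column carries a
#' dominant base at 85 of 100 counts.
#'
#' @param config a [sim_config()].
#' @param tf_ids character vector of TF gene IDs (one PWM each).
#' @return List with `pwms` (named list of [pwm()]) and `tf_map`
#'   (data.frame `gene_id`, `pwm_id`).
#' @export
generate_pwm_library <- function(config, tf_ids) {
  stopifnot(inherits(config, "sim_config"))
  if (length(tf_ids) < 1) stop("need at least one TF")
  pwms <- with_seed(child_seed(config$seed, "pwms"), {
    lapply(seq_along(tf_ids), function(i) {
      dom <- sample.int(4, config$motif_length, replace = TRUE)
      counts <- matrix(5, 4, config$motif_length)
      counts[cbind(dom, seq_len(config$motif_length))] <- 85
      pwm(counts, id = sprintf("SIM%04d", i), tf_gene = tf_ids[i],
          background = config$background)
    })
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "id")
  list(pwms = pwms,
       tf_map = data.frame(gene_id = tf_ids, pwm_id = names(pwms),
                           stringsAsFactors = FALSE))
}

# Draw one site from a PWM's column distributions, conditioned on scoring
# at least `threshold_frac` of the maximum log-odds score so that every
# planted site is recoverable by the scanner (rejection sampling).
sample_site <- function(p, threshold_frac = 0.8, max_tries = 1000) {
  pr <- pwm_probs(p)
  lom <- pwm_logodds(p)
  thr <- threshold_frac * sum(apply(lom, 2, max))
  for (try in seq_len(max_tries)) {
    bases <- vapply(seq_len(ncol(pr)), function(j)
      sample.int(4, 1, prob = pr[, j]), integer(1))
    if (sum(lom[cbind(bases, seq_along(bases))]) >= thr)
      return(paste(DNA[bases], collapse = ""))
  }
  pwm_consensus(p)  # motif too diffuse to hit the threshold by sampling
}

revcomp_string <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Generate promoter sequences with planted binding sites
#'
#' Every gene receives an i.i.d. background promoter at the configured base
#' composition; for each planted edge (TF, target) the target's promoter
#' has `motif_sites_per_edge` sites sampled from the TF's PWM written in at
#' non-overlapping random positions and strands.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth list containing `edges`.
#' @param pwms named list of [pwm()]s.
#' @param tf_map data.frame (`gene_id`, `pwm_id`).
#' @param gene_ids all gene IDs (each gets a promoter).
#' @return List with `promoters` (named character vector) and `sites`
#'   (data.frame `gene_id`, `tf`, `position`, `strand`).
#' @export
generate_promoters <- function(config, truth, pwms, tf_map, gene_ids) {
  stopifnot(inherits(config, "sim_config"))
  len <- config$promoter_length
  with_seed(child_seed(config$seed, "promoters"), {
    promoters <- vapply(gene_ids, function(g)
      paste(sample(DNA, len, replace = TRUE, prob = config$background),
            collapse = ""), character(1))
    sites <- list()
    if (config$motif_sites_per_edge > 0 && nrow(truth$edges)) {
      for (g in unique(truth$edges$target)) {
        seq_chars <- strsplit(promoters[[g]], "")[[1]]
        occupied <- logical(len)
        for (tf in truth$edges$tf[truth$edges$target == g]) {
          p <- pwms[[tf_map$pwm_id[tf_map$gene_id == tf][1]]]
          L <- ncol(p$counts)
          for (k in seq_len(config$motif_sites_per_edge)) {
            # rejection-sample a start that does not overlap earlier sites
            for (try in 1:200) {
              pos <- sample.int(len - L + 1, 1)
              if (!any(occupied[pos:(pos + L - 1)])) break
            }
            occupied[pos:(pos + L - 1)] <- TRUE
            site <- sample_site(p, config$site_threshold_frac)
            strand <- sample(c("+", "-"), 1)
            if (strand == "-") site <- revcomp_string(site)
            seq_chars[pos:(pos + L - 1)] <- strsplit(site, "")[[1]]
            sites[[length(sites) + 1]] <- data.frame(
              gene_id = g, tf = tf, position = pos, strand = strand,
              stringsAsFactors = FALSE)
          }
        }
        promoters[[g]] <- paste(seq_chars, collapse = "")
      }
    }
    sites <- if (length(sites)) do.call(rbind, sites) else
      data.frame(gene_id = character(0), tf = character(0),
                 position = integer(0), strand = character(0),
                 stringsAsFactors = FALSE)
    list(promoters = promoters, sites = sites)
  })
}

#' Generate the two-class expression matrix
#'
#' Log2-normal model: each probe's control-group log2 mean is drawn
#' uniformly in [5, 11]; planted-DEG probes shift the tumour mean by the
#' gene's true log2 fold change (all probes of a gene share the shift);
#' i.i.d. Gaussian noise of sd `noise_sd` is added on the log2 scale and
#' the result exponentiated to signal scale. Outlier tumours are drawn from
#' the control distribution; absent probes are flagged `A` in every sample.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth list (`deg`, `outlier_sample_ids`,
#'   `absent_probe_ids`, `probe_gene`).
#' @return An [expr_mat()] on signal scale with detection flags.
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  probes <- names(truth$probe_gene)
  samples <- c(sprintf("T%03d", seq_len(config$n_tumor)),
               sprintf("C%03d", seq_len(config$n_control)))
  classes <- stats::setNames(rep(c("tumor", "control"),
                                 c(config$n_tumor, config$n_control)),
                             samples)
  with_seed(child_seed(config$seed, "expression"), {
    base_mean <- stats::setNames(stats::runif(length(probes), 5, 11), probes)
    lfc <- stats::setNames(rep(0, length(probes)), probes)
    if (nrow(truth$deg)) {
      idx <- truth$probe_gene %in% truth$deg$gene_id
      gene_lfc <- stats::setNames(truth$deg$log2fc, truth$deg$gene_id)
      lfc[idx] <- gene_lfc[truth$probe_gene[idx]]
    }
    shift <- outer(lfc, ifelse(classes == "tumor", 1, 0))
    # mislabeled tumours follow the control distribution
    shift[, colnames(shift) %in% truth$outlier_sample_ids] <- 0
    mu <- base_mean + shift
    noise <- matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                    nrow(mu), ncol(mu))
    values <- 2^(mu + noise)
    dimnames(values) <- list(probes, samples)
    detection <- matrix("P", nrow(values), ncol(values),
                        dimnames = dimnames(values))
    detection[truth$absent_probe_ids, ] <- "A"
    expr_mat(values, classes, truth$probe_gene, detection = detection,
             scale = "signal")
  })
}

#' Simulate a complete planted study
#'
#' Draws the ground truth (DEG set, TF set, regulatory edges, outliers,
#' absent probes), then generates the PWM library, the promoters with
#' planted sites, and the expression matrix. TFs and their targets are
#' chosen among the planted DEGs so the full pipeline can recover the
#' planted network; when `n_tfs >= 2` each target is regulated by exactly
#' two TFs, making the planted network minimal by construction.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_study`: `expr` (an [expr_mat()]), `truth`
#'   (list with `deg`, `edges`, `tf_ids`, `outlier_sample_ids`,
#'   `absent_probe_ids`, `probe_gene`, `sites`), `promoters`, `pwms`,
#'   `tf_map`, and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))

  truth <- with_seed(child_seed(config$seed, "truth"), {
    n_deg <- round(config$frac_deg * config$n_genes)
    if (n_deg < 1) {
      warning("frac_deg * n_genes < 1; no DEGs planted")
      n_deg <- 0
    }
    deg_ids <- sort(sample(gene_ids, n_deg))
    n_up <- round(config$frac_up * n_deg)
    dirs <- sample(rep(c("up", "down"), c(n_up, n_deg - n_up)))
    lfc <- ifelse(dirs == "up", 1, -1) * log2(config$deg_fold)
    deg <- data.frame(
      gene_id = deg_ids, direction = dirs, log2fc = lfc,
      fold_change = 2^lfc, stringsAsFactors = FALSE)

    tf_ids <- if (config$n_tfs > 0 && n_deg >= config$n_tfs)
      sort(sample(deg_ids, config$n_tfs)) else character(0)
    edges <- make_planted_edges(tf_ids, setdiff(deg_ids, tf_ids),
                                config$edges_per_tf)

    ppg <- seq(config$probes_per_gene[1], config$probes_per_gene[2])
    n_probes <- ppg[sample.int(length(ppg), config$n_genes,
                               replace = TRUE)]
    probe_gene <- stats::setNames(rep(gene_ids, n_probes),
                                  unlist(lapply(seq_along(gene_ids),
                                                function(i) sprintf(
                                                  "%s_p%d", gene_ids[i],
                                                  seq_len(n_probes[i])))))
    non_deg_probes <- names(probe_gene)[!probe_gene %in% deg_ids]
    n_absent <- round(config$frac_absent * length(probe_gene))
    absent <- sort(sample(non_deg_probes, min(n_absent,
                                              length(non_deg_probes))))
    outliers <- sort(sample(sprintf("T%03d", seq_len(config$n_tumor)),
                            config$n_outliers))
    list(deg = deg, tf_ids = tf_ids, edges = edges,
         probe_gene = probe_gene, absent_probe_ids = absent,
         outlier_sample_ids = outliers)
  })

  lib <- if (length(truth$tf_ids))
    generate_pwm_library(config, truth$tf_ids)
  else list(pwms = list(),
            tf_map = data.frame(gene_id = character(0),
                                pwm_id = character(0)))
  prom <- generate_promoters(config, truth, lib$pwms, lib$tf_map, gene_ids)
  truth$sites <- prom$sites
  expr <- generate_expression(config, truth)
  structure(list(expr = expr, truth = truth, promoters = prom$promoters,
                 pwms = lib$pwms, tf_map = lib$tf_map, config = config),
            class = "sim_study")
}

# Planted edge set: targets drawn from the non-TF DEG pool, each regulated
# by exactly two TFs (cyclic pairing) so the planted network is already
# minimal; with a single TF, targets get one regulator each.
make_planted_edges <- function(tf_ids, target_pool, edges_per_tf) {
  empty <- data.frame(tf = character(0), target = character(0),
                      stringsAsFactors = FALSE)
  if (!length(tf_ids) || edges_per_tf < 1) return(empty)
  n_tf <- length(tf_ids)
  if (n_tf == 1) {
    targets <- sample(target_pool, min(edges_per_tf, length(target_pool)))
    return(data.frame(tf = tf_ids, target = sort(targets),
                      stringsAsFactors = FALSE))
  }
  n_targets <- floor(n_tf * edges_per_tf / 2)
  n_targets <- min(n_targets, length(target_pool))
  if (n_targets < 1) return(empty)
  targets <- sort(sample(target_pool, n_targets))
  rows <- lapply(seq_len(n_targets), function(j) {
    a <- (2 * (j - 1)) %% n_tf + 1
    b <- (2 * (j - 1) + 1) %% n_tf + 1
    if (a == b) b <- a %% n_tf + 1
    data.frame(tf = tf_ids[c(a, b)], target = targets[j],
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  edges[order(edges$tf, edges$target), , drop = FALSE]
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "sim_study: %d genes / %d probes, %d tumor + %d control samples\n",
    x$config$n_genes, nrow(x$expr$values), x$config$n_tumor,
    x$config$n_control))
  cat(sprintf("  planted: %d DEGs, %d TFs, %d edges, %d outliers, %d absent probes\n",
              nrow(x$truth$deg), length(x$truth$tf_ids),
              nrow(x$truth$edges), length(x$truth$outlier_sample_ids),
              length(x$truth$absent_probe_ids)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Expression (values, detection, classes, probe annotation) as TSV,
#' promoters as FASTA, PWMs in JASPAR count format, the TF-PWM mapping and
#' both truth tables as TSV.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory.
#' @return Invisibly, the named vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_expression(sim$expr, dir)
  fa <- file.path(dir, "promoters.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$promoters), fa)
  paths[["promoters"]] <- fa
  paths[["pwms"]] <- file.path(dir, "pwms.jaspar")
  write_jaspar(sim$pwms, paths[["pwms"]])
  paths[["tf_map"]] <- file.path(dir, "tf_map.tsv")
  utils::write.table(sim$tf_map, paths[["tf_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths[["deg_truth"]] <- file.path(dir, "truth_degs.tsv")
  utils::write.table(sim$truth$deg, paths[["deg_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths[["edge_truth"]] <- file.path(dir, "truth_edges.tsv")
  utils::write.table(sim$truth$edges, paths[["edge_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
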