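# Iterative parallel-SAM framework for stable differential-expression
# calls: the tumour cohort is split in half; the training half is
# repeatedly sub-split 2:1, SAM is run on each subgroup against the shared
# controls and the gene-level calls intersected; genes surviving every
# iteration form the training signature, which must then be recapitulated
# by a single SAM on the held-out test half.

#' Randomly split a tumour cohort into training and test halves
#'
#' @param sample_ids character vector of tumour sample IDs.
#' @param seed RNG seed.
#' @return List with `train` and `test` ID vectors; disjoint and exhaustive.
#'   For odd cohorts the larger half goes to training.
#' @export
split_cohort <- function(sample_ids, seed) {
  n <- length(sample_ids)
  shuffled <- with_seed(seed, sample(sample_ids))
  n_train <- ceiling(n / 2)
  list(train = sort(shuffled[seq_len(n_train)]),
       test = sort(shuffled[-seq_len(n_train)]))
}

# Intersect two gene-level call tables requiring direction agreement.
intersect_calls <- function(a, b) {
  common <- intersect(a$gene_id, b$gene_id)
  a2 <- a[match(common, a$gene_id), , drop = FALSE]
  b2 <- b[match(common, b$gene_id), , drop = FALSE]
  agree <- a2$direction == b2$direction
  out <- a2[agree, , drop = FALSE]
  rownames(out) <- NULL
  out
}

run_sam_genes <- function(x, tumors, controls, sam_args, seed) {
  sub <- subset_expr(x, samples = c(tumors, controls))
  fit <- do.call(sam, c(list(x = sub, seed = seed), sam_args))
  suppressWarnings(sam_genes(fit))
}

#' Training loop of the iterative SAM framework
#'
#' For each iteration the training tumours are re-randomized into two
#' subgroups in a 2:1 ratio, SAM is run for each subgroup against the same
#' control set, gene-level calls are intersected with direction agreement,
#' and the running intersection across iterations is kept. The training
#' signature is the set of genes significant in both subgroups in every
#' iteration.
#'
#' @param x an [expr_mat()] holding at least the training tumours and all
#'   controls.
#' @param train_ids tumour sample IDs of the training half (>= 6).
#' @param n_iter number of iterations.
#' @param seed master seed; per-iteration seeds are derived with
#'   [child_seed()] so earlier iterations are unchanged when `n_iter` grows.
#' @param sam_args list of arguments forwarded to [sam()] (e.g. `n_perm`,
#'   `fold_min`).
#' @return List with `signature` (gene-level data.frame), `iterations`
#'   (per-iteration intersected call tables) and `splits` (the subgroup
#'   assignments).
#' @export
training_loop <- function(x, train_ids, n_iter = 10, seed = 1,
                          sam_args = list()) {
  stopifnot(inherits(x, "expr_mat"))
  if (length(train_ids) < 6)
    stop("training loop needs >= 6 tumour samples")
  controls <- control_ids(x)
  n_sub1 <- round(length(train_ids) * 2 / 3)
  n_sub1 <- min(max(n_sub1, 3L), length(train_ids) - 3L)
  iterations <- vector("list", n_iter)
  splits <- vector("list", n_iter)
  signature <- NULL
  for (i in seq_len(n_iter)) {
    it_seed <- child_seed(seed, i)
    sub1 <- with_seed(it_seed, sample(train_ids, n_sub1))
    sub2 <- setdiff(train_ids, sub1)
    g1 <- run_sam_genes(x, sub1, controls, sam_args,
                        child_seed(it_seed, "sub1"))
    g2 <- run_sam_genes(x, sub2, controls, sam_args,
                        child_seed(it_seed, "sub2"))
    it <- intersect_calls(g1, g2)
    iterations[[i]] <- it
    splits[[i]] <- list(sub1 = sort(sub1), sub2 = sort(sub2))
    signature <- if (is.null(signature)) it else
      intersect_calls(signature, it)
    if (!nrow(signature))
      warning("empty intersection at iteration ", i,
              "; training signature is empty")
  }
  list(signature = signature, iterations = iterations, splits = splits)
}

#' Test arm: recapitulation of the training signature
#'
#' A single SAM analysis of the held-out test tumours against the controls;
#' the final call set is the training signature restricted to genes also
#' called, with the same direction, in the test arm.
#'
#' @param x an [expr_mat()] holding the test tumours and controls.
#' @param test_ids tumour sample IDs of the test half.
#' @param signature training-signature data.frame from [training_loop()].
#' @param seed seed for the test-arm SAM.
#' @param sam_args arguments forwarded to [sam()].
#' @return List with `final` (gene table), `not_recapitulated` (training
#'   genes missing from the test-arm calls) and `test_calls`.
#' @export
test_arm <- function(x, test_ids, signature, seed = 1, sam_args = list()) {
  controls <- control_ids(x)
  calls <- run_sam_genes(x, test_ids, controls, sam_args, seed)
  final <- intersect_calls(signature, calls)
  list(final = final,
       not_recapitulated = setdiff(signature$gene_id, final$gene_id),
       test_calls = calls)
}

#' Stable differential-expression calls by iterative parallel SAM
#'
#' The full framework: the tumour cohort is split into equal training and
#' test halves; [training_loop()] builds the training signature over
#' `n_iter` re-randomized 2:1 sub-splits, and [test_arm()] retains only the
#' signature genes recapitulated in the held-out half.
#'
#' @param x an [expr_mat()] (signal or log2 scale) with tumour and control
#'   samples.
#' @param n_iter number of training iterations (default 10).
#' @param seed master seed driving the cohort split, every iteration split
#'   and every SAM permutation.
#' @param sam_args list of arguments forwarded to [sam()].
#' @return An object of class `deg_set`: list with `genes` (data.frame
#'   `gene_id`, `direction`, `fold_change`), `provenance` (per-gene
#'   iteration counts and test-arm membership), `training`, `test` and
#'   `parameters`.
#' @export
deg_signature <- function(x, n_iter = 10, seed = 1, sam_args = list()) {
  stopifnot(inherits(x, "expr_mat"))
  tumors <- tumor_ids(x)
  halves <- split_cohort(tumors, child_seed(seed, "split"))
  tr <- training_loop(x, halves$train, n_iter = n_iter,
                      seed = child_seed(seed, "train"),
                      sam_args = sam_args)
  te <- test_arm(x, halves$test, tr$signature,
                 seed = child_seed(seed, "test"), sam_args = sam_args)
  called_per_iter <- table(unlist(lapply(tr$iterations,
                                         function(it) it$gene_id)))
  genes <- te$final
  prov <- data.frame(
    gene_id = genes$gene_id,
    n_iterations_called = as.integer(called_per_iter[genes$gene_id]),
    in_test_arm = rep(TRUE, nrow(genes)),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, provenance = prov,
                 training = tr, test = te,
                 parameters = list(n_iter = n_iter, seed = seed,
                                   train_ids = halves$train,
                                   test_ids = halves$test,
                                   sam_args = sam_args)),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  g <- x$genes
  cat(sprintf("deg_set: %d genes (%d up, %d down) after %d training iterations + test arm\n",
              nrow(g), sum(g$direction == "up"), sum(g$direction == "down"),
              x$parameters$n_iter))
  if (length(x$test$not_recapitulated))
    cat(sprintf("  %d training genes not recapitulated in the test arm\n",
                length(x$test$not_recapitulated)))
  invisible(x)
}

#' @export
summary.deg_set <- function(object, ...) {
  print(object)
  cat(sprintf("  training signature: %d genes; per-iteration call counts: %s\n",
              nrow(object$training$signature),
              paste(vapply(object$training$iterations, nrow, integer(1)),
                    collapse = " ")))
  invisible(object$genes)
}

#' Write DEG calls as TSV plus a JSON run log
#'
#' @param degs a [deg_signature()] result.
#' @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_degs <- function(degs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- merge(degs$genes, degs$provenance, by = "gene_id", sort = TRUE)
  paths <- c(degs = file.path(dir, "degs.tsv"),
             log = file.path(dir, "deg_run_log.json"))
  utils::write.table(tab, paths[["degs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(parameters = degs$parameters[c("n_iter", "seed")],
         train_ids = degs$parameters$train_ids,
         test_ids = degs$parameters$test_ids,
         splits = degs$training$splits,
         n_signature = nrow(degs$training$signature),
         n_final = nrow(degs$genes)),
    paths[["log"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
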