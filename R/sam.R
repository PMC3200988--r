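# Significance Analysis of Microarrays (SAM), two-class unpaired, written
# from scratch: moderated d statistic, Tusher-style fudge factor s0,
# permutation null with rank-wise expected statistics, an FDR-vs-delta
# table, the zero-FDR delta selection rule, and a linear fold-change filter.

# d_i = (mean_tumor - mean_control) / (s_i + s0), with
# s_i = sqrt(((1/n1 + 1/n2) / (n1 + n2 - 2)) * (SS_tumor + SS_control)),
# the pooled standard error of the group difference.
sam_stats <- function(m, is_tumor, s0 = 0) {
  n1 <- sum(is_tumor); n2 <- sum(!is_tumor)
  if (n1 < 2 || n2 < 2) stop("each class needs >= 2 samples")
  x1 <- m[, is_tumor, drop = FALSE]
  x2 <- m[, !is_tumor, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  s <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) * (ss1 + ss2))
  list(r = m1 - m2, s = s, d = (m1 - m2) / (s + s0))
}

#' Per-probe SAM d statistic
#'
#' @param x an [expr_mat()] on `log2` scale (signal-scale input is log2
#'   transformed first).
#' @param s0 the fudge-factor constant added to the denominator.
#' @return Named numeric vector of d statistics.
#' @export
d_statistic <- function(x, s0 = 0) {
  stopifnot(inherits(x, "expr_mat"))
  x <- log2_transform(x)
  sam_stats(x$values, x$classes == "tumor", s0)$d
}

#' Estimate SAM's fudge factor s0
#'
#' The Tusher procedure: candidate values are the 0, 5, ..., 100 percentiles
#' of the per-probe standard errors `s`; for each candidate the coefficient
#' of variation of the d statistics is computed across quantile windows of
#' `s` (spread measured by MAD within each window), and the candidate
#' minimizing this CV is returned. Stabilizes probes whose tiny variance
#' would otherwise inflate d.
#'
#' @param r per-probe numerators (group mean differences).
#' @param s per-probe pooled standard errors.
#' @return The chosen s0 (a value of the `s` distribution).
#' @export
estimate_s0 <- function(r, s) {
  if (length(s) < 10) stop("s0 estimation needs >= 10 probes")
  if (diff(range(s)) <= .Machine$double.eps * max(1, max(s))) {
    message("all standard errors identical; s0 fixed at that value")
    return(stats::quantile(s, 0.05, names = FALSE))
  }
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(s, alphas, names = FALSE)
  n_win <- max(2L, min(100L, length(s) %/% 25L))
  win <- cut(rank(s, ties.method = "first"),
             breaks = n_win, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, stats::mad)
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

# Distinct two-class label assignments: choose(n, n1). Exhaustive when that
# is <= n_perm, otherwise Monte-Carlo with the given seed.
permutation_labels <- function(is_tumor, n_perm, seed) {
  n <- length(is_tumor); n1 <- sum(is_tumor)
  total <- choose(n, n1)
  if (total <= n_perm) {
    idx <- utils::combn(n, n1)
    lab <- matrix(FALSE, n, ncol(idx))
    lab[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- TRUE
    list(labels = lab, exhaustive = TRUE)
  } else {
    lab <- with_seed(seed, replicate(n_perm, {
      v <- logical(n); v[sample.int(n, n1)] <- TRUE; v
    }))
    list(labels = lab, exhaustive = FALSE)
  }
}

#' SAM permutation null
#'
#' Permutes the class labels, recomputes the ordered d statistics for every
#' permutation (same s0; per-probe standard errors recomputed under each
#' relabelling), and averages them rank-wise to give the expected order
#' statistics `d_expected`. All distinct label assignments are enumerated
#' when there are no more than `n_perm` of them; otherwise `n_perm`
#' assignments are drawn at random under `seed`.
#'
#' @param x an [expr_mat()] on `log2` scale.
#' @param s0 fudge factor.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed for Monte-Carlo label draws.
#' @return A list with `d_expected` (rank-wise means, ascending),
#'   `d_perm` (probe-rank x permutation matrix of ordered permuted d),
#'   and `exhaustive` (logical).
#' @export
permutation_null <- function(x, s0, n_perm = 100, seed = 1) {
  stopifnot(inherits(x, "expr_mat"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  x <- log2_transform(x)
  pl <- permutation_labels(x$classes == "tumor", n_perm, seed)
  d_perm <- apply(pl$labels, 2, function(lab)
    sort(sam_stats(x$values, lab, s0)$d))
  list(d_expected = rowMeans(d_perm), d_perm = d_perm,
       exhaustive = pl$exhaustive)
}

# Number of elements of |sorted diff vector| >= each delta, for all deltas
# at once (diffs need not be pre-sorted).
count_exceed <- function(absdiff, deltas) {
  sorted <- sort(absdiff)
  length(sorted) - findInterval(deltas, sorted, left.open = TRUE)
}

#' Fit SAM to a two-class expression matrix
#'
#' Runs the full SAM procedure: estimates (or accepts) the fudge factor s0,
#' builds the permutation null, tabulates significant-call counts and the
#' permutation FDR distribution over a grid of delta thresholds, selects
#' delta as the largest value at which the 90th percentile of the FDR
#' distribution is zero (with at least one call), and applies a minimum
#' linear fold-change filter on the unlogged group means.
#'
#' A probe at sorted-rank i is called at threshold delta when
#' |d_(i) - d_expected_(i)| >= delta; per-permutation false-call counts at
#' the same threshold, divided by the observed call count, give the FDR
#' distribution whose percentiles drive the delta rule.
#'
#' @param x an [expr_mat()]; `signal`-scale input is log2 transformed for
#'   the statistic and its raw values reused for the fold-change filter.
#' @param s0 fudge factor; `NULL` (default) estimates it via [estimate_s0()].
#' @param n_perm number of permutations.
#' @param fold_min minimum linear fold change (calls require ratio >=
#'   `fold_min` or <= `1/fold_min`); `NULL` disables the filter.
#' @param delta_grid_size number of evenly spaced candidate deltas.
#' @param seed RNG seed for the permutation draws.
#' @param signal optional probe x sample matrix of unlogged signal values
#'   for the fold filter when `x` is already on log2 scale (defaults to
#'   `2^values`).
#' @return An object of class `sam`: list with `d`, `d_expected`, `s0`,
#'   `delta_table`, `selected_delta`, `significant` (data.frame of called
#'   probes with direction and fold change), `fold_change`, and bookkeeping
#'   fields.
#' @export
sam <- function(x, s0 = NULL, n_perm = 100, fold_min = 2,
                delta_grid_size = 200, seed = 1, signal = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$scale == "z")
    stop("SAM runs on log2 (or signal) values, not z-scores")
  if (is.null(signal))
    signal <- if (x$scale == "signal") x$values else 2^x$values
  x <- log2_transform(x)
  is_tumor <- x$classes == "tumor"
  st <- sam_stats(x$values, is_tumor, 0)
  if (is.null(s0)) s0 <- estimate_s0(st$r, st$s)
  d <- st$r / (st$s + s0)

  null <- permutation_null(x, s0, n_perm = n_perm, seed = seed)
  ord <- order(d)
  d_sorted <- d[ord]
  diff_obs <- d_sorted - null$d_expected
  absdiff <- abs(diff_obs)

  deltas <- seq(0, max(absdiff), length.out = delta_grid_size)
  n_sig <- count_exceed(absdiff, deltas)
  # FDR distribution: one FDR value per permutation, false calls divided by
  # observed calls, capped at 100%; 0/0 treated as FDR 0.
  false_counts <- apply(null$d_perm, 2, function(dp)
    count_exceed(abs(dp - null$d_expected), deltas))  # deltas x B
  fdr <- sweep(false_counts, 1, pmax(n_sig, 1), "/")
  fdr <- pmin(fdr, 1)
  fdr[n_sig == 0, ] <- 0
  delta_table <- data.frame(
    delta = deltas,
    n_significant = n_sig,
    fdr_median = 100 * apply(fdr, 1, stats::median),
    fdr_q90 = 100 * apply(fdr, 1, stats::quantile, probs = 0.9))

  # The zero-FDR deltas form a terminal interval (FDR falls as delta
  # rises); the selected delta is where the 90th-percentile FDR reaches and
  # remains zero, i.e. the smallest delta of that terminal run -- the
  # threshold giving the largest call set whose estimated FDR is still 0.
  nonzero <- which(delta_table$fdr_q90 > 0)
  first_zero <- if (length(nonzero)) nonzero[length(nonzero)] + 1L else 1L
  ok <- which(seq_along(deltas) >= first_zero &
                delta_table$n_significant >= 1)
  if (!length(ok)) {
    warning("no delta achieves 90th-percentile FDR = 0 with >= 1 call; ",
            "significant set is empty")
    selected_delta <- NA_real_
    called_ranks <- integer(0)
  } else {
    selected_delta <- deltas[min(ok)]
    called_ranks <- which(absdiff >= selected_delta)
  }

  sig1 <- rowMeans(signal[, is_tumor, drop = FALSE])
  sig2 <- rowMeans(signal[, !is_tumor, drop = FALSE])
  fold <- sig1 / sig2
  called_probes <- names(d_sorted)[called_ranks]
  if (!is.null(fold_min) && length(called_probes)) {
    f <- fold[called_probes]
    called_probes <- called_probes[f >= fold_min | f <= 1 / fold_min]
  }
  significant <- data.frame(
    probe_id = called_probes,
    gene_id = unname(x$probe_gene[called_probes]),
    d = unname(d[called_probes]),
    fold_change = unname(fold[called_probes]),
    direction = ifelse(d[called_probes] > 0, "up", "down"),
    stringsAsFactors = FALSE)

  structure(list(d = d, d_expected = null$d_expected, s0 = s0,
                 order = ord, delta_table = delta_table,
                 selected_delta = selected_delta,
                 significant = significant, fold_change = fold,
                 n_perm = ncol(null$d_perm), exhaustive = null$exhaustive,
                 fold_min = fold_min, probe_gene = x$probe_gene,
                 classes = x$classes, seed = seed),
            class = "sam")
}

#' @export
print.sam <- function(x, ...) {
  cat(sprintf("SAM fit: %d probes, %d tumor vs %d control, s0 = %.4g\n",
              length(x$d), sum(x$classes == "tumor"),
              sum(x$classes == "control"), x$s0))
  cat(sprintf("  %d permutations (%s)\n", x$n_perm,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo"))
  if (is.na(x$selected_delta)) {
    cat("  no delta with 90th-percentile FDR = 0; empty call set\n")
  } else {
    cat(sprintf("  selected delta = %.4g -> %d significant probes (fold filter %s)\n",
                x$selected_delta, nrow(x$significant),
                if (is.null(x$fold_min)) "off"
                else sprintf(">= %g-fold", x$fold_min)))
  }
  invisible(x)
}

#' @export
summary.sam <- function(object, ...) {
  print(object)
  cat("\nDelta table (every 20th row):\n")
  dt <- object$delta_table
  print(dt[seq(1, nrow(dt), by = 20), ], row.names = FALSE, digits = 4)
  invisible(object$delta_table)
}

#' SAM quantile plot
#'
#' Ordered observed d statistics against their permutation-expected values;
#' the classic SAM plot. Dashed lines mark the selected delta band and
#' called probes are highlighted.
#'
#' @param x a fitted [sam()] object.
#' @param ... passed to [plot()].
#' @export
plot.sam <- function(x, ...) {
  ds <- x$d[x$order]
  plot(x$d_expected, ds, pch = 20, cex = 0.6,
       xlab = "expected d (permutation)", ylab = "observed d", ...)
  graphics::abline(0, 1, col = "grey40")
  if (!is.na(x$selected_delta)) {
    graphics::abline(x$selected_delta, 1, lty = 2, col = "red")
    graphics::abline(-x$selected_delta, 1, lty = 2, col = "red")
    called <- names(ds) %in% x$significant$probe_id
    graphics::points(x$d_expected[called], ds[called], pch = 20,
                     cex = 0.7, col = "red")
  }
  invisible(x)
}

#' Collapse per-probe SAM calls to gene-level calls
#'
#' A gene is called when at least one of its probes is significant and no
#' probe of that gene is significant in the opposite direction; genes with
#' conflicting probe directions are dropped (and counted in the `"log"`
#' attribute). The representative fold change is taken from the probe with
#' the largest |d|.
#'
#' @param fit a fitted [sam()] object.
#' @return data.frame with columns `gene_id`, `direction`, `fold_change`.
#' @export
sam_genes <- function(fit) {
  stopifnot(inherits(fit, "sam"))
  sig <- fit$significant
  if (!nrow(sig)) {
    out <- data.frame(gene_id = character(0), direction = character(0),
                      fold_change = numeric(0), stringsAsFactors = FALSE)
    attr(out, "log") <- log_line("sam_genes: 0 calls")
    return(out)
  }
  parts <- split(sig, sig$gene_id)
  conflicts <- vapply(parts, function(p)
    length(unique(p$direction)) > 1, logical(1))
  keep <- parts[!conflicts]
  if (!length(keep)) {
    out <- data.frame(gene_id = character(0), direction = character(0),
                      fold_change = numeric(0), stringsAsFactors = FALSE)
    attr(out, "log") <- log_line("sam_genes: 0 genes (", sum(conflicts),
                                 " direction conflicts dropped)")
    return(out)
  }
  out <- do.call(rbind, lapply(keep, function(p) {
    best <- p[which.max(abs(p$d)), ]
    data.frame(gene_id = best$gene_id, direction = best$direction,
               fold_change = best$fold_change, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "log") <- log_line("sam_genes: ", nrow(out), " genes (",
                               sum(conflicts), " direction conflicts dropped)")
  out
}

#' Write per-probe SAM results and the delta table as TSV
#'
#' @param fit a fitted [sam()] object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Invisibly, the files written.
#' @export
write_sam <- function(fit, dir, prefix = "sam") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  probes <- names(fit$d)
  res <- data.frame(
    probe_id = probes,
    gene_id = unname(fit$probe_gene[probes]),
    d = unname(fit$d),
    fold_change = unname(fit$fold_change[probes]),
    called = probes %in% fit$significant$probe_id,
    direction = ifelse(fit$d > 0, "up", "down"),
    stringsAsFactors = FALSE)
  paths <- c(results = file.path(dir, paste0(prefix, "_results.tsv")),
             delta = file.path(dir, paste0(prefix, "_delta_table.tsv")))
  utils::write.table(res, paths[["results"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fit$delta_table, paths[["delta"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
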