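test_that("d statistic matches hand computation and basic invariances", {
  # one probe, tumour (2,2) vs control (1,1): pooled se is 0, d = 1/s0
  m <- matrix(c(2, 2, 1, 1), 1, 4,
              dimnames = list("p1", paste0("s", 1:4)))
  x <- make_expr(m, n_tumor = 2)
  expect_equal(unname(d_statistic(x, s0 = 0.5)), 2)

  set.seed(5)
  x2 <- make_expr(matrix(rnorm(80), 10, 8), n_tumor = 4)
  d <- d_statistic(x2, s0 = 0.3)
  # shifting every sample by a constant leaves d unchanged
  x3 <- x2; x3$values <- x3$values + 5
  expect_equal(d_statistic(x3, s0 = 0.3), d, tolerance = 1e-12)
  # identical group means give d = 0
  x4 <- make_expr(cbind(matrix(1:10, 10, 2), matrix(1:10, 10, 2)),
                  n_tumor = 2)
  expect_equal(unname(d_statistic(x4, s0 = 1)), rep(0, 10))
  # swapping class labels negates every d
  x5 <- x2
  x5$classes <- setNames(ifelse(x5$classes == "tumor", "control", "tumor"),
                         names(x5$classes))
  expect_equal(d_statistic(x5, s0 = 0.3), -d, tolerance = 1e-12)
  # a class with fewer than two samples is refused
  expect_error(d_statistic(make_expr(matrix(rnorm(30), 10, 3),
                                     n_tumor = 1), s0 = 1), ">= 2")
})

test_that("s0 estimation: argmin property, degenerate grid, homoscedastic data", {
  # constant s: the chosen s0 is that value
  expect_message(s0 <- estimate_s0(rnorm(10), rep(1, 10)), "identical")
  expect_equal(s0, 1)

  set.seed(9)
  r <- rnorm(500); s <- rep(0.5, 500) + abs(rnorm(500, 0, 0.1))
  s0 <- estimate_s0(r, s)
  # returned s0 is a grid candidate achieving the minimal CV criterion
  alphas <- seq(0, 1, by = 0.05)
  cand <- quantile(s, alphas, names = FALSE)
  n_win <- max(2L, min(100L, length(s) %/% 25L))
  win <- cut(rank(s, ties.method = "first"), breaks = n_win, labels = FALSE)
  cv <- vapply(cand, function(s0c) {
    d <- r / (s + s0c)
    v <- tapply(d, win, mad); v <- v[is.finite(v) & v > 0]
    sd(v) / mean(v)
  }, numeric(1))
  expect_equal(min(abs(cand - s0)), 0, tolerance = 1e-12)
  expect_lte(cv[which(cand == s0)[1]], min(cv) + 1e-12)

  # homoscedastic data: chosen s0 is a quantile of the observed s
  # distribution (the CV criterion may legitimately pick an extreme
  # percentile here, where it is harmless: d becomes proportional to r)
  set.seed(10)
  m <- matrix(rnorm(400 * 12, sd = 1), 400, 12)
  st <- minregnet:::sam_stats(m, rep(c(TRUE, FALSE), each = 6))
  s0h <- estimate_s0(st$r, st$s)
  expect_gte(s0h, min(st$s))
  expect_lte(s0h, max(st$s))
})

test_that("permutation null: exhaustive enumeration, determinism, agreement", {
  set.seed(2)
  x <- make_expr(matrix(rnorm(40), 10, 4), n_tumor = 2)
  # 2v2 gives choose(4,2) = 6 exhaustive assignments
  n1 <- permutation_null(x, s0 = 0.2, n_perm = 25, seed = 1)
  expect_true(n1$exhaustive)
  expect_identical(ncol(n1$d_perm), 6L)
  # exhaustive result independent of the seed
  n2 <- permutation_null(x, s0 = 0.2, n_perm = 100, seed = 99)
  expect_equal(n1$d_expected, n2$d_expected, tolerance = 1e-14)

  x8 <- make_expr(matrix(rnorm(160), 10, 16), n_tumor = 8)
  a <- permutation_null(x8, s0 = 0.2, n_perm = 40, seed = 7)
  b <- permutation_null(x8, s0 = 0.2, n_perm = 40, seed = 7)
  expect_false(a$exhaustive)
  expect_equal(a$d_expected, b$d_expected, tolerance = 1e-14)
  expect_error(permutation_null(x8, s0 = 0.2, n_perm = 0), "n_perm")
})

test_that("call counts are non-increasing in delta and fold filter applies", {
  sim <- quick_sim(seed = 21)
  pre <- preprocess(sim$expr)
  fit <- sam(pre$signal, n_perm = 40, seed = 3)
  expect_true(all(diff(fit$delta_table$n_significant) <= 0))
  expect_true(all(fit$delta_table$fdr_q90 >= 0 &
                    fit$delta_table$fdr_q90 <= 100))
  expect_false(is.na(fit$selected_delta))
  sig_d <- abs(fit$d[fit$significant$probe_id] -
                 fit$d_expected[match(fit$significant$probe_id,
                                      names(fit$d)[fit$order])])
  expect_true(all(sig_d >= fit$selected_delta - 1e-12))
  f <- fit$significant$fold_change
  expect_true(all(f >= 2 | f <= 0.5))

  # a strong but sub-threshold fold change is removed by the fold filter:
  # plant a 1.5-fold gene with tiny noise so its d is enormous
  set.seed(30)
  base <- matrix(2^rnorm(50 * 16, 8, 0.05), 50, 16)
  base[1, 1:10] <- base[1, 1:10] * 1.5
  x <- make_expr(base, n_tumor = 10, scale = "signal")
  fit2 <- sam(x, n_perm = 50, fold_min = 2, seed = 4)
  expect_false("p001" %in% fit2$significant$probe_id)
  fit3 <- sam(x, n_perm = 50, fold_min = NULL, seed = 4)
  expect_true("p001" %in% fit3$significant$probe_id)
})

test_that("gene collapse keeps agreeing probes and drops conflicts", {
  sim <- quick_sim(seed = 22)
  pre <- preprocess(sim$expr)
  fit <- sam(pre$signal, n_perm = 40, seed = 5)
  genes <- sam_genes(fit)
  expect_true(all(genes$gene_id %in% fit$probe_gene))
  expect_false(anyDuplicated(genes$gene_id) > 0)
  # construct a conflict by force: two probes of one gene, opposite calls
  fake <- fit
  fake$significant <- data.frame(
    probe_id = c("a", "b"), gene_id = c("g1", "g1"), d = c(3, -3),
    fold_change = c(4, 0.25), direction = c("up", "down"),
    stringsAsFactors = FALSE)
  expect_identical(nrow(sam_genes(fake)), 0L)
})

test_that("under the global null the full call rule makes no calls (type I)", {
  # pure-noise two-class data on the signal scale; calls require both the
  # zero-FDR delta rule and the two-fold filter, as in real selection
  calls <- vapply(1:15, function(i) {
    set.seed(700 + i)
    mu <- runif(300, 5, 11)
    m <- 2^(mu + matrix(rnorm(300 * 18, 0, 0.3), 300, 18))
    x <- make_expr(m, n_tumor = 12, scale = "signal")
    fit <- suppressWarnings(sam(x, n_perm = 40, fold_min = 2, seed = i))
    nrow(fit$significant)
  }, numeric(1))
  expect_gte(mean(calls == 0), 0.9)
  expect_equal(median(calls), 0)
})
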