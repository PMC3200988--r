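test_that("JASPAR count files round-trip and bad input is rejected", {
  sim <- quick_sim(seed = 41)
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(sim$pwms, path)
  back <- read_jaspar(path)
  expect_identical(names(back), names(sim$pwms))
  for (id in names(back)) {
    expect_equal(back[[id]]$counts, sim$pwms[[id]]$counts)
    expect_identical(back[[id]]$tf_gene, sim$pwms[[id]]$tf_gene)
  }
  empty <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(character(0), empty)
  expect_length(read_jaspar(empty), 0)
  ragged <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 TF1", "A [1 2 3 4]", "C [1 2 3]", "G [1 2 3 4]",
               "T [1 2 3 4]"), ragged)
  expect_error(read_jaspar(ragged), "M1")
})

test_that("consensus scores maximally on + and its reverse complement on -", {
  counts <- rbind(A = c(10, 0, 0, 8, 0, 0),
                  C = c(0, 10, 0, 1, 0, 0),
                  G = c(0, 0, 10, 1, 0, 10),
                  T = c(0, 0, 0, 0, 10, 0))
  p <- pwm(counts, id = "M1", tf_gene = "TFX")
  cons <- pwm_consensus(p)
  expect_identical(cons, "ACGATG")
  hits <- scan_promoter(p, cons)
  expect_identical(hits$position, 1L)
  expect_identical(hits$strand, "+")
  expect_equal(hits$score, attr(hits, "max_score"))
  rc <- minregnet:::revcomp_string(cons)
  hits_rc <- scan_promoter(p, rc)
  expect_identical(hits_rc$strand, "-")
  expect_equal(hits_rc$score, attr(hits, "max_score"))
  expect_error(scan_promoter(p, "ACGRT"), "invalid")
  expect_error(scan_promoter(p, "ACG"), "shorter")
})

test_that("scanning matches a naive per-window oracle, incl. N handling", {
  set.seed(50)
  sim <- quick_sim(seed = 42)
  p <- sim$pwms[[1]]
  n_hits <- 0
  for (i in 1:12) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    if (i > 9) substr(s, 50, 52) <- "NNN"
    got <- scan_promoter(p, s, threshold_frac = 0.2)
    want <- naive_scan(p, s, threshold_frac = 0.2)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-10)
    n_hits <- n_hits + nrow(got)
  }
  expect_gt(n_hits, 0)  # the comparison actually exercised hits
  # and at the default threshold on promoters with planted sites
  for (g in unique(sim$truth$sites$gene_id)[1:2]) {
    s <- sim$promoters[[g]]
    got <- scan_promoter(p, s)
    want <- naive_scan(p, s)
    expect_equal(got$position, want$position)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("scanning is strand-symmetric on reverse-complemented input", {
  set.seed(51)
  sim <- quick_sim(seed = 43)
  p <- sim$pwms[[2]]
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    fwd <- scan_promoter(p, s, threshold_frac = 0.65)
    rev <- scan_promoter(p, minregnet:::revcomp_string(s),
                         threshold_frac = 0.65)
    # mirrored positions, flipped strands, identical score multiset
    L <- ncol(p$counts)
    expect_setequal(rev$position, nchar(s) - L + 2 - fwd$position)
    expect_equal(sort(rev$score), sort(fwd$score), tolerance = 1e-10)
    expect_identical(sum(rev$strand == "+"), sum(fwd$strand == "-"))
  }
})

test_that("binomial p-values match the closed form and are monotone", {
  # two sites in 1986 windows at rate 1e-4, by explicit closed form
  r <- 1e-4; n <- 1986
  oracle <- 1 - (1 - r)^n - n * r * (1 - r)^(n - 1)
  expect_equal(interaction_pvalue(2, n, r), oracle, tolerance = 1e-9)
  expect_equal(interaction_pvalue(0, n, r), 1)
  pv <- vapply(0:6, interaction_pvalue, numeric(1), n_windows = n, rate = r)
  expect_true(all(diff(pv) < 0))
  expect_error(interaction_pvalue(1, n, 0), "rate")
  expect_error(interaction_pvalue(1, n, 1), "rate")
})

test_that("TF identification intersects DEGs with the PWM mapping", {
  degs <- data.frame(gene_id = c("A", "B", "C"), stringsAsFactors = FALSE)
  map <- data.frame(gene_id = c("B", "D"), pwm_id = c("M1", "M2"),
                    stringsAsFactors = FALSE)
  expect_identical(identify_tfs(degs, map), "B")
  expect_identical(identify_tfs(data.frame(gene_id = "Z"), map),
                   character(0))
  expect_error(identify_tfs(degs, map[0, ]), "empty")
})

test_that("planted edges are recovered; cutoff limits behave", {
  sim <- quick_sim(seed = 44, n_genes = 80, n_tfs = 3, edges_per_tf = 4,
                   promoter_length = 500)
  truth <- sim$truth
  degs <- truth$deg
  tfs <- truth$tf_ids
  ints <- predict_interactions(tfs, sim$promoters, degs, sim$pwms,
                               sim$tf_map, seed = 3)
  pred <- paste(ints$tf, ints$target)
  want <- paste(truth$edges$tf, truth$edges$target)
  expect_gte(length(intersect(pred, want)) / length(want), 0.8)
  expect_true(all(ints$p_value < 0.005))

  tested <- attr(ints, "tested")
  all_kept <- predict_interactions(tfs, sim$promoters, degs, sim$pwms,
                                   sim$tf_map, p_cutoff = 1.0, seed = 3)
  expect_identical(nrow(as.data.frame(all_kept)), nrow(tested))
  none <- predict_interactions(tfs, sim$promoters, degs, sim$pwms,
                               sim$tf_map, p_cutoff = 0, seed = 3)
  expect_identical(nrow(as.data.frame(none)), 0L)
  # no self-pairs, no duplicates
  expect_false(any(tested$tf == tested$target))
  expect_false(anyDuplicated(tested[, c("tf", "target")]) > 0)
})
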