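test_that("network assembly restricts to DEG nodes and copies overlay", {
  inter <- data.frame(tf = c("T1", "T2", "T1", "T1"),
                      target = c("G1", "G1", "T2", "X9"),
                      p_value = c(1e-4, 2e-4, 3e-4, 1e-5),
                      stringsAsFactors = FALSE)
  degs <- data.frame(gene_id = c("T1", "T2", "G1"),
                     direction = c("up", "down", "up"),
                     fold_change = c(4, 0.25, 8), stringsAsFactors = FALSE)
  net <- build_network(inter, degs, tfs = c("T1", "T2"))
  expect_identical(nrow(net$nodes), 3L)
  expect_identical(nrow(net$edges), 3L)  # X9 is not a DEG -> dropped
  expect_true(net$nodes$is_tf[net$nodes$gene_id == "T2"])
  expect_identical(net$nodes$direction[net$nodes$gene_id == "G1"], "up")
  s <- network_summary(net)
  expect_identical(s, list(n_tfs = 2L, n_targets = 1L, n_edges = 3L))

  empty <- build_network(inter[0, ], degs, tfs = character(0))
  expect_identical(network_summary(empty),
                   list(n_tfs = 0L, n_targets = 0L, n_edges = 0L))
})

test_that("pruning boundary: one regulator removed, two retained", {
  nodes <- data.frame(gene_id = c("T1", "T2", "G1", "G2"),
                      is_tf = c(TRUE, TRUE, FALSE, FALSE),
                      direction = "up", fold_change = 2,
                      stringsAsFactors = FALSE)
  edges <- data.frame(tf = c("T1", "T2", "T1"),
                      target = c("G1", "G1", "G2"),
                      p_value = 1e-4, stringsAsFactors = FALSE)
  min_net <- prune_minimal(reg_network(nodes, edges))
  expect_true(min_net$minimal)
  expect_true("G1" %in% min_net$nodes$gene_id)   # in-degree 2
  expect_false("G2" %in% min_net$nodes$gene_id)  # in-degree 1
  expect_identical(nrow(min_net$edges), 2L)
})

test_that("pruning equals the brute-force fixed point on random graphs", {
  for (seed in 1:40) {
    net <- rand_network(n_tf = sample(2:5, 1), n_target = sample(3:10, 1),
                        n_edges = sample(5:25, 1), seed = seed)
    got <- prune_minimal(net)
    want <- brute_prune(net$nodes, net$edges)
    expect_identical(sort(got$nodes$gene_id), want$nodes)
    expect_identical(edge_key_df(got), want$edges)
    # idempotence and monotonicity
    again <- prune_minimal(got)
    expect_identical(edge_key_df(again), edge_key_df(got))
    expect_true(all(edge_key_df(got) %in% edge_key_df(net)))
    # postcondition: every surviving non-TF target has >= 2 distinct TFs
    for (g in got$nodes$gene_id[!got$nodes$is_tf])
      expect_gte(length(unique(got$edges$tf[got$edges$target == g])), 2)
  }
})

test_that("hypergeometric p-values match exact enumeration", {
  # explicit combinatorial oracle for a universe of 1000
  p_oracle <- sum(vapply(10:30, function(k)
    choose(50, k) * choose(950, 30 - k), numeric(1))) / choose(1000, 30)
  got <- pathway_overrepresentation(
    sprintf("g%03d", 1:30),
    list(pw = c(sprintf("g%03d", 21:30), sprintf("x%03d", 1:40))),
    c(sprintf("g%03d", 1:30), sprintf("x%03d", 1:40),
      sprintf("u%03d", 1:930)))
  expect_equal(got$p_value, p_oracle, tolerance = 1e-12)
  expect_identical(got$n_overlap, 10L)

  # small universes, exhaustive check against the enumeration formula
  set.seed(60)
  for (i in 1:20) {
    N <- sample(10:60, 1)
    uni <- sprintf("u%02d", seq_len(N))
    pw <- sample(uni, sample.int(N, 1))
    sel <- sample(uni, sample.int(N, 1))
    k <- length(intersect(pw, sel))
    oracle <- sum(vapply(k:min(length(pw), length(sel)), function(j)
      choose(length(pw), j) * choose(N - length(pw), length(sel) - j),
      numeric(1))) / choose(N, length(sel))
    got <- pathway_overrepresentation(sel, list(pw = pw), uni)
    expect_equal(got$p_value, oracle, tolerance = 1e-10)
  }

  # degenerate cases: saturated overlap and zero overlap give p = 1
  uni <- sprintf("u%02d", 1:10)
  expect_equal(pathway_overrepresentation(uni, list(all = uni),
                                          uni)$p_value, 1)
  expect_equal(pathway_overrepresentation(uni[1:3],
                                          list(none = uni[8:10]),
                                          uni)$p_value, 1)
  expect_error(pathway_overrepresentation("a", list(), character(0)),
               "universe")
})

test_that("SIF and GraphML exports round-trip edge and node structure", {
  net <- rand_network(3, 6, 12, seed = 77)
  dir <- withr::local_tempdir()
  sif <- file.path(dir, "net.sif")
  write_sif(net, sif)
  back <- read_sif(sif)
  expect_identical(edge_key_df(back), edge_key_df(net))

  gml <- file.path(dir, "net.graphml")
  write_graphml(net, gml)
  back2 <- read_graphml(gml)
  expect_identical(edge_key_df(back2), edge_key_df(net))
  idx <- match(net$nodes$gene_id, back2$nodes$gene_id)
  expect_identical(back2$nodes$is_tf[idx], net$nodes$is_tf)
  expect_identical(back2$nodes$direction[idx], net$nodes$direction)
  expect_equal(sort(back2$edges$p_value), sort(net$edges$p_value))
})
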