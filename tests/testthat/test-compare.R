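test_that("edge classification partitions the focal edge set exactly", {
  focal <- rand_network(3, 6, 12, seed = 1)
  others <- list(a = rand_network(3, 6, 10, seed = 2),
                 b = rand_network(3, 6, 8, seed = 3))
  cmp <- classify_edges(focal, others)
  expect_identical(cmp$counts$n_common + cmp$counts$n_specific,
                   nrow(focal$edges))
  all_keys <- sort(c(paste(cmp$common$tf, cmp$common$target),
                     paste(cmp$specific$tf, cmp$specific$target)))
  expect_identical(all_keys, edge_key_df(focal))
  expect_length(intersect(paste(cmp$common$tf, cmp$common$target),
                          paste(cmp$specific$tf, cmp$specific$target)), 0)
  # order of the comparison networks is irrelevant to the partition
  cmp2 <- classify_edges(focal, rev(others))
  expect_setequal(paste(cmp2$common$tf, cmp2$common$target),
                  paste(cmp$common$tf, cmp$common$target))
})

test_that("degenerate comparisons: empty others, containment, mismatch", {
  focal <- rand_network(2, 4, 6, seed = 5)
  cmp <- classify_edges(focal, list())
  expect_identical(cmp$counts$n_common, 0L)
  expect_identical(cmp$counts$n_specific, nrow(focal$edges))

  cmp2 <- classify_edges(focal, list(self = focal))
  expect_identical(cmp2$counts$n_specific, 0L)
  expect_identical(cmp2$counts$n_common, nrow(focal$edges))
  expect_setequal(cmp2$shared_tfs,
                  focal$nodes$gene_id[focal$nodes$is_tf])

  alien <- rand_network(2, 4, 6, seed = 6)
  alien$nodes$gene_id <- paste0("Z_", alien$nodes$gene_id)
  alien$edges$tf <- paste0("Z_", alien$edges$tf)
  alien$edges$target <- paste0("Z_", alien$edges$target)
  expect_warning(classify_edges(focal, list(alien = alien)), "namespace")
})

test_that("union_composite is associative, commutative, and dedupes by min p", {
  a <- rand_network(3, 5, 8, seed = 11)
  b <- rand_network(3, 5, 8, seed = 12)
  c3 <- rand_network(3, 5, 8, seed = 13)
  u_abc <- union_composite(list(a, b, c3))
  u_cab <- union_composite(list(c3, a, b))
  u_nested <- union_composite(list(union_composite(list(a, b)), c3))
  expect_identical(edge_key_df(u_abc), edge_key_df(u_cab))
  expect_identical(edge_key_df(u_abc), edge_key_df(u_nested))
  expect_identical(edge_key_df(u_abc),
                   sort(unique(c(edge_key_df(a), edge_key_df(b),
                                 edge_key_df(c3)))))
  expect_identical(edge_key_df(union_composite(list(a))), edge_key_df(a))

  # shared edge keeps the smallest p-value
  e1 <- data.frame(tf = "T1", target = "G1", p_value = 0.004,
                   stringsAsFactors = FALSE)
  e2 <- data.frame(tf = "T1", target = "G1", p_value = 0.001,
                   stringsAsFactors = FALSE)
  nodes <- data.frame(gene_id = c("T1", "G1"), is_tf = c(TRUE, FALSE),
                      direction = c("up", "down"), fold_change = c(2, 0.3),
                      stringsAsFactors = FALSE)
  u <- union_composite(list(reg_network(nodes, e1),
                            reg_network(nodes, e2)))
  expect_equal(u$edges$p_value, 0.001)

  # conflicting node directions are flagged
  nodes2 <- nodes; nodes2$direction <- c("down", "down")
  u2 <- union_composite(list(reg_network(nodes, e1),
                             reg_network(nodes2, e2)))
  expect_identical(attr(u2, "direction_conflicts"), "T1")
  expect_true(is.na(u2$nodes$direction[u2$nodes$gene_id == "T1"]))
})

test_that("paired simulations sharing a planted subnetwork yield common edges", {
  # two studies over the same gene universe and the same planted network,
  # differing only in expression noise seed: their recovered networks must
  # share the planted edges found in both
  sim <- quick_sim(seed = 71, n_genes = 80, n_tfs = 3, edges_per_tf = 4,
                   promoter_length = 500)
  truth_keys <- paste(sim$truth$edges$tf, sim$truth$edges$target)
  ints1 <- predict_interactions(sim$truth$tf_ids, sim$promoters,
                                sim$truth$deg, sim$pwms, sim$tf_map,
                                seed = 1)
  ints2 <- predict_interactions(sim$truth$tf_ids, sim$promoters,
                                sim$truth$deg, sim$pwms, sim$tf_map,
                                seed = 2)
  n1 <- build_network(ints1, sim$truth$deg, sim$truth$tf_ids)
  n2 <- build_network(ints2, sim$truth$deg, sim$truth$tf_ids)
  cmp <- classify_edges(n1, list(rep2 = n2))
  common_keys <- paste(cmp$common$tf, cmp$common$target)
  in_both <- intersect(edge_key_df(n1), edge_key_df(n2))
  shared_truth <- intersect(truth_keys, in_both)
  expect_gte(length(intersect(common_keys, shared_truth)) /
               max(length(shared_truth), 1), 0.8)
})
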