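# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# Small two-class expr_mat from a plain matrix (probes auto-named).
make_expr <- function(m, n_tumor, scale = "log2", probe_gene = NULL) {
  rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  classes <- stats::setNames(
    rep(c("tumor", "control"), c(n_tumor, ncol(m) - n_tumor)), colnames(m))
  if (is.null(probe_gene))
    probe_gene <- stats::setNames(sub("^p", "g", rownames(m)), rownames(m))
  expr_mat(m, classes, probe_gene, scale = scale)
}

# Naive O(n^3) UPGMA returning the cophenetic distance matrix: clusters are
# merged greedily on the arithmetic-mean distance, members recorded at each
# merge height.
naive_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  coph <- matrix(0, n, n)
  dm <- d
  while (length(active) > 1) {
    best <- c(NA, NA); best_val <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i < j && dm[active[i], active[j]] < best_val) {
        best_val <- dm[active[i], active[j]]
        best <- c(active[i], active[j])
      }
    }
    a <- best[1]; b <- best[2]
    for (x in members[[a]]) for (y in members[[b]])
      coph[x, y] <- coph[y, x] <- best_val
    # UPGMA update: distance to the merged cluster is the size-weighted mean
    na <- length(members[[a]]); nb <- length(members[[b]])
    for (k in setdiff(active, c(a, b)))
      dm[a, k] <- dm[k, a] <- (na * dm[a, k] + nb * dm[b, k]) / (na + nb)
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
  }
  coph
}

# Brute-force two-class SAM: per-probe loops, exhaustive label enumeration.
brute_sam_d <- function(m, is_tumor, s0) {
  apply(m, 1, function(v) {
    x1 <- v[is_tumor]; x2 <- v[!is_tumor]
    n1 <- length(x1); n2 <- length(x2)
    s <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) *
                (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)))
    (mean(x1) - mean(x2)) / (s + s0)
  })
}

brute_sam_d_expected <- function(m, n_tumor, s0) {
  n <- ncol(m)
  combos <- utils::combn(n, n_tumor)
  sorted <- apply(combos, 2, function(idx) {
    lab <- seq_len(n) %in% idx
    sort(brute_sam_d(m, lab, s0))
  })
  rowMeans(sorted)
}

# Character-by-character PWM scan, both strands, no vectorization.
naive_scan <- function(p, sequence, threshold_frac = 0.8) {
  probs <- sweep(p$counts + p$pseudocount, 2,
                 colSums(p$counts + p$pseudocount), "/")
  lom <- log2(sweep(probs, 1, p$background, "/"))
  L <- ncol(lom)
  chars <- strsplit(toupper(sequence), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  thr <- threshold_frac * sum(apply(lom, 2, max))
  hits <- list()
  for (pos in seq_len(length(chars) - L + 1)) {
    win <- chars[pos:(pos + L - 1)]
    if (any(win == "N")) next
    fwd <- sum(vapply(seq_len(L), function(j)
      lom[win[j], j], numeric(1)))
    rcw <- rev(unname(comp[win]))
    rev_score <- sum(vapply(seq_len(L), function(j)
      lom[rcw[j], j], numeric(1)))
    if (fwd >= thr)
      hits[[length(hits) + 1]] <- data.frame(position = pos, strand = "+",
                                             score = fwd)
    if (rev_score >= thr)
      hits[[length(hits) + 1]] <- data.frame(position = pos, strand = "-",
                                             score = rev_score)
  }
  if (!length(hits))
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

# Brute-force minimal-network pruning: recompute all in-degrees from
# scratch every pass until nothing changes.
brute_prune <- function(nodes, edges) {
  repeat {
    changed <- FALSE
    for (g in nodes$gene_id[!nodes$is_tf]) {
      indeg <- length(unique(edges$tf[edges$target == g]))
      if (indeg < 2) {
        nodes <- nodes[nodes$gene_id != g, , drop = FALSE]
        edges <- edges[edges$target != g, , drop = FALSE]
        changed <- TRUE
      }
    }
    for (g in nodes$gene_id[nodes$is_tf]) {
      if (!g %in% c(edges$tf, edges$target)) {
        nodes <- nodes[nodes$gene_id != g, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(nodes = sort(nodes$gene_id),
       edges = sort(paste(edges$tf, edges$target)))
}

# Random directed TF->target graph as a reg_network.
rand_network <- function(n_tf, n_target, n_edges, seed) {
  set.seed(seed)
  tfs <- sprintf("TF%02d", seq_len(n_tf))
  tgs <- sprintf("G%02d", seq_len(n_target))
  all_pairs <- expand.grid(tf = tfs, target = c(tfs, tgs),
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$tf != all_pairs$target, ]
  edges <- all_pairs[sample.int(nrow(all_pairs),
                                min(n_edges, nrow(all_pairs))), ]
  edges$p_value <- round(runif(nrow(edges)), 4)
  ids <- sort(unique(c(edges$tf, edges$target, tfs, tgs)))
  nodes <- data.frame(gene_id = ids, is_tf = ids %in% tfs,
                      direction = sample(c("up", "down"), length(ids),
                                         replace = TRUE),
                      fold_change = round(2^runif(length(ids), -3, 3), 3),
                      stringsAsFactors = FALSE)
  reg_network(nodes, edges)
}

edge_key_df <- function(net) sort(paste(net$edges$tf, net$edges$target))

# A quick simulated study at reduced scale for unit tests.
quick_sim <- function(seed = 1, ...) {
  args <- list(n_tumor = 16, n_control = 6, n_genes = 120, n_tfs = 3,
               edges_per_tf = 2, promoter_length = 300, noise_sd = 0.25,
               n_outliers = 1, seed = seed)
  args[names(list(...))] <- list(...)
  simulate_study(do.call(sim_config, args))
}
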