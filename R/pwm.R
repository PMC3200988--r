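# Position-weight-matrix promoter analysis: JASPAR count-matrix IO,
# log-odds scanning of both strands, an empirical background site rate from
# Markov-shuffled promoters, and a binomial over-representation p-value per
# TF-target pair. This reproduces the interface of promoter-analysis
# services (TF, target, p-value at a fixed cutoff) with a single-genome
# scoring model.

DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param counts 4 x L non-negative count matrix, rows A, C, G, T.
#' @param id matrix identifier (e.g. a JASPAR-style accession).
#' @param tf_gene gene ID of the transcription factor the motif belongs to
#'   (may be `NA` when the mapping is supplied separately).
#' @param pseudocount smoothing constant added to every count.
#' @param background base frequencies (A, C, G, T), summing to 1.
#' @return An object of class `pwm`.
#' @export
pwm <- function(counts, id, tf_gene = NA_character_, pseudocount = 0.5,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM needs 4 rows (A, C, G, T)")
  if (ncol(counts) < 4) stop("PWM must be at least 4 columns long")
  if (any(counts < 0)) stop("PWM counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop("PWM column sums must be positive")
  if (abs(sum(background) - 1) > 1e-8)
    stop("background frequencies must sum to 1")
  rownames(counts) <- DNA
  structure(list(id = id, tf_gene = tf_gene, counts = counts,
                 pseudocount = pseudocount, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (TF gene %s): length %d, information %.2f bits/column\n",
              x$id, x$tf_gene, ncol(x$counts), pwm_information(x)))
  invisible(x)
}

# Column probabilities with pseudocount smoothing.
pwm_probs <- function(p) {
  c0 <- p$counts + p$pseudocount
  sweep(c0, 2, colSums(c0), "/")
}

#' Mean information content per column (bits)
#'
#' @param p a [pwm()].
#' @return Average of `2 - H(column)` over columns, in bits.
#' @export
pwm_information <- function(p) {
  pr <- pwm_probs(p)
  mean(2 + colSums(pr * log2(pr)))
}

#' Log-odds scoring matrix of a PWM
#'
#' @param p a [pwm()].
#' @return 4 x L matrix of `log2(p_base / background_base)` scores.
#' @export
pwm_logodds <- function(p) {
  log2(pwm_probs(p) / p$background)
}

#' Consensus sequence (most probable base per column)
#'
#' @param p a [pwm()].
#' @return Character string of length L.
#' @export
pwm_consensus <- function(p) {
  paste(DNA[apply(p$counts, 2, which.max)], collapse = "")
}

# Reverse complement of a PWM: reverse columns, swap A<->T and C<->G, so
# minus-strand sites can be scored in forward coordinates.
pwm_revcomp <- function(p) {
  rc <- p$counts[c(4, 3, 2, 1), rev(seq_len(ncol(p$counts))), drop = FALSE]
  rownames(rc) <- DNA
  pwm(rc, id = p$id, tf_gene = p$tf_gene, pseudocount = p$pseudocount,
      background = p$background[c(4, 3, 2, 1)])
}

#' Read a JASPAR count-matrix file
#'
#' Parses the bracketed JASPAR (2016-style) format:
#' ```
#' >MA0001.1 NAME
#' A  [ 4 19  0 ... ]
#' C  [16  0 20 ... ]
#' ...
#' ```
#' Row order A, C, G, T is preserved. The motif name field is taken as the
#' TF gene ID when present.
#'
#' @param path file path.
#' @param pseudocount,background forwarded to [pwm()].
#' @return Named list of [pwm()] objects (names = matrix IDs).
#' @export
read_jaspar <- function(path, pseudocount = 0.5, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  hdr <- grep("^>", lines)
  if (!length(hdr) || hdr[1] != 1)
    stop("not a JASPAR matrix file: ", path)
  out <- list()
  bounds <- c(hdr, length(lines) + 1)
  for (k in seq_along(hdr)) {
    block <- lines[(bounds[k] + 1):(bounds[k + 1] - 1)]
    fields <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "\\s+")[[1]]
    id <- fields[1]
    name <- if (length(fields) > 1) fields[2] else NA_character_
    if (length(block) != 4)
      stop("matrix ", id, ": expected 4 base rows, got ", length(block))
    rows <- lapply(block, function(l) {
      nums <- sub("^[ACGTacgt]\\s*\\[?", "", l)
      nums <- sub("\\]\\s*$", "", nums)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    if (length(unique(vapply(rows, length, integer(1)))) != 1)
      stop("matrix ", id, ": ragged rows")
    bases <- toupper(substr(trimws(block), 1, 1))
    if (!identical(bases, DNA))
      stop("matrix ", id, ": rows must be ordered A, C, G, T")
    out[[id]] <- pwm(do.call(rbind, rows), id = id, tf_gene = name,
                     pseudocount = pseudocount, background = background)
  }
  out
}

#' Write PWMs in JASPAR count format
#'
#' @param pwms list of [pwm()] objects.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id,
                       if (is.na(p$tf_gene)) "" else p$tf_gene), con)
    for (i in 1:4) {
      writeLines(sprintf("%s  [ %s ]", DNA[i],
                         paste(format(p$counts[i, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

# Encode a sequence string as integer codes 1..4 (A,C,G,T); N -> NA.
encode_seq <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- !chars %in% c(DNA, "N")
  if (any(bad))
    stop("invalid sequence characters: ",
         paste(unique(chars[bad]), collapse = ", "))
  match(chars, DNA)
}

# Window scores of a log-odds matrix along an encoded sequence; windows
# containing N score NA.
window_scores <- function(code, lom) {
  L <- ncol(lom)
  n_win <- length(code) - L + 1
  if (n_win < 1) return(numeric(0))
  sc <- numeric(n_win)
  for (j in seq_len(L)) {
    sc <- sc + lom[, j][code[j:(j + n_win - 1)]]
  }
  sc
}

#' Scan a promoter sequence with a PWM
#'
#' Scores every window on both strands with the log2 odds of the smoothed
#' PWM against its background and reports windows scoring at least
#' `threshold_frac` of the maximum attainable score. Minus-strand hits are
#' scored via the reverse-complemented matrix and reported at their
#' forward-strand start coordinate (1-based). Windows containing `N` are
#' skipped.
#'
#' @param p a [pwm()].
#' @param sequence character string over A, C, G, T, N.
#' @param threshold_frac fraction of the maximum attainable log-odds score
#'   required to call a site (default 0.8).
#' @return data.frame with `position`, `strand` (`+`/`-`) and `score`,
#'   ordered by position then strand.
#' @export
scan_promoter <- function(p, sequence, threshold_frac = 0.8) {
  stopifnot(inherits(p, "pwm"))
  code <- encode_seq(sequence)
  lom <- pwm_logodds(p)
  if (length(code) < ncol(lom))
    stop("sequence shorter than the motif")
  max_score <- sum(apply(lom, 2, max))
  thr <- threshold_frac * max_score
  fwd <- window_scores(code, lom)
  rev <- window_scores(code, pwm_logodds(pwm_revcomp(p)))
  pos_f <- which(!is.na(fwd) & fwd >= thr)
  pos_r <- which(!is.na(rev) & rev >= thr)
  hits <- data.frame(position = c(pos_f, pos_r),
                     strand = rep(c("+", "-"),
                                  c(length(pos_f), length(pos_r))),
                     score = c(fwd[pos_f], rev[pos_r]),
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "max_score") <- max_score
  attr(hits, "n_windows") <- 2 * sum(!is.na(fwd))
  hits
}

# First-order-Markov resample of a sequence: new sequences of the same
# length drawn from the transition frequencies of the original, preserving
# its dinucleotide composition in expectation. Used only for background
# site-rate estimation. All n chains are advanced together, one position
# per step, so the R-level loop is over sequence length only.
markov_shuffle <- function(code, n = 1) {
  from <- code[-length(code)]; to <- code[-1]
  ok <- !is.na(from) & !is.na(to)
  trans <- matrix(1e-9, 4, 4)
  counts <- table(factor(from[ok], 1:4), factor(to[ok], 1:4))
  trans <- trans + as.matrix(counts)
  cum <- t(apply(trans / rowSums(trans), 1, cumsum))
  start_p <- tabulate(code[!is.na(code)], 4)
  len <- length(code)
  out <- matrix(0L, len, n)
  out[1, ] <- sample.int(4, n, replace = TRUE, prob = start_p)
  for (i in seq_len(len)[-1]) {
    u <- stats::runif(n)
    prev <- out[i - 1, ]
    out[i, ] <- 1L + (u > cum[prev, 1]) + (u > cum[prev, 2]) +
      (u > cum[prev, 3])
  }
  lapply(seq_len(n), function(j) out[, j])
}

# Shared background set: Markov shuffles of every promoter, encoded, so
# one set serves every PWM being calibrated.
shuffle_background <- function(codes, n_shuffle, seed) {
  with_seed(seed, {
    unlist(lapply(codes, function(code) {
      if (length(code) < 2) return(list())
      markov_shuffle(code, n_shuffle)
    }), recursive = FALSE)
  })
}

# Background rate of one PWM over pre-shuffled encoded sequences.
rate_from_background <- function(p, shuffled_codes, threshold_frac) {
  lom <- pwm_logodds(p)
  lom_rc <- pwm_logodds(pwm_revcomp(p))
  thr <- threshold_frac * sum(apply(lom, 2, max))
  hits <- 0; windows <- 0
  for (sh in shuffled_codes) {
    if (length(sh) < ncol(lom)) next
    f <- window_scores(sh, lom)
    r <- window_scores(sh, lom_rc)
    hits <- hits + sum(f >= thr, na.rm = TRUE) + sum(r >= thr, na.rm = TRUE)
    windows <- windows + 2 * length(f)
  }
  if (windows == 0) stop("no scannable windows in background promoters")
  rate <- (hits + 0.5) / (windows + 1)
  min(max(rate, .Machine$double.xmin), 1 - 1e-12)
}

#' Estimate the background site rate of a PWM
#'
#' Scans first-order-Markov shuffled copies of the supplied promoters
#' (dinucleotide composition preserved in expectation) and returns the
#' per-window, per-strand site rate. Half a pseudo-hit is added so the rate
#' is strictly positive even when no background site is found.
#'
#' @param p a [pwm()].
#' @param sequences character vector of promoter sequences.
#' @param n_shuffle shuffled copies per promoter (default 10).
#' @param threshold_frac score threshold forwarded to the scan.
#' @param seed RNG seed for the shuffles.
#' @return Site rate in (0, 1).
#' @export
background_site_rate <- function(p, sequences, n_shuffle = 10,
                                 threshold_frac = 0.8, seed = 1) {
  codes <- lapply(sequences, encode_seq)
  shuffled <- shuffle_background(codes, n_shuffle, seed)
  rate_from_background(p, shuffled, threshold_frac)
}

#' Binomial over-representation p-value for a TF-promoter pair
#'
#' Upper-tail binomial probability of observing at least `n_sites` hits in
#' the promoter's `2 * (len - L + 1)` scan windows (both strands) at the
#' background site rate.
#'
#' @param n_sites observed site count.
#' @param n_windows number of scan windows (both strands).
#' @param rate background site rate per window, in (0, 1).
#' @return p-value in [0, 1]; `n_sites = 0` gives exactly 1.
#' @export
interaction_pvalue <- function(n_sites, n_windows, rate) {
  if (rate <= 0 || rate >= 1)
    stop("background site rate must lie strictly in (0, 1)")
  if (n_sites <= 0) return(1)
  stats::pbinom(n_sites - 1, n_windows, rate, lower.tail = FALSE)
}

#' Identify transcription factors among differentially expressed genes
#'
#' @param degs a `deg_set` (or data.frame with a `gene_id` column).
#' @param tf_mapping data.frame with columns `gene_id` and `pwm_id` linking
#'   TF genes to their motifs.
#' @return Character vector of DEG gene IDs that map to at least one PWM.
#' @export
identify_tfs <- function(degs, tf_mapping) {
  if (inherits(degs, "deg_set")) degs <- degs$genes
  if (!nrow(tf_mapping)) stop("TF mapping table is empty")
  sort(intersect(unique(degs$gene_id), unique(tf_mapping$gene_id)))
}

#' Predict TF-target interactions by promoter over-representation
#'
#' For every (TF, DEG target) pair, counts PWM sites in the target's
#' promoter, compares the count to a background rate estimated from
#' Markov-shuffled promoters, and keeps pairs whose binomial upper-tail
#' p-value falls below the cutoff. TF-TF pairs are tested when the target
#' is itself a TF; self-pairs are skipped. Targets without a promoter are
#' skipped with a note in the `"log"` attribute.
#'
#' @param tfs character vector of TF gene IDs (e.g. from [identify_tfs()]).
#' @param promoters named character vector (or `Biostrings::DNAStringSet`)
#'   of promoter sequences keyed by gene ID.
#' @param degs a `deg_set` or data.frame with `gene_id`; defines the
#'   candidate target universe.
#' @param pwms named list of [pwm()] objects.
#' @param tf_mapping data.frame (`gene_id`, `pwm_id`).
#' @param p_cutoff retain pairs with `p_value < p_cutoff` (default 0.005).
#' @param threshold_frac site-score threshold fraction.
#' @param n_shuffle shuffles per promoter for the background rate.
#' @param seed RNG seed for the shuffles.
#' @return An object of class `interaction_set`: data.frame of retained
#'   interactions (`tf`, `target`, `p_value`, `n_sites`, `best_score`) with
#'   the cutoff and the full tested table as attributes.
#' @export
predict_interactions <- function(tfs, promoters, degs, pwms, tf_mapping,
                                 p_cutoff = 0.005, threshold_frac = 0.8,
                                 n_shuffle = 10, seed = 1) {
  if (inherits(degs, "deg_set")) degs <- degs$genes
  promoters <- as_promoter_vector(promoters)
  targets <- unique(degs$gene_id)
  logs <- character(0)
  missing <- setdiff(targets, names(promoters))
  if (length(missing)) {
    logs <- c(logs, log_line("predict_interactions: ", length(missing),
                             " target(s) without promoter skipped"))
    targets <- setdiff(targets, missing)
  }
  # one shared Markov-shuffled background set calibrates every PWM
  codes <- lapply(promoters[targets], encode_seq)
  shuffled <- if (length(targets))
    shuffle_background(codes, n_shuffle, child_seed(seed, "shuffle"))
  else list()
  rows <- list()
  for (tf in tfs) {
    pwm_ids <- tf_mapping$pwm_id[tf_mapping$gene_id == tf]
    pwm_ids <- intersect(pwm_ids, names(pwms))
    if (!length(pwm_ids)) next
    p <- pwms[[pwm_ids[1]]]
    rate <- rate_from_background(p, shuffled, threshold_frac)
    for (tg in setdiff(targets, tf)) {
      hits <- scan_promoter(p, promoters[[tg]],
                            threshold_frac = threshold_frac)
      pv <- interaction_pvalue(nrow(hits), attr(hits, "n_windows"), rate)
      rows[[length(rows) + 1]] <- data.frame(
        tf = tf, target = tg, p_value = pv, n_sites = nrow(hits),
        best_score = if (nrow(hits)) max(hits$score) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tested <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(0), target = character(0),
               p_value = numeric(0), n_sites = integer(0),
               best_score = numeric(0), stringsAsFactors = FALSE)
  # a cutoff of 1 is vacuous (keeps even zero-site pairs, whose p is 1)
  keep <- if (p_cutoff >= 1) rep(TRUE, nrow(tested)) else
    tested$p_value < p_cutoff
  kept <- tested[keep, , drop = FALSE]
  rownames(kept) <- NULL
  structure(kept, class = c("interaction_set", "data.frame"),
            p_cutoff = p_cutoff, tested = tested, log = logs)
}

as_promoter_vector <- function(promoters) {
  if (inherits(promoters, "DNAStringSet")) {
    stats::setNames(as.character(promoters), names(promoters))
  } else {
    stopifnot(is.character(promoters), !is.null(names(promoters)))
    promoters
  }
}

#' Write an interaction set as TSV
#'
#' @param x an `interaction_set`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_interactions <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
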