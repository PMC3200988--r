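# The expression container used throughout: probe x sample signal values
# with sample class labels, MAS5-style P/M/A detection flags, and a
# probe -> gene annotation. The `scale` tag tracks whether values are raw
# signal, log2 signal, or per-probe z-scores.

#' Construct an expression matrix object
#'
#' Bundles a probe-by-sample value matrix with sample class labels
#' (`tumor` / `control`), optional detection flags (`P`/`M`/`A`, as produced
#' by MAS 5.0), and a probe-to-gene annotation. Most pipeline stages consume
#' and return this container.
#'
#' @param values numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample IDs).
#' @param classes named character vector mapping every sample ID to
#'   `"tumor"` or `"control"`.
#' @param probe_gene named character vector mapping probe IDs to gene IDs.
#' @param detection optional character matrix of `P`/`M`/`A` flags with the
#'   same dimnames as `values`.
#' @param scale one of `"signal"`, `"log2"`, `"z"`.
#' @return An object of class `expr_mat`.
#' @export
expr_mat <- function(values, classes, probe_gene,
                     detection = NULL, scale = "signal") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in expression matrix")
  scale <- match.arg(scale, c("signal", "log2", "z"))
  missing_cls <- setdiff(colnames(values), names(classes))
  if (length(missing_cls))
    stop("samples missing from class annotation: ",
         paste(missing_cls, collapse = ", "))
  classes <- classes[colnames(values)]
  if (!all(classes %in% c("tumor", "control")))
    stop("sample classes must be 'tumor' or 'control'")
  if (!is.null(detection)) {
    if (!identical(dim(detection), dim(values)))
      stop("detection flags must match the value matrix dimensions")
    dimnames(detection) <- dimnames(values)
    if (!all(detection %in% c("P", "M", "A")))
      stop("detection flags must be P, M or A")
  }
  missing_ann <- setdiff(rownames(values), names(probe_gene))
  if (length(missing_ann))
    stop("probes missing from annotation: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  probe_gene <- probe_gene[rownames(values)]
  structure(list(values = values, classes = classes,
                 probe_gene = probe_gene, detection = detection,
                 scale = scale),
            class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("expr_mat: %d probes x %d samples (%d tumor, %d control), %s scale\n",
              nrow(x$values), ncol(x$values),
              sum(x$classes == "tumor"), sum(x$classes == "control"),
              x$scale))
  if (!is.null(x$detection))
    cat(sprintf("  detection flags present (%.1f%% 'A')\n",
                100 * mean(x$detection == "A")))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Subset an expression matrix by probes and/or samples
#'
#' @param x an [expr_mat()].
#' @param probes,samples character vectors of IDs to keep (default all).
#' @return A new `expr_mat`.
#' @export
subset_expr <- function(x, probes = rownames(x$values),
                        samples = colnames(x$values)) {
  expr_mat(x$values[probes, samples, drop = FALSE],
           x$classes[samples],
           x$probe_gene[probes],
           detection = if (!is.null(x$detection))
             x$detection[probes, samples, drop = FALSE],
           scale = x$scale)
}

#' Convert signal-scale values to log2
#'
#' @param x an [expr_mat()] on `signal` scale.
#' @param offset constant added before the log to guard zero signals.
#' @return The matrix on `log2` scale.
#' @export
log2_transform <- function(x, offset = 1) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$scale == "log2") return(x)
  if (x$scale != "signal")
    stop("log2_transform expects signal-scale values")
  x$values <- log2(x$values + offset)
  x$scale <- "log2"
  x
}

#' Sample IDs by class
#'
#' @param x an [expr_mat()].
#' @return Character vector of sample IDs.
#' @export
tumor_ids <- function(x) names(x$classes)[x$classes == "tumor"]

#' @rdname tumor_ids
#' @export
control_ids <- function(x) names(x$classes)[x$classes == "control"]

#' Read an expression matrix from TSV files
#'
#' Expects the layout written by [write_expression()]: a value TSV with probe
#' IDs in the first column and sample IDs as header; a two-column class TSV
#' (`sample_id`, `class`); a two-column annotation TSV (`probe_id`,
#' `gene_id`); and optionally a parallel detection-flag TSV.
#'
#' @param values_path,classes_path,annotation_path,detection_path file paths;
#'   `detection_path` may be `NULL`.
#' @param scale scale tag of the stored values.
#' @return An [expr_mat()].
#' @export
read_expression <- function(values_path, classes_path, annotation_path,
                            detection_path = NULL, scale = "signal") {
  vals <- utils::read.delim(values_path, check.names = FALSE)
  if (anyDuplicated(vals[[1]]))
    stop("duplicate probe IDs in ", values_path)
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- as.character(vals[[1]])
  cls <- utils::read.delim(classes_path, check.names = FALSE)
  classes <- stats::setNames(as.character(cls$class),
                             as.character(cls$sample_id))
  ann <- utils::read.delim(annotation_path, check.names = FALSE)
  probe_gene <- stats::setNames(as.character(ann$gene_id),
                                as.character(ann$probe_id))
  det <- NULL
  if (!is.null(detection_path)) {
    d <- utils::read.delim(detection_path, check.names = FALSE)
    det <- as.matrix(d[, -1, drop = FALSE])
    rownames(det) <- as.character(d[[1]])
    det <- det[rownames(m), colnames(m), drop = FALSE]
  }
  expr_mat(m, classes, probe_gene, detection = det, scale = scale)
}

#' Write an expression matrix to TSV files
#'
#' @param x an [expr_mat()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of files written.
#' @export
write_expression <- function(x, dir, prefix = "expression") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(values = file.path(dir, paste0(prefix, "_values.tsv")),
             classes = file.path(dir, paste0(prefix, "_classes.tsv")),
             annotation = file.path(dir, paste0(prefix, "_probes.tsv")))
  write_tsv_matrix(x$values, paths[["values"]], id_col = "probe_id")
  utils::write.table(
    data.frame(sample_id = names(x$classes), class = unname(x$classes)),
    paths[["classes"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(probe_id = names(x$probe_gene), gene_id = unname(x$probe_gene)),
    paths[["annotation"]], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$detection)) {
    paths[["detection"]] <- file.path(dir, paste0(prefix, "_detection.tsv"))
    write_tsv_matrix(x$detection, paths[["detection"]], id_col = "probe_id")
  }
  invisible(paths)
}

write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
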