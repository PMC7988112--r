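#' Expression matrix with per-sample annotations
#'
#' The central data container of the package: a genes x samples numeric
#' matrix plus a per-sample annotation table, analogous to a `DGEList` but
#' covering both RNA-seq counts and microarray log2 intensities.
#'
#' @param values Numeric matrix with unique rownames (gene or probe IDs) and
#'   unique colnames (sample IDs). For `value_kind = "counts"` all entries
#'   must be non-negative integers.
#' @param value_kind One of `"counts"`, `"log_intensity"`, `"tpm"`.
#' @param samples Optional data.frame of per-sample annotations, one row per
#'   sample (matched by a `sample` column or rownames). Recognised columns:
#'   `group`, `lesional` (`control`/`lesional`/`nonlesional`), `scorad`,
#'   `subject`, `timepoint` (`baseline`/`week2`/`week12`). Samples present in
#'   `values` but not annotated get `NA` fields.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix), `value_kind`, and `samples` (annotation data.frame keyed
#'   by `sample`).
#' @export
expression_matrix <- function(values, value_kind = c("counts", "log_intensity", "tpm"),
                              samples = NULL) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene rownames and sample colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene IDs: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  if (anyNA(values)) stop("expression values must not contain NA")
  if (value_kind %in% c("counts", "tpm")) {
    neg <- which(values < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      stop(sprintf("negative values not allowed for value_kind='%s' (e.g. gene %s, sample %s)",
                   value_kind, rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
    }
  }
  if (value_kind == "counts" && any(values != round(values)))
    stop("counts must be integers")

  ann <- normalize_sample_annotations(samples, colnames(values))
  structure(list(values = values, value_kind = value_kind, samples = ann),
            class = "expr_matrix")
}

ANNOTATION_COLS <- c("group", "lesional", "scorad", "subject", "timepoint")

normalize_sample_annotations <- function(samples, sample_ids) {
  ann <- data.frame(sample = sample_ids, stringsAsFactors = FALSE)
  for (cl in ANNOTATION_COLS) ann[[cl]] <- rep(NA, length(sample_ids))
  ann$scorad <- as.numeric(ann$scorad)
  if (!is.null(samples)) {
    samples <- as.data.frame(samples)
    if (!"sample" %in% names(samples)) {
      if (is.null(rownames(samples))) stop("sample annotations need a 'sample' column or rownames")
      samples$sample <- rownames(samples)
    }
    if (anyDuplicated(samples$sample))
      stop("duplicate sample IDs in annotations")
    idx <- match(sample_ids, samples$sample)
    for (cl in intersect(ANNOTATION_COLS, names(samples))) {
      v <- samples[[cl]][idx]
      if (cl == "scorad") v <- as.numeric(v)
      else v <- as.character(v)
      ann[[cl]] <- v
    }
    ok <- !is.na(ann$lesional)
    if (any(ok & !ann$lesional[ok] %in% c("control", "lesional", "nonlesional")))
      stop("lesional must be one of control/lesional/nonlesional or NA")
    if (any(!is.na(ann$scorad) & ann$scorad < 0)) stop("scorad must be non-negative")
  }
  rownames(ann) <- NULL
  ann
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  grp <- x$samples$group
  if (!all(is.na(grp))) {
    tb <- table(grp, useNA = "no")
    cat("groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An object.
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_matrix")

#' Subset an expression matrix
#'
#' @param x An `expr_matrix`.
#' @param genes,samples Character vectors (or NULL to keep all). Order of the
#'   selection is preserved.
#' @return An `expr_matrix` restricted to the requested rows/columns.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  stopifnot(is_expr_matrix(x))
  v <- x$values
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss)) stop("genes not present: ", paste(utils::head(miss, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(v))
    if (length(miss)) stop("samples not present: ", paste(utils::head(miss, 5), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  ann <- x$samples[match(colnames(v), x$samples$sample), , drop = FALSE]
  rownames(ann) <- NULL
  structure(list(values = v, value_kind = x$value_kind, samples = ann),
            class = "expr_matrix")
}

#' Samples belonging to a group
#'
#' @param x An `expr_matrix`.
#' @param group A group label from the sample annotations.
#' @return Character vector of sample IDs.
#' @export
group_samples <- function(x, group) {
  stopifnot(is_expr_matrix(x))
  s <- x$samples$sample[!is.na(x$samples$group) & x$samples$group == group]
  if (!length(s)) stop("no samples in group '", group, "'")
  s
}
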