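#' @section File formats:
#' All files are UTF-8, tab-delimited, with `#` comment lines ignored.
#' Expression matrices are genes x samples TSV with the gene ID in the first
#' column; annotations are a TSV keyed by `sample`; gene sets use the Broad
#' GMT dialect; ortholog maps are two-column (`mouse`, `human`); signatures
#' are two-column (`gene`, `weight` in {+1, -1}). Writers emit a canonical
#' byte-stable form: rows sorted by gene, columns by sample, numeric values
#' at 6 significant digits.
#' @name adsig-io
NULL

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

fmt_num <- function(x) {
  # canonical 6-significant-digit text; integers stay integral
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15, format(x, scientific = FALSE, trim = TRUE),
                formatC(signif(x, 6), format = "g", digits = 6)))
}

#' Read an expression matrix from TSV
#'
#' @param path Expression TSV: first column gene ID, header of sample IDs.
#' @param value_kind `"counts"`, `"log_intensity"` or `"tpm"`.
#' @param annotation_path Optional sample-annotation TSV (keyed by `sample`).
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, value_kind = "counts", annotation_path = NULL) {
  df <- read_tsv_plain(path)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  ann <- if (!is.null(annotation_path)) read_tsv_plain(annotation_path) else NULL
  expression_matrix(m, value_kind, samples = ann)
}

#' Write an expression matrix (and optionally its annotations) to TSV
#'
#' Output is canonical: genes and samples sorted lexicographically, numeric
#' values at 6 significant digits, so identical inputs give byte-identical
#' files.
#'
#' @param x An `expr_matrix`.
#' @param path Output TSV path.
#' @param annotation_path Optional path for the sample-annotation TSV.
#' @return Invisibly, `x`.
#' @export
write_expression_matrix <- function(x, path, annotation_path = NULL) {
  stopifnot(is_expr_matrix(x))
  v <- x$values[order(rownames(x$values)), order(colnames(x$values)), drop = FALSE]
  lines <- c(paste(c("gene", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i], fmt_num(v[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(annotation_path)) {
    ann <- x$samples[order(x$samples$sample), , drop = FALSE]
    hdr <- paste(names(ann), collapse = "\t")
    body <- vapply(seq_len(nrow(ann)), function(i) {
      row <- ann[i, ]
      paste(vapply(names(ann), function(cl) {
        val <- row[[cl]]
        if (is.numeric(val)) fmt_num(val) else ifelse(is.na(val), "NA", as.character(val))
      }, character(1)), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), annotation_path, useBytes = TRUE)
  }
  invisible(x)
}

#' Collapse probe-level intensities to gene level by geometric mean
#'
#' A gene measured by several probes/probesets is summarised, per sample, by
#' the geometric mean of its probes. Matrices on the log2 scale are
#' exponentiated, collapsed, and re-logged, which equals the arithmetic mean
#' of the log2 values; natural-scale matrices must be strictly positive.
#' Probes absent from the map are dropped and counted in the
#' `"collapse_report"` attribute.
#'
#' @param x An `expr_matrix` whose rows are probe IDs.
#' @param probe_map Data.frame with columns `probe` and `gene` (many-to-one).
#' @return An `expr_matrix` with one row per gene.
#' @export
collapse_probes <- function(x, probe_map) {
  stopifnot(is_expr_matrix(x))
  probe_map <- as.data.frame(probe_map)
  if (!all(c("probe", "gene") %in% names(probe_map)))
    stop("probe_map needs 'probe' and 'gene' columns")
  if (anyDuplicated(probe_map$probe))
    stop("each probe must map to exactly one gene")
  v <- x$values
  if (x$value_kind == "log_intensity") {
    logv <- v
  } else {
    bad <- which(v <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-positive value at probe %s, sample %s: geometric mean undefined",
                   rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
    logv <- log2(v)
  }
  keep <- rownames(v) %in% probe_map$probe
  n_dropped <- sum(!keep)
  logv <- logv[keep, , drop = FALSE]
  gene <- probe_map$gene[match(rownames(logv), probe_map$probe)]
  agg <- rowsum(logv, group = gene, reorder = TRUE)
  cnt <- as.vector(table(gene)[rownames(agg)])
  agg <- agg / cnt
  out <- if (x$value_kind == "log_intensity") agg else 2^agg
  res <- expression_matrix(out, x$value_kind, samples = x$samples)
  attr(res, "collapse_report") <- list(n_probes_in = nrow(v),
                                       n_probes_unmapped = n_dropped,
                                       n_genes_out = nrow(out))
  res
}

#' Read a gene-set collection from a GMT file
#'
#' @param path GMT path (tab-separated: name, description, members...).
#' @return Named list of gene sets; each element is a character vector of
#'   member symbols with a `"description"` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("GMT line with no members: ", parts[1])
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set: ", parts[1])
    if (anyDuplicated(members)) stop("duplicate members in set ", parts[1])
    s <- members
    attr(s, "description") <- parts[2]
    sets[[parts[1]]] <- s
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors (as returned by `read_gene_sets`).
#' @export
write_gene_sets <- function(sets, path) {
  nm <- sort(names(sets))
  lines <- vapply(nm, function(n) {
    desc <- attr(sets[[n]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(n, desc, as.character(sets[[n]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(sets)
}

#' Read / write a mouse-to-human ortholog map
#'
#' Ambiguous pairs (a mouse symbol with several human partners, or vice
#' versa) are dropped so the working map is one-to-one; the dropped pairs
#' are kept in the `"dropped"` attribute for reporting.
#'
#' @param path Two-column TSV (`mouse`, `human`).
#' @return Data.frame with columns `mouse`, `human`; one-to-one.
#' @export
read_ortholog_map <- function(path) {
  df <- read_tsv_plain(path)
  if (!all(c("mouse", "human") %in% names(df)))
    stop("ortholog TSV needs 'mouse' and 'human' columns")
  ortholog_map(df$mouse, df$human)
}

#' @rdname read_ortholog_map
#' @param mouse,human Character vectors of paired symbols.
#' @export
ortholog_map <- function(mouse, human) {
  df <- unique(data.frame(mouse = as.character(mouse), human = as.character(human),
                          stringsAsFactors = FALSE))
  amb <- df$mouse %in% df$mouse[duplicated(df$mouse)] |
    df$human %in% df$human[duplicated(df$human)]
  keep <- df[!amb, , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "dropped") <- df[amb, , drop = FALSE]
  keep
}

#' @rdname read_ortholog_map
#' @param om An ortholog map data.frame.
#' @export
write_ortholog_map <- function(om, path) {
  om <- om[order(om$mouse, om$human), , drop = FALSE]
  writeLines(c("mouse\thuman", paste(om$mouse, om$human, sep = "\t")), path,
             useBytes = TRUE)
  invisible(om)
}

#' Read / write a weighted gene signature
#'
#' A signature is a set of gene symbols each carrying a weight of +1
#' (upregulated in lesional skin) or -1 (downregulated).
#'
#' @param path Two-column TSV (`gene`, `weight`).
#' @return Data.frame with columns `gene`, `weight`.
#' @export
read_signature <- function(path) {
  df <- read_tsv_plain(path)
  if (!all(c("gene", "weight") %in% names(df)))
    stop("signature TSV needs 'gene' and 'weight' columns")
  signature_table(df$gene, df$weight)
}

#' @rdname read_signature
#' @param gene Character vector of gene symbols.
#' @param weight Numeric vector of +1/-1 weights.
#' @export
signature_table <- function(gene, weight) {
  weight <- as.numeric(weight)
  if (!all(weight %in% c(1, -1)))
    stop("signature weights must be +1 or -1")
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("duplicate genes in signature")
  data.frame(gene = gene, weight = weight, stringsAsFactors = FALSE)
}

#' @rdname read_signature
#' @param sig A signature data.frame.
#' @export
write_signature <- function(sig, path) {
  sig <- sig[order(sig$gene), , drop = FALSE]
  writeLines(c("gene\tweight", paste(sig$gene, fmt_num(sig$weight), sep = "\t")),
             path, useBytes = TRUE)
  invisible(sig)
}

#' Write a differential-expression table to TSV
#'
#' @param deg A DEG table (see [nb_exact_test()], [sam_test()]).
#' @param path Output path.
#' @return Invisibly, `deg`.
#' @export
write_deg_table <- function(deg, path) {
  deg <- deg[order(deg$gene), , drop = FALSE]
  num <- c("log2fc", "statistic", "p", "fdr")
  lines <- c(paste(c("gene", num, "call"), collapse = "\t"),
             vapply(seq_len(nrow(deg)), function(i) {
               paste(c(deg$gene[i], fmt_num(unlist(deg[i, num])), deg$call[i]),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(deg)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("gene", "log2fc", "statistic", "p", "fdr", "call")
  if (!all(need %in% names(df))) stop("DEG TSV missing columns")
  df[, need]
}
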