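called_directions <- function(deg) {
  d <- deg[deg$call %in% c("up", "down"), c("gene", "call")]
  stats::setNames(ifelse(d$call == "up", 1, -1), d$gene)
}

map_mouse_calls <- function(dirs, om) {
  human <- om$human[match(names(dirs), om$mouse)]
  keep <- !is.na(human)
  stats::setNames(dirs[keep], human[keep])
}

intersect_directions <- function(dir_list) {
  genes <- Reduce(intersect, lapply(dir_list, names))
  if (!length(genes)) return(stats::setNames(numeric(0), character(0)))
  mat <- vapply(dir_list, function(d) d[genes], numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes))
  conc <- apply(mat, 1, function(r) all(r == r[1]))
  stats::setNames(mat[conc, 1], genes[conc])
}

#' Build a direction-weighted candidate gene pool
#'
#' A pool holds the genes called with the same direction in every supplied
#' human DEG table; if mouse DEG tables are given, each gene's mouse
#' ortholog must additionally be called with that same direction in every
#' mouse table (the Human, Human+CHS, Human+SSS, ... pools). Weights carry
#' the human direction: +1 up, -1 down.
#'
#' @param human_degs List of called human DEG tables.
#' @param mouse_degs Optional list of called mouse DEG tables (mouse symbols).
#' @param om Ortholog map (`mouse`, `human`), required with `mouse_degs`.
#' @param pool_id Label for the pool.
#' @return A signature-shaped data.frame (`gene`, `weight`) with a
#'   `pool_id` attribute.
#' @export
build_gene_pool <- function(human_degs, mouse_degs = NULL, om = NULL,
                            pool_id = "Human") {
  dirs <- lapply(human_degs, called_directions)
  if (!is.null(mouse_degs) && length(mouse_degs)) {
    if (is.null(om)) stop("ortholog map required when mouse DEG tables are supplied")
    dirs <- c(dirs, lapply(mouse_degs, function(d) map_mouse_calls(called_directions(d), om)))
  }
  pool <- intersect_directions(dirs)
  if (!length(pool)) {
    sizes <- vapply(dirs, length, integer(1))
    stop("empty gene pool '", pool_id, "'; called-gene counts per table: ",
         paste(sizes, collapse = ", "))
  }
  res <- signature_table(names(pool), unname(pool))
  attr(res, "pool_id") <- pool_id
  res
}

#' Assemble the cross-species gene signature
#'
#' Genes called with concordant direction in both mouse-model contrasts are
#' mapped to their human orthologs and intersected with the genes called
#' with concordant direction in every human discovery cohort; genes
#' dysregulated in opposite directions in the two models are excluded.
#' Weights follow the human direction (+1 upregulated in lesional skin, -1
#' downregulated).
#'
#' @param mouse_degs List of two called mouse DEG tables (one per model
#'   contrast, mouse symbols).
#' @param human_degs List of called human DEG tables.
#' @param om Ortholog map (`mouse`, `human`).
#' @return A signature data.frame (`gene`, `weight`).
#' @export
build_signature <- function(mouse_degs, human_degs, om) {
  mouse_dirs <- lapply(mouse_degs, function(d) map_mouse_calls(called_directions(d), om))
  human_dirs <- lapply(human_degs, called_directions)
  sig <- intersect_directions(c(human_dirs, mouse_dirs))
  if (!length(sig)) {
    sizes <- vapply(c(human_dirs, mouse_dirs), length, integer(1))
    stop("empty signature; called-gene counts per table: ",
         paste(sizes, collapse = ", "))
  }
  signature_table(names(sig), unname(sig))
}

#' AD index: weighted sum of standardized signature-gene expression
#'
#' Each sample's index is `sum_i w_i * (e_i - mu_i) / tau_i` over the
#' signature genes present in the matrix, where `mu_i` and `tau_i` are the
#' mean and standard deviation (n-1 denominator) of gene i across the
#' standardization sample set. A higher index implies a more severe disease
#' state. Signature genes missing from the matrix, or with zero standard
#' deviation, are excluded and reported.
#'
#' @param x An `expr_matrix` (log2 intensities) with >= 2 samples.
#' @param sig Signature data.frame (`gene`, `weight`).
#' @param standardize_samples Optional character vector of sample IDs over
#'   which `mu`/`tau` are computed (default: all samples of `x`); the index
#'   itself is always computed for every sample of `x`.
#' @return List of class `ad_index`: `index` (named per-sample vector),
#'   `n_genes_used`, `excluded` (missing or zero-variance genes), `stats`
#'   (data.frame `gene`, `weight`, `mu`, `tau` for reuse on held-out
#'   samples).
#' @export
ad_index <- function(x, sig, standardize_samples = NULL) {
  stopifnot(is_expr_matrix(x))
  v <- x$values
  if (ncol(v) < 2) stop("need >= 2 samples to standardize")
  std <- if (is.null(standardize_samples)) colnames(v) else standardize_samples
  if (!all(std %in% colnames(v))) stop("unknown standardization samples")
  present <- sig$gene[sig$gene %in% rownames(v)]
  missing <- setdiff(sig$gene, present)
  if (!length(present)) stop("no signature gene present in the expression matrix")
  mu <- rowMeans(v[present, std, drop = FALSE])
  tau <- apply(v[present, std, drop = FALSE], 1, stats::sd)
  zero <- present[tau == 0]
  if (length(zero))
    warning("excluding zero-variance genes: ", paste(zero, collapse = ", "))
  use <- present[tau > 0]
  if (!length(use)) stop("no usable signature gene (all zero variance)")
  w <- sig$weight[match(use, sig$gene)]
  z <- (v[use, , drop = FALSE] - mu[use]) / tau[use]
  idx <- as.vector(crossprod(z, w))
  names(idx) <- colnames(v)
  structure(list(index = idx, n_genes_used = length(use),
                 excluded = c(missing, zero),
                 stats = data.frame(gene = use, weight = w, mu = mu[use],
                                    tau = tau[use], row.names = NULL)),
            class = "ad_index")
}

#' @export
print.ad_index <- function(x, ...) {
  cat(sprintf("ad_index over %d samples using %d genes (%d excluded)\n",
              length(x$index), x$n_genes_used, length(x$excluded)))
  print(utils::head(x$index))
  invisible(x)
}

#' Correlation between the AD index and a clinical severity score
#'
#' Pearson correlation between per-sample index values and SCORAD (or any
#' severity covariate), over the samples with both values available.
#'
#' @param idx An `ad_index` object or a named numeric vector of index values.
#' @param scorad Named numeric vector of severity scores (names = sample IDs)
#'   or an unnamed vector aligned with the index.
#' @return List with `r`, `p` (two-sided) and `n` pairs used.
#' @export
severity_correlation <- function(idx, scorad) {
  iv <- if (inherits(idx, "ad_index")) idx$index else idx
  if (!is.null(names(scorad)) && !is.null(names(iv))) {
    common <- intersect(names(iv), names(scorad))
    iv <- iv[common]; scorad <- scorad[common]
  }
  ok <- !is.na(iv) & !is.na(scorad)
  if (sum(ok) < 3) stop("need >= 3 paired non-NA values, got ", sum(ok))
  ct <- stats::cor.test(iv[ok], scorad[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Paired pre/post-treatment comparison of AD indices
#'
#' Paired Student t-test on per-subject index differences (`t1` minus `t0`)
#' within one tissue compartment; subjects missing either timepoint are
#' excluded and counted.
#'
#' @param idx An `ad_index` object (or named vector).
#' @param samples Sample annotation data.frame with `sample`, `subject`,
#'   `timepoint`, `lesional`.
#' @param t0,t1 Timepoint labels (e.g. `"baseline"`, `"week2"`).
#' @param tissue Lesional status to restrict to (`"lesional"` or
#'   `"nonlesional"`), or NULL for all.
#' @return List with `mean_change`, `t`, `p`, `n_pairs`,
#'   `n_excluded_subjects`.
#' @export
paired_timepoint_test <- function(idx, samples, t0, t1, tissue = "lesional") {
  iv <- if (inherits(idx, "ad_index")) idx$index else idx
  ann <- samples[samples$sample %in% names(iv), , drop = FALSE]
  if (!is.null(tissue)) ann <- ann[!is.na(ann$lesional) & ann$lesional == tissue, ]
  pick <- function(tp) {
    a <- ann[!is.na(ann$timepoint) & ann$timepoint == tp, ]
    stats::setNames(iv[a$sample], a$subject)
  }
  v0 <- pick(t0); v1 <- pick(t1)
  subj <- intersect(names(v0), names(v1))
  n_excluded <- length(union(names(v0), names(v1))) - length(subj)
  if (length(subj) < 2) stop("need >= 2 complete subject pairs, got ", length(subj))
  diff <- v1[subj] - v0[subj]
  if (stats::sd(diff) == 0) {
    # degenerate: constant differences (all-zero -> no change at all)
    t <- if (mean(diff) == 0) 0 else sign(mean(diff)) * Inf
    p <- if (mean(diff) == 0) 1 else 0
  } else {
    tt <- stats::t.test(diff)
    t <- unname(tt$statistic); p <- tt$p.value
  }
  list(mean_change = mean(diff), t = t, p = p,
       n_pairs = length(subj), n_excluded_subjects = n_excluded)
}
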