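#' Configuration for FAIME pathway scoring
#'
#' @param weight_decay Positive decay rate of the exponential rank weight
#'   `exp(-decay * rank / N)`; rank 1 is the most highly expressed gene.
#' @return A list of class `faime_config`.
#' @export
faime_config <- function(weight_decay = 1.0) {
  stopifnot(weight_decay > 0)
  structure(list(tie_method = "average_rank", weight_decay = weight_decay),
            class = "faime_config")
}

#' FAIME rank-weighted single-sample pathway scores
#'
#' For each sample, genes are ranked by descending expression (ties take the
#' average rank) and weighted by `exp(-decay * rank / N)`. A pathway's score
#' is the mean weight of its member genes minus the mean weight of all
#' non-members, so a higher score means the pathway's genes sit nearer the
#' top of that sample's expression profile. Scores depend on ranks only, so
#' they are invariant to any strictly monotone transform of a sample's
#' values. Pathways with no member present in the matrix, or covering every
#' gene (empty complement), are dropped and listed in the `"dropped_sets"`
#' attribute.
#'
#' @param x An `expr_matrix` with at least 2 genes.
#' @param gene_sets Named list of character vectors (see [read_gene_sets()]).
#' @param cfg A [faime_config()].
#' @return Pathways x samples numeric matrix of scores.
#' @export
faime_scores <- function(x, gene_sets, cfg = faime_config()) {
  stopifnot(is_expr_matrix(x))
  v <- x$values
  if (nrow(v) < 2) stop("need >= 2 genes")
  n <- nrow(v)
  # average ranks of descending expression, per sample
  r <- apply(-v, 2, rank, ties.method = "average")
  w <- exp(-cfg$weight_decay * r / n)
  dropped <- character(0)
  rows <- lapply(names(gene_sets), function(nm) {
    memb <- rownames(v) %in% gene_sets[[nm]]
    if (!any(memb) || all(memb)) return(NULL)
    colMeans(w[memb, , drop = FALSE]) - colMeans(w[!memb, , drop = FALSE])
  })
  names(rows) <- names(gene_sets)
  keep <- !vapply(rows, is.null, logical(1))
  dropped <- names(rows)[!keep]
  if (length(dropped))
    warning("dropped pathways with empty member or complement set: ",
            paste(dropped, collapse = ", "))
  if (!any(keep)) stop("no scorable pathway")
  scores <- do.call(rbind, rows[keep])
  colnames(scores) <- colnames(v)
  attr(scores, "dropped_sets") <- dropped
  attr(scores, "config") <- cfg
  scores
}

#' Per-pathway two-group contrast of FAIME scores
#'
#' Equal-variance two-sample Student t per pathway, `group_b` minus
#' `group_a`, so a positive t means the pathway is upregulated in the
#' disease/model group. P-values are two-sided; `p_corrected` is
#' Benjamini-Hochberg. Pathways with zero pooled variance get t = 0, p = 1
#' when the group means agree; when they differ the t is capped at +/-1e6
#' with p = 0 and the `degenerate` flag set.
#'
#' @param scores Pathway x sample score matrix from [faime_scores()].
#' @param samples Sample annotation data.frame (with `sample` and `group`),
#'   e.g. the `samples` element of the scored `expr_matrix`.
#' @param group_a,group_b Group labels.
#' @return Data.frame: `pathway`, `t`, `p`, `p_corrected`, `direction`,
#'   `degenerate`.
#' @export
pathway_contrast <- function(scores, samples, group_a, group_b) {
  sa <- samples$sample[!is.na(samples$group) & samples$group == group_a]
  sb <- samples$sample[!is.na(samples$group) & samples$group == group_b]
  sa <- intersect(sa, colnames(scores)); sb <- intersect(sb, colnames(scores))
  if (length(sa) < 2 || length(sb) < 2) stop("need >= 2 samples per group")
  a <- scores[, sa, drop = FALSE]; b <- scores[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb); df <- na + nb - 2
  ma <- rowMeans(a); mb <- rowMeans(b)
  sp2 <- (rowSums((a - ma)^2) + rowSums((b - mb)^2)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (mb - ma) / se
  degenerate <- se == 0
  t[degenerate & mb == ma] <- 0
  t[degenerate & mb != ma] <- sign(mb - ma)[degenerate & mb != ma] * 1e6
  p <- 2 * stats::pt(-abs(t), df)
  p[degenerate & mb == ma] <- 1
  p[degenerate & mb != ma] <- 0
  data.frame(pathway = rownames(scores), t = t, p = p,
             p_corrected = stats::p.adjust(p, "BH"),
             direction = sign(t), degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlation of pathway t-statistics between two contrasts
#'
#' Pearson correlation of per-pathway t-statistics over the pathways shared
#' by both contrast tables — the concordance measure used to ask whether
#' pathways dysregulated in a mouse model tend to be dysregulated the same
#' way in human disease.
#'
#' @param a,b Contrast tables from [pathway_contrast()].
#' @return List with `r`, `p` (two-sided, t-distribution transform of r) and
#'   `n_shared`.
#' @export
contrast_correlation <- function(a, b) {
  shared <- intersect(a$pathway, b$pathway)
  if (length(shared) < 3) stop("need >= 3 shared pathways, got ", length(shared))
  ta <- a$t[match(shared, a$pathway)]
  tb <- b$t[match(shared, b$pathway)]
  ct <- stats::cor.test(ta, tb, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_shared = length(shared))
}

#' Translate gene sets between species through an ortholog map
#'
#' @param gene_sets Named list of human-symbol gene sets.
#' @param om Ortholog map data.frame (`mouse`, `human`).
#' @param to `"mouse"` maps human members to mouse symbols, `"human"` the
#'   reverse. Unmapped members are dropped; sets left empty are removed.
#' @return Named list of translated gene sets.
#' @export
map_gene_sets <- function(gene_sets, om, to = c("mouse", "human")) {
  to <- match.arg(to)
  from <- if (to == "mouse") om$human else om$mouse
  dest <- if (to == "mouse") om$mouse else om$human
  out <- lapply(gene_sets, function(s) {
    m <- dest[match(s, from)]
    m <- unique(m[!is.na(m)])
    if (!length(m)) return(NULL)
    attr(m, "description") <- attr(s, "description")
    m
  })
  out[!vapply(out, is.null, logical(1))]
}
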