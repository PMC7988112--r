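#' Filter genes by mean TPM
#'
#' Retains genes whose mean TPM across samples is strictly greater than
#' `min_mean_tpm` (the expressed-gene filter applied to the mouse RNA-seq
#' data before testing).
#'
#' @param counts An `expr_matrix` of counts.
#' @param tpm An `expr_matrix` of TPM values with the same gene/sample IDs.
#' @param min_mean_tpm Threshold; genes with mean TPM > threshold are kept.
#' @return The filtered counts `expr_matrix`, original gene order preserved.
#' @export
filter_by_tpm <- function(counts, tpm, min_mean_tpm = 1) {
  stopifnot(is_expr_matrix(counts), is_expr_matrix(tpm))
  if (!identical(rownames(counts$values), rownames(tpm$values)) ||
      !identical(colnames(counts$values), colnames(tpm$values)))
    stop("counts and tpm matrices must share identical gene and sample IDs")
  keep <- rowMeans(tpm$values) > min_mean_tpm
  subset_expr(counts, genes = rownames(counts$values)[keep])
}

#' Configuration for the count-based exact test
#'
#' @param trim_m Fraction of extreme M-values (log ratios) trimmed from each
#'   tail when computing TMM factors.
#' @param trim_a Fraction of extreme A-values (mean abundances) trimmed.
#' @param dispersion Common negative-binomial dispersion; `NULL` to estimate
#'   from the data by moment matching on equalized pseudo-counts.
#' @param prior_count Offset added to normalized group means before the
#'   log2 fold-change (guards log of zero).
#' @return A list of class `nb_config`.
#' @export
nb_config <- function(trim_m = 0.30, trim_a = 0.05, dispersion = NULL,
                      prior_count = 0.125) {
  stopifnot(trim_m >= 0, trim_m < 0.5, trim_a >= 0, trim_a < 0.5,
            is.null(dispersion) || dispersion >= 0, prior_count >= 0)
  structure(list(trim_m = trim_m, trim_a = trim_a, dispersion = dispersion,
                 prior_count = prior_count), class = "nb_config")
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample, genes with zero counts in the
#' sample or the reference are excluded, the per-gene log2 ratios (M) are
#' trimmed on both the M and A scales, and a precision-weighted mean of the
#' surviving M-values gives the log factor. Factors are scaled to geometric
#' mean 1.
#'
#' @param counts An `expr_matrix` of counts; every sample needs a positive
#'   library size.
#' @param ref_sample Reference sample ID, or `"auto"` to pick the sample
#'   whose upper quartile (of counts-per-million) is closest to the mean.
#' @param cfg An [nb_config()].
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, ref_sample = "auto", cfg = nb_config()) {
  stopifnot(is_expr_matrix(counts))
  y <- counts$values
  lib <- colSums(y)
  if (any(lib <= 0)) stop("all-zero sample: ", colnames(y)[which(lib <= 0)[1]])
  if (identical(ref_sample, "auto")) {
    uq <- apply(sweep(y, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref_sample <- colnames(y)[which.min(abs(uq - mean(uq)))]
  }
  if (!ref_sample %in% colnames(y)) stop("unknown reference sample")
  r <- y[, ref_sample]
  f <- vapply(colnames(y), function(s) {
    tmm_one(y[, s], lib[s], r, lib[ref_sample], cfg$trim_m, cfg$trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  f
}

tmm_one <- function(obs, n_obs, ref, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # asymptotic (delta-method) variance of M
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & is.finite(w) & w > 0
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (!length(m)) return(1)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep_m <- rank(m, ties.method = "first") >= lo_m & rank(m, ties.method = "first") <= hi_m
  keep_a <- rank(a, ties.method = "first") >= lo_a & rank(a, ties.method = "first") <= hi_a
  sel <- keep_m & keep_a
  if (!any(sel)) return(1)
  2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
}

#' Negative-binomial exact test for two-group count data
#'
#' The classic two-group exact-test construction: counts are scaled to a
#' common effective library size (TMM-normalized, rounded to integers with
#' ties-to-even), a common NB dispersion is estimated by moment matching on
#' the pooled within-group variances (unless supplied), and for each gene
#' the two-sided exact p sums the conditional probabilities of all splits of
#' the gene's total that are no more likely than the observed one. With
#' dispersion 0 the conditional law is binomial (Poisson limit). FDR is
#' Benjamini-Hochberg.
#'
#' @param counts An `expr_matrix` of counts with group annotations.
#' @param group_a,group_b Group labels; log2FC is `group_b` minus `group_a`.
#' @param cfg An [nb_config()].
#' @return A DEG table: `gene`, `log2fc`, `statistic` (signed z-equivalent of
#'   p), `p`, `fdr`, `call` (initially `"none"`; see [call_degs()]).
#' @export
nb_exact_test <- function(counts, group_a, group_b, cfg = nb_config()) {
  stopifnot(is_expr_matrix(counts))
  sa <- group_samples(counts, group_a)
  sb <- group_samples(counts, group_b)
  sub <- subset_expr(counts, samples = c(sa, sb))
  y <- sub$values
  f <- tmm_factors(sub, cfg = cfg)
  eff <- colSums(y) * f
  common <- exp(mean(log(eff)))
  # equalized pseudo-counts at the common effective library size
  pseudo <- round(sweep(y, 2, common / eff, "*"))
  na <- length(sa); nb <- length(sb)
  ia <- colnames(y) %in% sa
  phi <- if (is.null(cfg$dispersion)) estimate_common_dispersion(pseudo, ia) else cfg$dispersion

  ya <- rowSums(pseudo[, ia, drop = FALSE])
  yb <- rowSums(pseudo[, !ia, drop = FALSE])
  p <- vapply(seq_len(nrow(y)), function(g) {
    exact_nb_pvalue(ya[g], yb[g], na, nb, phi)
  }, numeric(1))
  mean_a <- ya / na; mean_b <- yb / nb
  log2fc <- log2((mean_b + cfg$prior_count) / (mean_a + cfg$prior_count))
  stat <- sign(log2fc) * abs(stats::qnorm(pmax(p / 2, 1e-300)))
  data.frame(gene = rownames(y), log2fc = log2fc, statistic = stat,
             p = p, fdr = stats::p.adjust(p, "BH"), call = "none",
             stringsAsFactors = FALSE, row.names = NULL)
}

# common dispersion by conditional maximum likelihood on the equalized
# pseudo-counts: within each group, the likelihood of the counts given
# their sum does not involve the mean, only phi (r = 1/phi); summed over
# genes and both groups and maximized over log phi. Every gene contributes
# on the same scale, so no single high-count gene can dominate.
estimate_common_dispersion <- function(pseudo, ia) {
  keep <- rowSums(pseudo) > 0
  groups <- list(pseudo[keep, ia, drop = FALSE], pseudo[keep, !ia, drop = FALSE])
  cll <- function(lphi) {
    r <- exp(-lphi)
    tot <- 0
    for (y in groups) {
      n <- ncol(y); z <- rowSums(y)
      tot <- tot + sum(lgamma(y + r)) - length(z) * n * lgamma(r) +
        sum(lgamma(n * r) - lgamma(z + n * r))
    }
    tot
  }
  opt <- stats::optimize(cll, interval = log(c(1e-6, 5)), maximum = TRUE)
  phi <- exp(opt$maximum)
  if (phi <= 1.5e-6) 0 else phi
}

# two-sided exact p conditional on the total: sum of conditional
# probabilities over splits no more likely than the observed split
exact_nb_pvalue <- function(ya, yb, na, nb, phi) {
  t <- ya + yb
  if (t == 0) return(1)
  ys <- 0:t
  if (phi <= 0) {
    logp <- stats::dbinom(ys, t, na / (na + nb), log = TRUE)
  } else {
    mu <- t / (na + nb)
    logp <- stats::dnbinom(ys, size = na / phi, mu = na * mu, log = TRUE) +
      stats::dnbinom(t - ys, size = nb / phi, mu = nb * mu, log = TRUE)
  }
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[ya + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Call differentially expressed genes by FDR and fold-change thresholds
#'
#' `call = "up"` iff `fdr < max_fdr` and `log2fc > log2(min_fc)`; `"down"`
#' symmetrically; otherwise `"none"`. Inequalities are strict.
#'
#' @param deg A DEG table.
#' @param max_fdr FDR threshold (e.g. 0.05 for the mouse contrasts, 0.10 for
#'   the human cohorts).
#' @param min_fc Fold-change threshold on the natural scale (2 for mouse,
#'   1.5 for human).
#' @return The DEG table with the `call` column filled in.
#' @export
call_degs <- function(deg, max_fdr, min_fc) {
  stopifnot(max_fdr > 0, min_fc > 0)
  lfc <- log2(min_fc)
  deg$call <- ifelse(deg$fdr < max_fdr & deg$log2fc > lfc, "up",
                     ifelse(deg$fdr < max_fdr & deg$log2fc < -lfc, "down", "none"))
  deg
}
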