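#' Configuration for the SAM permutation test
#'
#' @param n_perm Maximum number of group-label permutations. When the number
#'   of distinct label assignments is at most `n_perm` they are all
#'   enumerated; otherwise `n_perm` random assignments are drawn.
#' @param s0 Fudge constant added to the per-gene standard error, or
#'   `"auto"` for Tusher's percentile rule (minimize the coefficient of
#'   variation of the spread of d across windows of the standard-error
#'   distribution).
#' @param seed Integer seed for the sampled-permutation path.
#' @return A list of class `sam_config`.
#' @export
sam_config <- function(n_perm = 1000, s0 = "auto", seed = 17) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!identical(s0, "auto")) stopifnot(is.numeric(s0), s0 >= 0)
  structure(list(n_perm = as.integer(n_perm), s0 = s0, seed = as.integer(seed)),
            class = "sam_config")
}

sam_d <- function(x, ia, ib, s0) {
  na <- sum(ia); nb <- sum(ib)
  ma <- rowMeans(x[, ia, drop = FALSE])
  mb <- rowMeans(x[, ib, drop = FALSE])
  ssa <- rowSums((x[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((x[, ib, drop = FALSE] - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * (ssa + ssb) / (na + nb - 2))
  list(d = (mb - ma) / (s + s0), s = s)
}

# Tusher's rule: pick s0 (from percentiles of s) minimizing the coefficient
# of variation of the median absolute deviation of d across s-quantile windows
choose_s0 <- function(diff, s) {
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE))
  cuts <- stats::quantile(s, probs = seq(0, 1, by = 0.01), names = FALSE)
  grp <- cut(s, breaks = unique(cuts), include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- diff / (s + s0)
    v <- tapply(d, grp, stats::mad)
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

#' SAM two-group permutation test for log-scale expression
#'
#' Computes the SAM statistic d = (mean_b - mean_a) / (s + s0) with pooled
#' standard error s, then builds a per-gene null distribution by permuting
#' group labels. All distinct assignments are enumerated when their count is
#' at most `cfg$n_perm` (p is then an exact k/B); otherwise `n_perm` seeded
#' draws are used with add-one smoothing so p is never 0. FDR is Storey's
#' q-value.
#'
#' @param x An `expr_matrix` of log2 intensities with group annotations.
#' @param group_a,group_b Group labels; d and log2fc are `group_b` minus
#'   `group_a`.
#' @param cfg A [sam_config()].
#' @return A DEG table: `gene`, `log2fc`, `statistic` (d), `p`, `fdr`
#'   (q-value), `call`.
#' @export
sam_test <- function(x, group_a, group_b, cfg = sam_config()) {
  stopifnot(is_expr_matrix(x))
  sa <- group_samples(x, group_a)
  sb <- group_samples(x, group_b)
  if (length(sa) < 2 || length(sb) < 2) stop("need >=2 samples per group")
  sub <- subset_expr(x, samples = c(sa, sb))
  v <- sub$values
  n <- ncol(v); na <- length(sa)
  ia <- colnames(v) %in% sa

  mean_a <- rowMeans(v[, ia, drop = FALSE])
  mean_b <- rowMeans(v[, !ia, drop = FALSE])
  diff <- mean_b - mean_a
  s <- sam_d(v, ia, !ia, 0)$s
  s0 <- if (identical(cfg$s0, "auto")) choose_s0(diff, s) else cfg$s0
  if (s0 == 0 && any(s == 0)) stop("zero pooled standard error with s0 = 0")
  d_obs <- diff / (s + s0)

  n_distinct <- choose(n, na)
  exhaustive <- n_distinct <= cfg$n_perm
  if (exhaustive) {
    assign_idx <- utils::combn(n, na, simplify = FALSE)
  } else {
    set.seed(cfg$seed)
    assign_idx <- replicate(cfg$n_perm, sample.int(n, na), simplify = FALSE)
  }
  B <- length(assign_idx)
  # permuted |d| per gene, vectorized over genes per permutation
  exceed <- integer(nrow(v))
  abs_obs <- abs(d_obs)
  for (idx in assign_idx) {
    pa <- logical(n); pa[idx] <- TRUE
    dp <- sam_d(v, pa, !pa, s0)$d
    exceed <- exceed + (abs(dp) >= abs_obs - 1e-12)
  }
  p <- if (exhaustive) exceed / B else (1 + exceed) / (1 + B)
  data.frame(gene = rownames(v), log2fc = diff, statistic = d_obs,
             p = p, fdr = qvalues(p), call = "none",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on a lambda grid (smoothed and taken at
#' the grid's right end, clamped to (0, 1]); for short p-value lists
#' (< 100) falls back to `pi0 = min(1, 2 * mean(p))`. q-values are the
#' pi0-scaled step-up values, monotone non-decreasing in sorted p.
#'
#' @param p Vector of p-values in [0, 1].
#' @param lambda_grid Grid for the pi0 estimate.
#' @return Vector of q-values aligned with `p`.
#' @export
qvalues <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m < 100) {
    pi0 <- min(1, 2 * mean(p))
  } else {
    pi0_l <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda_grid))$y
    pi0 <- min(1, max(pi0, 1 / m))
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / (m - seq_len(m) + 1)))[ro]
  q
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(p, "BH")` kept for a uniform module
#' surface.
#'
#' @param p Vector of p-values in [0, 1].
#' @return BH-adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, "BH")
}
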