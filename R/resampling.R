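#' Configuration for random-signature resampling
#'
#' @param B Number of random signatures (the benchmarking default is 1000).
#' @param size Signature size drawn from the pool (default: set from the
#'   candidate signature at call time).
#' @param seed Master seed; each of the B signatures draws from its own
#'   derived substream, so enlarging B extends rather than reshuffles the
#'   draw sequence.
#' @param tail `"right"` (candidate expected to beat the pool) or `"left"`.
#' @return A list of class `resampling_config`.
#' @export
resampling_config <- function(B = 1000, size = NULL, seed = 17,
                              tail = c("right", "left")) {
  tail <- match.arg(tail)
  stopifnot(B >= 1, is.null(size) || size >= 1)
  structure(list(B = as.integer(B), size = if (is.null(size)) NULL else as.integer(size),
                 seed = as.integer(seed), tail = tail),
            class = "resampling_config")
}

substream_seeds <- function(master, B) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, B, replace = TRUE)
}

#' Draw random size-matched signatures from a gene pool
#'
#' Each signature consists of `cfg$size` genes sampled uniformly without
#' replacement from the pool, keeping the pool's +1/-1 direction weights;
#' draws are independent across signatures and reproducible from the seed.
#'
#' @param pool Pool data.frame (`gene`, `weight`), e.g. from
#'   [build_gene_pool()].
#' @param cfg A [resampling_config()] with `size` set.
#' @return List of `cfg$B` signature data.frames.
#' @export
draw_random_signatures <- function(pool, cfg) {
  if (is.null(cfg$size)) stop("cfg$size must be set")
  if (cfg$size > nrow(pool))
    stop("signature size ", cfg$size, " exceeds pool size ", nrow(pool))
  seeds <- substream_seeds(cfg$seed, cfg$B)
  lapply(seq_len(cfg$B), function(b) {
    set.seed(seeds[b])
    pool[sort(sample.int(nrow(pool), cfg$size)), , drop = FALSE]
  })
}

# standardized expression (z) restricted to pool genes, plus aligned scorad;
# shared precomputation so each resampled index is a weighted column sum
prepare_scoring <- function(x, genes, scorad) {
  v <- x$values
  genes <- intersect(genes, rownames(v))
  if (!is.null(names(scorad))) {
    common <- intersect(colnames(v), names(scorad))
    v <- v[, common, drop = FALSE]
    scorad <- scorad[common]
  }
  ok <- !is.na(scorad)
  v <- v[, ok, drop = FALSE]; scorad <- scorad[ok]
  if (ncol(v) < 3) stop("need >= 3 samples with severity scores")
  mu <- rowMeans(v[genes, , drop = FALSE])
  tau <- apply(v[genes, , drop = FALSE], 1, stats::sd)
  use <- genes[tau > 0]
  z <- (v[use, , drop = FALSE] - mu[use]) / tau[use]
  list(z = z, scorad = scorad)
}

#' Distribution of severity correlations over random signatures
#'
#' For each of B random signatures drawn from the pool, computes the AD
#' index of every scored sample and its Pearson correlation with the
#' severity score; the B correlations form the benchmark distribution
#' against which a candidate signature is judged.
#'
#' @param pool Pool data.frame (`gene`, `weight`).
#' @param x An `expr_matrix` of the validation cohort samples to score.
#' @param scorad Named numeric severity vector (sample IDs); samples with NA
#'   are dropped.
#' @param cfg A [resampling_config()] with `size` set.
#' @return List of class `resampling_result` with `resampled_r` (length B),
#'   `pool_id`, `config`; `observed_r` and `empirical_p` are NA until a
#'   candidate is evaluated (see [compare_to_reference_signature()] or
#'   [empirical_p()]).
#' @export
resampling_distribution <- function(pool, x, scorad, cfg) {
  stopifnot(is_expr_matrix(x))
  sigs <- draw_random_signatures(pool, cfg)
  prep <- prepare_scoring(x, pool$gene, scorad)
  r <- vapply(sigs, function(s) {
    use <- intersect(s$gene, rownames(prep$z))
    w <- s$weight[match(use, s$gene)]
    idx <- as.vector(crossprod(prep$z[use, , drop = FALSE], w))
    stats::cor(idx, prep$scorad)
  }, numeric(1))
  structure(list(observed_r = NA_real_, resampled_r = r, empirical_p = NA_real_,
                 pool_id = attr(pool, "pool_id"), config = cfg),
            class = "resampling_result")
}

#' Empirical tail p-value of an observed correlation
#'
#' Add-one smoothed tail probability: right tail
#' `(1 + #\{r_b >= observed\}) / (B + 1)`, left tail analogous — never 0,
#' with floor `1/(B+1)`.
#'
#' @param observed_r Observed correlation of the candidate signature.
#' @param resampled_r Vector of B resampled correlations.
#' @param tail `"right"` or `"left"`.
#' @return The empirical p-value.
#' @export
empirical_p <- function(observed_r, resampled_r, tail = c("right", "left")) {
  tail <- match.arg(tail)
  if (!length(resampled_r)) stop("resampled_r must be non-empty")
  B <- length(resampled_r)
  k <- if (tail == "right") sum(resampled_r >= observed_r) else sum(resampled_r <= observed_r)
  (1 + k) / (B + 1)
}

#' Evaluate a candidate signature against a pool's resampling distribution
#'
#' @param candidate Candidate signature data.frame.
#' @param pool Pool data.frame; `cfg$size` defaults to the candidate size.
#' @param x,scorad As in [resampling_distribution()].
#' @param cfg A [resampling_config()].
#' @return A complete `resampling_result` with `observed_r` and
#'   `empirical_p` filled in.
#' @export
evaluate_signature <- function(candidate, pool, x, scorad, cfg = resampling_config()) {
  if (is.null(cfg$size)) cfg$size <- nrow(candidate)
  res <- resampling_distribution(pool, x, scorad, cfg)
  sub <- subset_expr(x, samples = names(scorad)[!is.na(scorad)])
  idx <- ad_index(sub, candidate)
  obs <- severity_correlation(idx, scorad)
  res$observed_r <- obs$r
  res$empirical_p <- empirical_p(obs$r, res$resampled_r, cfg$tail)
  res
}

#' Compare the resampling distributions of two gene pools
#'
#' Two-sided equal-variance two-sample t-test on the two correlation
#' distributions — the test used to ask whether one pool (e.g. Human+CHS)
#' yields systematically more predictive random signatures than another.
#'
#' @param a,b `resampling_result` objects with >= 2 resampled correlations
#'   each.
#' @return List with `t`, `p`, `mean_diff` (mean r of `a` minus `b`).
#' @export
compare_pools <- function(a, b) {
  ra <- a$resampled_r; rb <- b$resampled_r
  if (length(ra) < 2 || length(rb) < 2) stop("need >= 2 resampled correlations per pool")
  if (identical(ra, rb)) return(list(t = 0, p = 1, mean_diff = 0))
  tt <- stats::t.test(ra, rb, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(ra) - mean(rb))
}

#' Benchmark a published reference signature against subsets of a candidate
#'
#' Resamples `cfg$size`-gene subsets of the candidate signature (size
#' matched to the reference), builds their correlation distribution, and
#' locates the reference signature's own correlation in it with the
#' configured tail — a left-tail p near 0 means the reference underperforms
#' random pieces of the candidate.
#'
#' @param candidate Candidate signature used as the sampling pool.
#' @param reference Reference signature to evaluate; must not exceed the
#'   candidate's size.
#' @param x,scorad As in [resampling_distribution()].
#' @param cfg A [resampling_config()]; `size` defaults to the reference size.
#' @return A complete `resampling_result`.
#' @export
compare_to_reference_signature <- function(candidate, reference, x, scorad,
                                           cfg = resampling_config(tail = "left")) {
  if (is.null(cfg$size)) cfg$size <- nrow(reference)
  if (cfg$size > nrow(candidate))
    stop("reference size exceeds candidate size")
  pool <- candidate
  attr(pool, "pool_id") <- "candidate-subsets"
  res <- resampling_distribution(pool, x, scorad, cfg)
  sub <- subset_expr(x, samples = names(scorad)[!is.na(scorad)])
  idx <- ad_index(sub, reference)
  obs <- severity_correlation(idx, scorad)
  res$observed_r <- obs$r
  res$empirical_p <- empirical_p(obs$r, res$resampled_r, cfg$tail)
  res
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("resampling_result (pool %s): B=%d, mean r=%.3f",
              if (is.null(x$pool_id)) "?" else x$pool_id,
              length(x$resampled_r), mean(x$resampled_r)))
  if (!is.na(x$observed_r))
    cat(sprintf(", observed r=%.3f, %s-tail p=%.4g",
                x$observed_r, x$config$tail, x$empirical_p))
  cat("\n")
  invisible(x)
}
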