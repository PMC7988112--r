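test_that("TPM filter keeps genes strictly above the mean threshold", {
  cv <- named_matrix(rep(5L, 6), 3, 2)
  tv <- named_matrix(c(2, 1, 0.5, 2, 1, 0.5), 3, 2)
  counts <- make_expr(cv, kind = "counts")
  tpm <- make_expr(tv, kind = "tpm")
  out <- filter_by_tpm(counts, tpm, 1)
  expect_identical(rownames(out$values), "g001")   # strict inequality drops the mean-1 gene
  expect_equal(nrow(filter_by_tpm(counts, tpm, 0)$values), 3)
  # brute-force survivor oracle on random matrices
  set.seed(2)
  for (i in 1:5) {
    tv <- named_matrix(runif(40, 0, 3), 10, 4)
    cv <- named_matrix(rpois(40, 10), 10, 4)
    thr <- runif(1, 0, 2)
    survivors <- sum(vapply(seq_len(10), function(g) mean(tv[g, ]) > thr, logical(1)))
    out <- filter_by_tpm(make_expr(cv, kind = "counts"), make_expr(tv, kind = "tpm"), thr)
    expect_equal(nrow(out$values), survivors)
  }
  tv2 <- tv; rownames(tv2) <- rev(rownames(tv2))
  expect_error(filter_by_tpm(make_expr(cv, kind = "counts"),
                             make_expr(tv2, kind = "tpm"), 1), "identical")
})

test_that("TMM factors are 1 for identical or depth-scaled samples", {
  v <- named_matrix(rep(c(10L, 20L, 40L, 80L, 160L, 5L), 2), 6, 2)
  expect_equal(unname(tmm_factors(make_expr(v, kind = "counts"))), c(1, 1))
  v2 <- cbind(v[, 1], v[, 1] * 2L); dimnames(v2) <- dimnames(v)
  expect_equal(unname(tmm_factors(make_expr(v2, kind = "counts"))), c(1, 1))
  vz <- v; vz[, 2] <- 0L
  expect_error(tmm_factors(make_expr(vz, kind = "counts")), "all-zero")
})

test_that("TMM factors match an independently coded trimmed weighted mean", {
  # oracle: explicit sort-based double trimming and precision-weighted mean
  tmm_oracle <- function(obs, ref) {
    no <- sum(obs); nr <- sum(ref)
    keep <- obs > 0 & ref > 0
    o <- obs[keep]; r <- ref[keep]
    m <- log2((o / no) / (r / nr))
    a <- 0.5 * log2((o / no) * (r / nr))
    w <- (no - o) / (no * o) + (nr - r) / (nr * r)
    n <- length(m)
    lo_m <- floor(n * 0.30) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
    sel_m <- order(m)[lo_m:hi_m]; sel_a <- order(a)[lo_a:hi_a]
    sel <- intersect(sel_m, sel_a)
    2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
  }
  set.seed(7)
  for (i in 1:5) {
    v <- named_matrix(rpois(40, c(5, 500, 50, 20, 200, 1000, 8, 90, 30, 300)), 10, 4)
    storage.mode(v) <- "integer"
    x <- make_expr(v, kind = "counts")
    f <- tmm_factors(x, ref_sample = "s01")
    raw <- vapply(1:4, function(j) tmm_oracle(v[, j], v[, 1]), numeric(1))
    expect_equal(unname(f), raw / exp(mean(log(raw))), tolerance = 1e-10)
  }
})

test_that("TMM factors agree with edgeR on simulated libraries", {
  skip_if_not_installed("edgeR")
  ms <- simulate_mouse_study(sim_config(n_genes = 500, seed = 3))
  sub <- subset_expr(ms$counts, samples = c(group_samples(ms$counts, "VT"),
                                            group_samples(ms$counts, "CHS")))
  ours <- tmm_factors(sub)
  theirs <- edgeR::calcNormFactors(edgeR::DGEList(sub$values))$samples$norm.factors
  expect_equal(unname(ours), theirs, tolerance = 0.02)
})

test_that("exact test gives p = 1 and log2fc = 0 for identical balanced groups", {
  v <- named_matrix(rep(c(10L, 25L, 50L, 100L), 4), 4, 4)
  x <- make_expr(v, kind = "counts", groups = c("A", "A", "B", "B"))
  d <- nb_exact_test(x, "A", "B", nb_config(dispersion = 0))
  expect_equal(d$p, rep(1, 4))
  expect_equal(d$log2fc, rep(0, 4))
})

test_that("exact-test p equals full conditional-binomial enumeration in the Poisson limit", {
  # oracle: enumerate every split of the total under Binomial(t, na/(na+nb))
  binom_oracle <- function(ya, t, na, nb) {
    pr <- vapply(0:t, function(y) dbinom(y, t, na / (na + nb)), numeric(1))
    sum(pr[pr <= pr[ya + 1] * (1 + 1e-12)])
  }
  set.seed(8)
  cases <- 0
  for (i in 1:30) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    va <- rpois(na, 1.2); vb <- rpois(nb, 1.2)
    t <- sum(va) + sum(vb)
    if (t == 0 || t > 20) next
    v <- matrix(as.integer(c(va, vb)), 1, na + nb,
                dimnames = list("g1", sprintf("s%02d", seq_len(na + nb))))
    # pad with a constant high-count gene so library sizes are equal and positive
    v <- rbind(v, matrix(1000L, 1, na + nb, dimnames = list("pad", colnames(v))))
    x <- make_expr(v, kind = "counts", groups = rep(c("A", "B"), c(na, nb)))
    d <- nb_exact_test(x, "A", "B", nb_config(dispersion = 0))
    expect_equal(d$p[d$gene == "g1"], binom_oracle(sum(va), t, na, nb),
                 tolerance = 1e-10)
    cases <- cases + 1
  }
  expect_gte(cases, 10)
})

test_that("exact-test p is symmetric under group swap and log2fc negates", {
  ms <- simulate_mouse_study(small_sim_cfg(n_genes = 200, seed = 9))
  ex <- ms$counts
  ab <- nb_exact_test(ex, "VT", "CHS", nb_config(dispersion = 0.1))
  ba <- nb_exact_test(ex, "CHS", "VT", nb_config(dispersion = 0.1))
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
})

test_that("planted 4-fold genes are recovered with high power at 4 vs 4", {
  ms <- simulate_mouse_study(sim_config(seed = 17))
  ex <- filter_by_tpm(ms$counts, ms$tpm, 1)
  d <- call_degs(nb_exact_test(ex, "VT", "CHS"), 0.05, 2)
  planted <- c(ms$truth$mouse_shared_up, ms$truth$mouse_shared_down)
  called <- d$gene[d$call != "none"]
  expect_gte(mean(planted %in% called), 0.90)
  # planted genes dominate the smallest p-values
  top <- d$gene[order(d$p)][seq_along(planted)]
  expect_gte(mean(top %in% c(planted, ms$truth$chs_specific, ms$truth$discordant)), 0.9)
})

test_that("exact test is calibrated under the global null", {
  cfg <- sim_config(seed = 17, mouse = list(n_shared = 0, n_specific = 0,
                                            n_discordant = 0),
                    human = list(n_signature = 0, n_human_only = 0))
  d <- nb_exact_test(simulate_mouse_study(cfg)$counts, "VT", "CHS")
  for (alpha in c(0.01, 0.05)) {
    se3 <- 3 * sqrt(alpha * (1 - alpha) / nrow(d))
    expect_lt(abs(mean(d$p < alpha) - alpha), se3)
  }
})

test_that("DEG calling applies strict FDR and fold-change thresholds", {
  d <- data.frame(gene = c("a", "b", "c", "d"),
                  log2fc = c(1.5, 3, -0.9, -2),
                  statistic = 0, p = 0.001,
                  fdr = c(0.04, 0.06, 0.01, 0.05), call = "none")
  out <- call_degs(d, 0.05, 2)
  expect_identical(out$call, c("up", "none", "none", "none"))
  out2 <- call_degs(d, 0.051, 1.5)
  expect_identical(out2$call, c("up", "none", "down", "down"))
})
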