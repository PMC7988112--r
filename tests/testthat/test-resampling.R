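pool_fixture <- function(n = 10) {
  p <- signature_table(sprintf("G%03d", seq_len(n)), rep(c(1, -1), length.out = n))
  attr(p, "pool_id") <- "test"
  p
}

test_that("random draws are reproducible, size-checked, and exhaust a full pool", {
  pool <- pool_fixture(5)
  cfg <- resampling_config(B = 4, size = 5, seed = 1)
  draws <- draw_random_signatures(pool, cfg)
  for (d in draws) expect_identical(d$gene, pool$gene)   # size = pool: forced draw
  cfg2 <- resampling_config(B = 6, size = 3, seed = 9)
  expect_identical(draw_random_signatures(pool, cfg2),
                   draw_random_signatures(pool, cfg2))
  expect_error(draw_random_signatures(pool, resampling_config(B = 2, size = 9)),
               "exceeds pool size")
  # enlarging B keeps the earlier draws (substream property)
  d10 <- draw_random_signatures(pool, resampling_config(B = 10, size = 3, seed = 9))
  expect_identical(d10[1:6], draw_random_signatures(pool, cfg2))
})

test_that("subsets are drawn uniformly from the pool", {
  pool <- pool_fixture(5)
  cfg <- resampling_config(B = 3000, size = 2, seed = 5)
  draws <- draw_random_signatures(pool, cfg)
  keys <- vapply(draws, function(d) paste(sort(d$gene), collapse = "+"), character(1))
  tab <- table(keys)
  expect_equal(length(tab), choose(5, 2))   # all 10 subsets appear
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("empirical tail p follows the add-one counting rule", {
  expect_equal(empirical_p(0.25, c(0.1, 0.2, 0.3), "right"), (1 + 1) / 4)
  expect_equal(empirical_p(0.99, runif(999, 0, 0.5), "right"), 1 / 1000)
  expect_equal(empirical_p(-1, runif(999), "right"), 1)
  expect_equal(empirical_p(0.25, c(0.1, 0.2, 0.3), "left"), (1 + 2) / 4)
  expect_error(empirical_p(0, numeric(0)), "non-empty")
  # monotone non-increasing in the observed value (right tail)
  set.seed(41)
  rs <- rnorm(200)
  obs <- sort(rnorm(20))
  ps <- vapply(obs, empirical_p, numeric(1), resampled_r = rs, tail = "right")
  expect_true(all(diff(ps) <= 0))
  # right and left tails are complementary up to the shared atom
  o <- 0.37
  expect_equal(empirical_p(o, rs, "right") + empirical_p(o, rs, "left"),
               1 + 1 / 201, tolerance = 1e-12)
})

test_that("a single resampled correlation equals the direct index-plus-correlation route", {
  set.seed(42)
  v <- named_matrix(rnorm(200, 8), 20, 10, gene_prefix = "G")
  x <- make_expr(v)
  pool <- pool_fixture(12)
  scorad <- setNames(runif(10, 20, 80), colnames(v))
  cfg <- resampling_config(B = 1, size = 5, seed = 7)
  res <- resampling_distribution(pool, x, scorad, cfg)
  drawn <- draw_random_signatures(pool, cfg)[[1]]
  idx <- ad_index(x, drawn)
  direct <- severity_correlation(idx, scorad)
  expect_equal(res$resampled_r, direct$r, tolerance = 1e-12)
})

test_that("pool comparison matches the closed-form two-sample t", {
  a <- structure(list(resampled_r = c(0.5, 0.6, 0.7, 0.65)), class = "resampling_result")
  b <- structure(list(resampled_r = c(0.2, 0.3, 0.25)), class = "resampling_result")
  out <- compare_pools(a, b)
  o <- pooled_t_oracle(b$resampled_r, a$resampled_r)   # oracle is (mean a - mean b)
  expect_equal(out$t, o$t, tolerance = 1e-12)
  expect_equal(out$p, o$p, tolerance = 1e-12)
  same <- compare_pools(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(compare_pools(a, structure(list(resampled_r = 0.1),
                                          class = "resampling_result")), ">= 2")
})

test_that("a predictive pool beats a decoy pool across seeds", {
  for (sd in c(1, 2, 3)) {
    cfg <- sim_config(n_genes = 600, seed = sd)
    val <- simulate_validation_cohort(cfg)
    tr <- simulation_truth(cfg)
    ann <- val$samples
    les <- ann$sample[ann$lesional == "lesional"]
    vl <- subset_expr(val, samples = les)
    sc <- setNames(ann$scorad, ann$sample)[les]
    predictive <- tr$signature; attr(predictive, "pool_id") <- "signature"
    decoy <- tr$human_only; attr(decoy, "pool_id") <- "decoy"
    rc <- resampling_config(B = 200, size = 18, seed = sd)
    cp <- compare_pools(resampling_distribution(predictive, vl, sc, rc),
                        resampling_distribution(decoy, vl, sc, rc))
    expect_lt(cp$p, 0.01)
    expect_gt(cp$mean_diff, 0)
  }
})

test_that("evaluating the full candidate against itself is never significant", {
  set.seed(43)
  v <- named_matrix(rnorm(300, 8), 30, 10, gene_prefix = "G")
  x <- make_expr(v)
  cand <- pool_fixture(6)
  scorad <- setNames(runif(10, 20, 80), colnames(v))
  cfg <- resampling_config(B = 50, size = 6, seed = 3)
  res <- compare_to_reference_signature(cand, cand, x, scorad, cfg)
  expect_true(all(abs(res$resampled_r - res$observed_r) < 1e-12))
  expect_equal(res$empirical_p, 1)
  expect_error(compare_to_reference_signature(cand, pool_fixture(9), x, scorad,
                                              resampling_config(B = 2)),
               "exceeds candidate")
})

test_that("a noise reference scores low against an informative candidate", {
  set.seed(44)
  ng <- 40; ns <- 40
  v <- named_matrix(rnorm(ng * ns, 8), ng, ns, gene_prefix = "G")
  sev <- rnorm(ns)
  informative <- sprintf("G%03d", 1:10)
  v[informative, ] <- v[informative, ] + outer(rep(1, 10), sev) * 1.5
  x <- make_expr(v)
  scorad <- setNames(50 + 10 * sev + rnorm(ns, 0, 2), colnames(v))
  cand <- signature_table(informative, rep(1, 10))
  ref <- signature_table(sprintf("G%03d", 31:35), rep(1, 5))  # pure noise genes
  res <- compare_to_reference_signature(cand, ref, x, scorad,
                                        resampling_config(B = 200, size = 5,
                                                          seed = 2, tail = "left"))
  expect_lt(res$empirical_p, 0.05)
})
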