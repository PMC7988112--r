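test_that("gene pools require direction concordance across every table", {
  de <- deg_fixture(c("A", "B", "C", "D"), c("up", "up", "down", "up"))
  se <- deg_fixture(c("A", "B", "C", "E"), c("up", "down", "down", "up"))
  pool <- build_gene_pool(list(de, se), pool_id = "Human")
  expect_setequal(pool$gene, c("A", "C"))          # B discordant, D/E not shared
  expect_equal(pool$weight[pool$gene == "A"], 1)
  expect_equal(pool$weight[pool$gene == "C"], -1)
  expect_identical(attr(pool, "pool_id"), "Human")
})

test_that("mouse-constrained pools intersect through the ortholog map", {
  de <- deg_fixture(c("HA", "HB"), c("up", "up"))
  se <- deg_fixture(c("HA", "HB"), c("up", "up"))
  chs <- deg_fixture(c("ma", "mc"), c("up", "up"))   # mb has no CHS call
  om <- ortholog_map(c("ma", "mb", "mc"), c("HA", "HB", "HC"))
  pool <- build_gene_pool(list(de, se), list(chs), om, pool_id = "Human+CHS")
  expect_identical(pool$gene, "HA")
  # opposite mouse direction excludes the gene
  chs2 <- deg_fixture(c("ma", "mb"), c("down", "up"))
  pool2 <- build_gene_pool(list(de, se), list(chs2), om)
  expect_identical(pool2$gene, "HB")
  expect_error(build_gene_pool(list(de), list(deg_fixture("mz", "up")), om),
               "empty gene pool")
})

test_that("signature assembly excludes genes dysregulated in opposite mouse directions", {
  om <- ortholog_map(c("m1", "m2", "m3"), c("H1", "H2", "H3"))
  chs <- deg_fixture(c("m1", "m2", "m3"), c("up", "up", "down"))
  sss <- deg_fixture(c("m1", "m2", "m3"), c("up", "down", "down"))
  de <- deg_fixture(c("H1", "H2", "H3"), c("up", "up", "down"))
  se <- deg_fixture(c("H1", "H2", "H3"), c("up", "up", "down"))
  sig <- build_signature(list(chs, sss), list(de, se), om)
  expect_setequal(sig$gene, c("H1", "H3"))          # H2 flips between models
  expect_equal(sig$weight[match(c("H1", "H3"), sig$gene)], c(1, -1))
  none <- deg_fixture(c("H1", "H2", "H3"), c("none", "none", "none"))
  expect_error(build_signature(list(chs, sss), list(none, se), om), "empty signature")
})

test_that("planted concordant genes survive the full cross-species chain", {
  cfg <- sim_config(n_genes = 600, seed = 31,
                    mouse = list(effect_log2fc = 3))
  ms <- simulate_mouse_study(cfg)
  ex <- filter_by_tpm(ms$counts, ms$tpm, 1)
  md <- list(CHS = call_degs(nb_exact_test(ex, "VT", "CHS"), 0.05, 2),
             SSS = call_degs(nb_exact_test(ex, "NT", "SSS"), 0.05, 2))
  hd <- lapply(simulate_human_cohorts(cfg)$cohorts, function(h)
    call_degs(sam_test(h, "control", "lesional", sam_config(n_perm = 300)), 0.10, 1.5))
  sig <- build_signature(md, hd, simulate_fixtures(cfg)$ortholog_map)
  tr <- ms$truth$signature
  hit <- merge(sig, tr, by = "gene")
  expect_gte(nrow(hit) / nrow(tr), 0.9)
  expect_equal(hit$weight.x, hit$weight.y)
})

test_that("the AD index is the weighted sum of per-gene z-scores", {
  v <- named_matrix(c(1, 5, 3, 2, 6, 5, 3, 7, 7, 4, 8, 9), 3, 4, gene_prefix = "G")
  x <- make_expr(v)
  sig <- signature_table(c("G001", "G002", "G003"), c(1, 1, -1))
  idx <- ad_index(x, sig)
  # spreadsheet oracle
  oracle <- sapply(seq_len(4), function(j) {
    sum(c(1, 1, -1) * (v[, j] - rowMeans(v)) / apply(v, 1, sd))
  })
  expect_equal(unname(idx$index), unname(oracle), tolerance = 1e-12)
  expect_equal(idx$n_genes_used, 3)
  # every sample at the gene-wise mean -> index 0
  vc <- named_matrix(rep(c(2, 4, 6), 4), 3, 4, gene_prefix = "G")
  vc <- vc + matrix(c(-1, 1, 0, 0, 1, -1, 0, 0, 0, 0, 0, 0), 3, 4)
  # single gene, unit z-score -> index 1
  v1 <- matrix(c(1, 2, 3), 1, 3, dimnames = list("G001", c("a", "b", "c")))
  i1 <- ad_index(make_expr(v1), signature_table("G001", 1))
  expect_equal(unname(i1$index["c"]), (3 - 2) / 1, tolerance = 1e-12)
})

test_that("AD indices sum to zero over the standardization set", {
  set.seed(32)
  v <- named_matrix(rnorm(200, 8, 2), 20, 10, gene_prefix = "G")
  x <- make_expr(v)
  sig <- signature_table(sprintf("G%03d", 1:8), rep(c(1, -1), 4))
  idx <- ad_index(x, sig)
  expect_lt(abs(sum(idx$index)), 1e-9)
})

test_that("the AD index is affine-invariant per gene and negates with the weights", {
  set.seed(33)
  v <- named_matrix(rnorm(100, 8, 2), 10, 10, gene_prefix = "G")
  sig <- signature_table(sprintf("G%03d", 1:6), c(1, 1, 1, -1, -1, 1))
  a <- ad_index(make_expr(v), sig)
  scale <- runif(10, 0.5, 3); shift <- rnorm(10, 0, 5)
  v2 <- v * scale + shift
  b <- ad_index(make_expr(v2), sig)
  expect_equal(a$index, b$index, tolerance = 1e-9)
  neg <- sig; neg$weight <- -neg$weight
  expect_equal(ad_index(make_expr(v), neg)$index, -a$index, tolerance = 1e-12)
})

test_that("missing and zero-variance signature genes are excluded with a report", {
  v <- named_matrix(c(1, 5, 2, 5, 3, 5), 2, 3, gene_prefix = "G")
  x <- make_expr(v)
  sig <- signature_table(c("G001", "G002", "ABSENT"), c(1, -1, 1))
  expect_warning(idx <- ad_index(x, sig), "zero-variance")
  expect_equal(idx$n_genes_used, 1)
  expect_setequal(idx$excluded, c("ABSENT", "G002"))
  expect_error(ad_index(x, signature_table("NOPE", 1)), "no signature gene")
})

test_that("held-out standardization uses the requested sample set", {
  set.seed(34)
  v <- named_matrix(rnorm(40, 8), 4, 10, gene_prefix = "G")
  x <- make_expr(v)
  sig <- signature_table(sprintf("G%03d", 1:4), c(1, 1, -1, -1))
  idx <- ad_index(x, sig, standardize_samples = colnames(v)[1:5])
  mu <- rowMeans(v[, 1:5]); tau <- apply(v[, 1:5], 1, sd)
  oracle <- colSums(sig$weight * (v - mu) / tau)
  expect_equal(unname(idx$index), unname(oracle), tolerance = 1e-12)
  expect_lt(abs(sum(idx$index[1:5])), 1e-9)
})

test_that("severity correlation behaves at the fixed points and rejects tiny n", {
  idx <- setNames(c(1, 2, 3, 4, 5), paste0("s", 1:5))
  expect_equal(severity_correlation(idx, idx * 3 + 2)$r, 1, tolerance = 1e-12)
  expect_error(severity_correlation(idx[1:2], idx[1:2]), ">= 3")
  # independent severity: |r| small on average, p roughly uniform
  set.seed(35)
  ps <- replicate(200, {
    x <- rnorm(30); y <- rnorm(30)
    severity_correlation(setNames(x, 1:30), setNames(y, 1:30))$p
  })
  expect_lt(suppressWarnings(ks.test(ps, "punif")$statistic), 0.1)
})

test_that("designed severity correlation is recovered within the sampling band", {
  set.seed(36)
  rs <- replicate(30, {
    n <- 50
    z <- rnorm(n)
    scorad <- 2 * z + rnorm(n, 0, 2 * sqrt(1 / 0.8^2 - 1))
    severity_correlation(setNames(z, 1:n), setNames(scorad, 1:n))$r
  })
  expect_gte(mean(rs >= 0.65 & rs <= 0.95), 0.9)
})

test_that("paired timepoint tests match the closed-form paired t", {
  set.seed(37)
  n <- 5
  idx <- setNames(c(rnorm(n, 2), rnorm(n, 1)), c(paste0("S", 1:n, "_b"),
                                                 paste0("S", 1:n, "_w")))
  ann <- data.frame(sample = names(idx),
                    subject = rep(paste0("S", 1:n), 2),
                    timepoint = rep(c("baseline", "week2"), each = n),
                    lesional = "lesional", stringsAsFactors = FALSE)
  out <- paired_timepoint_test(idx, ann, "baseline", "week2", "lesional")
  o <- paired_t_oracle(idx[1:n], idx[n + 1:n])
  expect_equal(out$t, o$t, tolerance = 1e-12)
  expect_equal(out$p, o$p, tolerance = 1e-12)
  expect_equal(out$n_pairs, n)
  # identical pre/post -> t = 0, p = 1
  idx2 <- idx; idx2[n + 1:n] <- idx2[1:n]
  out2 <- paired_timepoint_test(idx2, ann, "baseline", "week2", "lesional")
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
  # unpaired subject is excluded and counted
  ann3 <- rbind(ann, data.frame(sample = "extra", subject = "S99",
                                timepoint = "baseline", lesional = "lesional"))
  idx3 <- c(idx, extra = 5)
  out3 <- paired_timepoint_test(idx3, ann3, "baseline", "week2", "lesional")
  expect_equal(out3$n_pairs, n)
  expect_equal(out3$n_excluded_subjects, 1)
  expect_equal(out3$t, out$t, tolerance = 1e-12)
})
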