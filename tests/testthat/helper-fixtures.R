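# small deterministic fixtures shared across tests

make_expr <- function(values, kind = "log_intensity", groups = NULL, ...) {
  ann <- NULL
  if (!is.null(groups)) {
    ann <- data.frame(sample = colnames(values), group = groups,
                      stringsAsFactors = FALSE, ...)
  }
  expression_matrix(values, kind, samples = ann)
}

# genes x samples matrix with deterministic dimnames
named_matrix <- function(values, n_genes, n_samples, gene_prefix = "g",
                         sample_prefix = "s") {
  matrix(values, n_genes, n_samples,
         dimnames = list(sprintf("%s%03d", gene_prefix, seq_len(n_genes)),
                         sprintf("%s%02d", sample_prefix, seq_len(n_samples))))
}

# a tiny two-group log-intensity matrix with given per-group means
two_group_expr <- function(mean_a, mean_b, n_a = 3, n_b = 3, sd = 0.5, seed = 1) {
  set.seed(seed)
  ng <- length(mean_a)
  va <- matrix(rnorm(ng * n_a, mean_a, sd), ng, n_a)
  vb <- matrix(rnorm(ng * n_b, mean_b, sd), ng, n_b)
  v <- cbind(va, vb)
  dimnames(v) <- list(sprintf("g%03d", seq_len(ng)),
                      c(sprintf("a%02d", seq_len(n_a)), sprintf("b%02d", seq_len(n_b))))
  make_expr(v, groups = rep(c("A", "B"), c(n_a, n_b)))
}

# independent closed-form oracle: equal-variance two-sample t
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# independent closed-form oracle: paired t on differences
paired_t_oracle <- function(x0, x1) {
  d <- x1 - x0
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = t, p = 2 * pt(-abs(t), length(d) - 1))
}

# a down-scaled simulated-study configuration for fast module tests
small_sim_cfg <- function(n_genes = 150, seed = 1, mouse = list(),
                          human = list(), ...) {
  sim_config(n_genes = n_genes, seed = seed,
             mouse = utils::modifyList(
               list(n_shared = 10, n_specific = 10, n_discordant = 4), mouse),
             human = utils::modifyList(
               list(n_signature = 12, n_human_only = 16), human), ...)
}

# a called DEG table from explicit gene/direction pairs
deg_fixture <- function(genes, calls) {
  lfc <- ifelse(calls == "up", 2, ifelse(calls == "down", -2, 0))
  data.frame(gene = genes, log2fc = lfc, statistic = lfc, p = 0.001,
             fdr = ifelse(calls == "none", 0.9, 0.001), call = calls,
             stringsAsFactors = FALSE)
}
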