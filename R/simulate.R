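#' Configuration for synthetic cross-species AD studies
#'
#' Defines the conditions of a complete simulated study: two mouse models
#' with their controls (NB-distributed RNA-seq counts with planted shared,
#' model-specific and discordant DEGs), two human discovery cohorts
#' (log-normal microarray intensities with direction-concordant planted
#' lesional effects), and a validation cohort whose SCORAD severity score is
#' a noisy linear function of the planted-signature expression, with paired
#' treatment attenuation across timepoints.
#'
#' @param n_genes Number of genes (one-to-one mouse/human orthologs).
#' @param n_pathways Number of random gene sets (sizes 10-100) in the GMT
#'   fixture, plus two planted sets holding the up/down planted genes.
#' @param mouse List: `n_per_group` (4), `phi` (NB dispersion, 0.1),
#'   `mean_range` (baseline means, log-uniform 5-500), `n_shared` (planted
#'   shared DEGs per direction, 30), `n_specific` (model-specific DEGs per
#'   model, 50), `n_discordant` (genes dysregulated in opposite directions,
#'   10), `effect_log2fc` (2), `libsize_jitter` (0.3).
#' @param human List: `n_control` / `n_lesional` per cohort (DE-like 14/12,
#'   SE-like 10/10), `sigma` (log2 noise SD, 0.4), `effect` (planted log2
#'   shift, 1.2), `n_signature` (planted concordant images of mouse-shared
#'   DEGs, 36), `n_human_only` (planted genes without mouse support, 60).
#' @param validation List: `n_subjects` (19), `timepoints`, `attenuation`
#'   (latent-severity multiplier per timepoint), `rho` (target SCORAD vs
#'   mean-signature-z correlation over lesional samples, 0.8), `sigma`
#'   (expression noise, 0.4), `effect` (log2 shift per latent-severity unit,
#'   1.0), `tissue_loading` (severity loading by compartment),
#'   `pool_loading` (relative loading of planted non-signature pool genes,
#'   0.3), `lesional_shift` (constant lesional-vs-nonlesional offset, 0.8).
#' @param n_decoy_orthologs Ambiguous decoy pairs added to the ortholog map
#'   (dropped by the one-to-one filter, exercising the report path).
#' @param seed Integer master seed.
#' @return Nested list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_pathways = 50,
                       mouse = list(),
                       human = list(),
                       validation = list(),
                       n_decoy_orthologs = 20,
                       seed = 17) {
  mouse <- utils::modifyList(list(
    n_per_group = 4, phi = 0.1, mean_range = c(5, 500),
    n_shared = 30, n_specific = 50, n_discordant = 10,
    effect_log2fc = 2, libsize_jitter = 0.3), mouse)
  human <- utils::modifyList(list(
    n_control = c(DE = 14, SE = 10), n_lesional = c(DE = 12, SE = 10),
    sigma = 0.4, effect = 1.2, n_signature = 36, n_human_only = 60), human)
  validation <- utils::modifyList(list(
    n_subjects = 19,
    timepoints = c("baseline", "week2", "week12"),
    attenuation = c(baseline = 1.0, week2 = 0.55, week12 = 0.45),
    rho = 0.8, sigma = 0.4, effect = 1.0,
    tissue_loading = c(lesional = 1.0, nonlesional = 0.5),
    pool_loading = 0.3, lesional_shift = 0.8,
    scorad_center = 50, scorad_scale = 15), validation)
  planted <- 2 * mouse$n_shared + 2 * mouse$n_specific + mouse$n_discordant +
    human$n_human_only
  if (planted > n_genes) stop("planted gene sets exceed n_genes")
  if (human$n_signature > 2 * mouse$n_shared)
    stop("n_signature cannot exceed the planted shared DEGs")
  stopifnot(validation$rho > 0, validation$rho < 1)
  structure(list(n_genes = n_genes, n_pathways = n_pathways, mouse = mouse,
                 human = human, validation = validation,
                 n_decoy_orthologs = n_decoy_orthologs, seed = as.integer(seed)),
            class = "sim_config")
}

mouse_symbols <- function(n) sprintf("mg%05d", seq_len(n))
human_symbols <- function(n) sprintf("HG%05d", seq_len(n))

# deterministic planted-gene layout shared by all simulate_* functions:
# which genes are shared/model-specific/discordant/human-only, with signs
planted_layout <- function(cfg) {
  set.seed(cfg$seed)
  mg <- mouse_symbols(cfg$n_genes)
  hg <- human_symbols(cfg$n_genes)
  m <- cfg$mouse
  need <- 2 * m$n_shared + 2 * m$n_specific + m$n_discordant + cfg$human$n_human_only
  idx <- sample.int(cfg$n_genes, need)
  take <- function(k) { out <- idx[seq_len(k)]; idx <<- idx[-seq_len(k)]; out }
  shared_up <- take(m$n_shared); shared_down <- take(m$n_shared)
  chs_spec <- take(m$n_specific); sss_spec <- take(m$n_specific)
  discord <- take(m$n_discordant)
  human_only <- take(cfg$human$n_human_only)
  # the true signature: a subset of the shared DEGs also planted in humans
  ns <- cfg$human$n_signature
  n_up <- ceiling(ns / 2)
  sig_idx <- c(shared_up[seq_len(min(n_up, length(shared_up)))],
               shared_down[seq_len(ns - min(n_up, length(shared_up)))])
  sig_sign <- c(rep(1, min(n_up, length(shared_up))),
                rep(-1, ns - min(n_up, length(shared_up))))
  ho_sign <- rep(c(1, -1), length.out = length(human_only))
  list(mouse_genes = mg, human_genes = hg,
       shared_up = shared_up, shared_down = shared_down,
       chs_specific = chs_spec, sss_specific = sss_spec,
       discordant = discord, human_only = human_only,
       sig_idx = sig_idx, sig_sign = sig_sign, human_only_sign = ho_sign)
}

#' Ground truth of a simulated study
#'
#' @param cfg A [sim_config()].
#' @return List with the planted gene sets (human and mouse symbol space),
#'   the implied true signature (`signature`: data.frame `gene`, `weight`),
#'   the planted human-only pool genes, and the designed severity
#'   correlation `rho`.
#' @export
simulation_truth <- function(cfg) {
  lay <- planted_layout(cfg)
  list(
    mouse_shared_up = lay$mouse_genes[lay$shared_up],
    mouse_shared_down = lay$mouse_genes[lay$shared_down],
    chs_specific = lay$mouse_genes[lay$chs_specific],
    sss_specific = lay$mouse_genes[lay$sss_specific],
    discordant = lay$mouse_genes[lay$discordant],
    human_concordant = data.frame(
      gene = c(lay$human_genes[lay$sig_idx], lay$human_genes[lay$human_only]),
      weight = c(lay$sig_sign, lay$human_only_sign), stringsAsFactors = FALSE),
    human_only = data.frame(gene = lay$human_genes[lay$human_only],
                            weight = lay$human_only_sign, stringsAsFactors = FALSE),
    signature = signature_table(lay$human_genes[lay$sig_idx], lay$sig_sign),
    rho = cfg$validation$rho)
}

#' Simulate the two mouse models and their controls
#'
#' Counts are negative-binomial (variance `mu + phi * mu^2`) around
#' log-uniform baseline means with per-sample library-size jitter. Shared
#' DEGs are perturbed identically in the CHS and SSS groups, model-specific
#' DEGs in one model only, and discordant genes in opposite directions. TPM
#' is derived from the counts with unit gene lengths.
#'
#' @param cfg A [sim_config()].
#' @return List: `counts` (`expr_matrix`, groups VT/CHS/NT/SSS), `tpm`,
#'   `truth` (see [simulation_truth()]).
#' @export
simulate_mouse_study <- function(cfg = sim_config()) {
  lay <- planted_layout(cfg)
  m <- cfg$mouse
  set.seed(cfg$seed + 1L)
  base <- exp(stats::runif(cfg$n_genes, log(m$mean_range[1]), log(m$mean_range[2])))
  groups <- rep(c("VT", "CHS", "NT", "SSS"), each = m$n_per_group)
  ids <- paste0(groups, "_", sequence(rep(m$n_per_group, 4)))
  lfc <- matrix(0, cfg$n_genes, 4, dimnames = list(NULL, c("VT", "CHS", "NT", "SSS")))
  e <- m$effect_log2fc
  lfc[lay$shared_up, c("CHS", "SSS")] <- e
  lfc[lay$shared_down, c("CHS", "SSS")] <- -e
  half <- seq_len(floor(m$n_specific / 2))
  lfc[lay$chs_specific[half], "CHS"] <- e
  lfc[lay$chs_specific[-half], "CHS"] <- -e
  lfc[lay$sss_specific[half], "SSS"] <- e
  lfc[lay$sss_specific[-half], "SSS"] <- -e
  dhalf <- seq_len(floor(m$n_discordant / 2))
  lfc[lay$discordant[dhalf], "CHS"] <- e
  lfc[lay$discordant[dhalf], "SSS"] <- -e
  lfc[lay$discordant[-dhalf], "CHS"] <- -e
  lfc[lay$discordant[-dhalf], "SSS"] <- e
  lib <- exp(stats::runif(length(ids), -log1p(m$libsize_jitter), log1p(m$libsize_jitter)))
  counts <- matrix(0L, cfg$n_genes, length(ids),
                   dimnames = list(lay$mouse_genes, ids))
  for (j in seq_along(ids)) {
    mu <- base * 2^lfc[, groups[j]] * lib[j]
    counts[, j] <- stats::rnbinom(cfg$n_genes, size = 1 / m$phi, mu = mu)
  }
  ann <- data.frame(sample = ids, group = groups, stringsAsFactors = FALSE)
  cem <- expression_matrix(counts, "counts", samples = ann)
  tpmv <- sweep(counts, 2, colSums(counts), "/") * 1e6
  tpm <- expression_matrix(tpmv, "tpm", samples = ann)
  list(counts = cem, tpm = tpm, truth = simulation_truth(cfg))
}

#' Simulate the two human discovery cohorts
#'
#' Log2 intensities are gene baselines plus Normal(0, sigma) noise; the
#' planted lesional effect (direction-concordant across both cohorts) is
#' applied to the true-signature genes and to the human-only pool genes.
#' With `probe_level = TRUE` each cohort is additionally emitted at probe
#' resolution (2-3 probes per gene with jitter) together with the probe map,
#' to exercise [collapse_probes()].
#'
#' @param cfg A [sim_config()].
#' @param probe_level Also return probe-level matrices.
#' @return List: `cohorts` (named list of `expr_matrix`, groups
#'   control/lesional), `truth`, and with `probe_level` also `probes`
#'   (matrices) and `probe_map`.
#' @export
simulate_human_cohorts <- function(cfg = sim_config(), probe_level = FALSE) {
  lay <- planted_layout(cfg)
  h <- cfg$human
  set.seed(cfg$seed + 2L)
  effect <- numeric(cfg$n_genes)
  effect[lay$sig_idx] <- h$effect * lay$sig_sign
  effect[lay$human_only] <- h$effect * lay$human_only_sign
  cohorts <- list(); probes <- list(); pmap <- NULL
  for (co in names(h$n_control)) {
    nc <- h$n_control[[co]]; nl <- h$n_lesional[[co]]
    ids <- c(paste0(co, "_C", seq_len(nc)), paste0(co, "_L", seq_len(nl)))
    grp <- c(rep("control", nc), rep("lesional", nl))
    base <- stats::runif(cfg$n_genes, 6, 12)
    vals <- base + outer(effect, as.numeric(grp == "lesional")) +
      matrix(stats::rnorm(cfg$n_genes * length(ids), 0, h$sigma),
             cfg$n_genes, length(ids))
    dimnames(vals) <- list(lay$human_genes, ids)
    ann <- data.frame(sample = ids, group = grp, lesional = grp,
                      stringsAsFactors = FALSE)
    cohorts[[co]] <- expression_matrix(vals, "log_intensity", samples = ann)
    if (probe_level) {
      npr <- sample(2:3, cfg$n_genes, replace = TRUE)
      gi <- rep(seq_len(cfg$n_genes), npr)
      pid <- paste0(co, "_p", seq_along(gi))
      pv <- vals[gi, , drop = FALSE] +
        matrix(stats::rnorm(length(gi) * length(ids), 0, 0.1), length(gi), length(ids))
      rownames(pv) <- pid
      probes[[co]] <- expression_matrix(pv, "log_intensity", samples = ann)
      pmap <- rbind(pmap, data.frame(probe = pid, gene = lay$human_genes[gi],
                                     stringsAsFactors = FALSE))
    }
  }
  out <- list(cohorts = cohorts, truth = simulation_truth(cfg))
  if (probe_level) { out$probes <- probes; out$probe_map <- pmap }
  out
}

#' Simulate the treatment validation cohort
#'
#' Each subject carries a positive latent severity, attenuated by treatment
#' at later timepoints, and contributes one lesional and one non-lesional
#' sample per timepoint. Expression of the scored signature's genes loads on
#' the latent severity (more strongly in lesional skin), plus a constant
#' lesional shift; planted pool genes without mouse support load weakly
#' (`pool_loading`). SCORAD is generated per sample as a linear function of
#' the realized mean signature z-score plus Normal noise whose SD is
#' calibrated analytically (`sigma_eps = a * sd(z) * sqrt(1/rho^2 - 1)`) so
#' the designed correlation over lesional samples equals `rho`.
#'
#' @param cfg A [sim_config()].
#' @param sig Signature whose genes carry the severity signal (default: the
#'   configuration's true signature).
#' @return An `expr_matrix` with `scorad`, `subject`, `timepoint` and
#'   `lesional` annotations.
#' @export
simulate_validation_cohort <- function(cfg = sim_config(), sig = NULL) {
  lay <- planted_layout(cfg)
  v <- cfg$validation
  truth <- simulation_truth(cfg)
  if (is.null(sig)) sig <- truth$signature
  if (!nrow(sig)) stop("signature must be non-empty")
  set.seed(cfg$seed + 3L)
  subj <- sprintf("S%02d", seq_len(v$n_subjects))
  grid <- expand.grid(subject = subj, timepoint = v$timepoints,
                      lesional = c("lesional", "nonlesional"),
                      stringsAsFactors = FALSE)
  ids <- sprintf("%s_%s_%s", grid$subject, grid$timepoint,
                 ifelse(grid$lesional == "lesional", "L", "NL"))
  latent <- stats::setNames(stats::rnorm(v$n_subjects, 2, 0.6), subj)
  sev <- latent[grid$subject] * v$attenuation[grid$timepoint] *
    v$tissue_loading[grid$lesional]
  base <- stats::runif(cfg$n_genes, 6, 12)
  load <- numeric(cfg$n_genes)
  si <- match(sig$gene, lay$human_genes)
  if (anyNA(si)) stop("signature genes outside the simulated gene universe")
  load[si] <- v$effect * sig$weight
  ho <- setdiff(lay$human_only, si)
  load[ho] <- v$effect * v$pool_loading *
    lay$human_only_sign[match(lay$human_genes[ho], truth$human_only$gene)]
  shift <- numeric(cfg$n_genes)
  shift[si] <- v$lesional_shift * sig$weight
  vals <- base + outer(load, sev) +
    outer(shift, as.numeric(grid$lesional == "lesional")) +
    matrix(stats::rnorm(cfg$n_genes * length(ids), 0, v$sigma),
           cfg$n_genes, length(ids))
  dimnames(vals) <- list(lay$human_genes, ids)
  # mean signature z across all samples, the quantity SCORAD tracks
  sv <- vals[si, , drop = FALSE]
  z <- (sv - rowMeans(sv)) / apply(sv, 1, stats::sd)
  zbar <- as.vector(crossprod(z, sig$weight)) / nrow(sig)
  les <- grid$lesional == "lesional"
  a <- v$scorad_scale / stats::sd(zbar[les])
  sigma_eps <- a * stats::sd(zbar[les]) * sqrt(1 / v$rho^2 - 1)
  scorad <- pmax(0, v$scorad_center + a * zbar +
                   stats::rnorm(length(ids), 0, sigma_eps))
  ann <- data.frame(sample = ids, group = grid$lesional, lesional = grid$lesional,
                    scorad = scorad, subject = grid$subject,
                    timepoint = grid$timepoint, stringsAsFactors = FALSE)
  expression_matrix(vals, "log_intensity", samples = ann)
}

#' Simulated ortholog map and pathway fixtures
#'
#' The ortholog map is the simulation's mouse-to-human bijection plus a
#' configurable number of ambiguous decoy pairs (extra symbols with
#' one-to-many mappings) that the one-to-one filter must drop. The gene-set
#' collection holds `n_pathways` random sets (sizes 10-100) plus two planted
#' sets collecting the up- and down-planted human genes.
#'
#' @param cfg A [sim_config()].
#' @return List: `ortholog_map` (filtered, with `"dropped"` attribute),
#'   `gene_sets` (named list, human symbols).
#' @export
simulate_fixtures <- function(cfg = sim_config()) {
  lay <- planted_layout(cfg)
  set.seed(cfg$seed + 4L)
  mouse <- lay$mouse_genes; human <- lay$human_genes
  if (cfg$n_decoy_orthologs > 0) {
    k <- cfg$n_decoy_orthologs
    dm <- sprintf("mx%03d", seq_len(k))
    dh <- sprintf("HX%03d", seq_len(2 * k))
    mouse <- c(mouse, rep(dm, each = 2))
    human <- c(human, dh)
  }
  om <- ortholog_map(mouse, human)
  sizes <- sample(10:100, cfg$n_pathways, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(lay$human_genes, s))
  names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(cfg$n_pathways))
  up <- lay$human_genes[c(lay$sig_idx[lay$sig_sign > 0],
                          lay$human_only[lay$human_only_sign > 0])]
  dn <- lay$human_genes[c(lay$sig_idx[lay$sig_sign < 0],
                          lay$human_only[lay$human_only_sign < 0])]
  sets$PLANTED_UP <- unique(up)
  sets$PLANTED_DOWN <- unique(dn)
  list(ortholog_map = om, gene_sets = sets)
}
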