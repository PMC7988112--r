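#' Configuration for a full pipeline run
#'
#' Collects every input path, threshold and stage configuration of the
#' end-to-end analysis (mouse DEGs -> human DEGs -> pathway concordance ->
#' signature -> AD index -> resampling). Threshold defaults are the study's:
#' mouse contrasts at FDR < 5% and FC > 2, human cohorts at FDR < 10% and
#' FC > 1.5, expressed genes at mean TPM > 1.
#'
#' @param mouse_counts,mouse_tpm,mouse_annotation Paths for the mouse count
#'   matrix, TPM matrix and sample annotations.
#' @param mouse_contrasts Named list of `c(control, model)` group pairs.
#' @param human Named list of cohorts, each `list(expr=, annotation=)`
#'   (log2-intensity TSVs, groups `control`/`lesional`).
#' @param validation `list(expr=, annotation=)` for the treatment cohort
#'   (with `scorad`, `subject`, `timepoint`, `lesional` annotations).
#' @param gmt,orthologs Paths for the gene-set GMT and the ortholog TSV.
#' @param out_dir Output directory (created if needed).
#' @param mouse_fdr,mouse_fc,human_fdr,human_fc,min_mean_tpm Calling
#'   thresholds.
#' @param nb,sam,faime Stage configurations.
#' @param resampling_B Number of random signatures per pool.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mouse_counts, mouse_tpm, mouse_annotation,
                            human, validation, gmt, orthologs, out_dir,
                            mouse_contrasts = list(CHS = c("VT", "CHS"),
                                                   SSS = c("NT", "SSS")),
                            mouse_fdr = 0.05, mouse_fc = 2,
                            human_fdr = 0.10, human_fc = 1.5,
                            min_mean_tpm = 1,
                            nb = nb_config(), sam = sam_config(),
                            faime = faime_config(), resampling_B = 1000,
                            seed = 17) {
  structure(list(mouse_counts = mouse_counts, mouse_tpm = mouse_tpm,
                 mouse_annotation = mouse_annotation,
                 mouse_contrasts = mouse_contrasts,
                 human = human, validation = validation, gmt = gmt,
                 orthologs = orthologs, out_dir = out_dir,
                 mouse_fdr = mouse_fdr, mouse_fc = mouse_fc,
                 human_fdr = human_fdr, human_fc = human_fc,
                 min_mean_tpm = min_mean_tpm, nb = nb, sam = sam,
                 faime = faime, resampling_B = resampling_B,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full cross-species signature pipeline
#'
#' Executes, in order: TPM filtering and NB exact tests on the mouse
#' contrasts; SAM tests on the human cohorts; FAIME pathway scoring with
#' per-contrast t-statistics and cross-contrast correlations; assembly of
#' the direction-concordant cross-species signature; AD-index scoring of
#' the validation cohort with SCORAD correlations and paired treatment
#' tests; and pool-based resampling benchmarks. Every intermediate table is
#' written as TSV under `cfg$out_dir` together with a JSON run report.
#' Output is byte-identical across runs with the same config and seed.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the run report list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)
  report <- list(seed = cfg$seed,
                 thresholds = cfg[c("mouse_fdr", "mouse_fc", "human_fdr",
                                    "human_fc", "min_mean_tpm")],
                 stages = character(0), counts = list(), warnings = character(0))
  note <- function(stage) report$stages <<- c(report$stages, stage)

  # --- mouse DEGs -----------------------------------------------------------
  note("mouse_deg")
  counts <- read_expression_matrix(cfg$mouse_counts, "counts", cfg$mouse_annotation)
  tpm <- read_expression_matrix(cfg$mouse_tpm, "tpm", cfg$mouse_annotation)
  expressed <- filter_by_tpm(counts, tpm, cfg$min_mean_tpm)
  report$counts$genes_total <- nrow(counts$values)
  report$counts$genes_expressed <- nrow(expressed$values)
  mouse_deg <- lapply(cfg$mouse_contrasts, function(ct) {
    call_degs(nb_exact_test(expressed, ct[1], ct[2], cfg$nb),
              cfg$mouse_fdr, cfg$mouse_fc)
  })
  for (nm in names(mouse_deg))
    write_deg_table(mouse_deg[[nm]], out(paste0("deg_mouse_", nm, ".tsv")))
  report$counts$mouse_called <- lapply(mouse_deg, function(d) {
    list(up = sum(d$call == "up"), down = sum(d$call == "down"))
  })

  # --- human DEGs -----------------------------------------------------------
  note("human_deg")
  human <- lapply(cfg$human, function(h)
    read_expression_matrix(h$expr, "log_intensity", h$annotation))
  human_deg <- lapply(human, function(hm)
    call_degs(sam_test(hm, "control", "lesional", cfg$sam),
              cfg$human_fdr, cfg$human_fc))
  for (nm in names(human_deg))
    write_deg_table(human_deg[[nm]], out(paste0("deg_human_", nm, ".tsv")))
  report$counts$human_called <- lapply(human_deg, function(d) {
    list(up = sum(d$call == "up"), down = sum(d$call == "down"))
  })

  # --- pathway concordance --------------------------------------------------
  note("pathways")
  sets <- read_gene_sets(cfg$gmt)
  om <- read_ortholog_map(cfg$orthologs)
  report$counts$orthologs_kept <- nrow(om)
  report$counts$orthologs_dropped_ambiguous <- nrow(attr(om, "dropped"))
  mouse_sets <- map_gene_sets(sets, om, to = "mouse")
  mscore <- suppressWarnings(faime_scores(expressed, mouse_sets, cfg$faime))
  mouse_ct <- lapply(cfg$mouse_contrasts, function(ct)
    pathway_contrast(mscore, expressed$samples, ct[1], ct[2]))
  human_ct <- lapply(human, function(hm) {
    sc <- suppressWarnings(faime_scores(hm, sets, cfg$faime))
    pathway_contrast(sc, hm$samples, "control", "lesional")
  })
  long <- do.call(rbind, lapply(names(c(mouse_ct, human_ct)), function(nm) {
    ct <- c(mouse_ct, human_ct)[[nm]]
    data.frame(pathway = ct$pathway, contrast = nm, t = ct$t,
               p_corrected = ct$p_corrected, stringsAsFactors = FALSE)
  }))
  long <- long[order(long$pathway, long$contrast), ]
  writeLines(c("pathway\tcontrast\tt\tp_corrected",
               paste(long$pathway, long$contrast, fmt_num(long$t),
                     fmt_num(long$p_corrected), sep = "\t")),
             out("pathway_contrasts.tsv"), useBytes = TRUE)
  cors <- list()
  for (mn in names(mouse_ct)) for (hn in names(human_ct)) {
    cc <- contrast_correlation(mouse_ct[[mn]], human_ct[[hn]])
    cors[[paste(mn, hn, sep = "_vs_")]] <- cc
  }
  report$pathway_correlations <- cors

  # --- signature ------------------------------------------------------------
  note("signature")
  sig <- build_signature(mouse_deg, human_deg, om)
  write_signature(sig, out("signature.tsv"))
  report$counts$signature_size <- nrow(sig)
  mouse_shared <- intersect_directions(lapply(mouse_deg, function(d)
    map_mouse_calls(called_directions(d), om)))
  report$counts$mouse_shared_concordant <- length(mouse_shared)

  # --- AD index on the validation cohort ------------------------------------
  note("ad_index")
  val <- read_expression_matrix(cfg$validation$expr, "log_intensity",
                                cfg$validation$annotation)
  idx <- ad_index(val, sig)
  ann <- val$samples
  writeLines(c("sample\tindex\tn_genes_used",
               paste(sort(names(idx$index)),
                     fmt_num(idx$index[sort(names(idx$index))]),
                     idx$n_genes_used, sep = "\t")),
             out("ad_index.tsv"), useBytes = TRUE)
  scorad <- stats::setNames(ann$scorad, ann$sample)
  les <- ann$sample[!is.na(ann$lesional) & ann$lesional == "lesional"]
  nles <- ann$sample[!is.na(ann$lesional) & ann$lesional == "nonlesional"]
  report$severity <- list(
    lesional = severity_correlation(idx$index[les], scorad[les]),
    nonlesional = severity_correlation(idx$index[nles], scorad[nles]))
  report$treatment <- list(
    lesional_wk2 = paired_timepoint_test(idx, ann, "baseline", "week2", "lesional"),
    lesional_wk12 = paired_timepoint_test(idx, ann, "week2", "week12", "lesional"),
    nonlesional_wk2 = paired_timepoint_test(idx, ann, "baseline", "week2", "nonlesional"))

  # --- resampling benchmarks ------------------------------------------------
  note("resampling")
  pools <- list(Human = build_gene_pool(human_deg, pool_id = "Human"))
  for (nm in names(mouse_deg)) {
    pid <- paste0("Human+", nm)
    pools[[pid]] <- tryCatch(
      build_gene_pool(human_deg, mouse_deg[nm], om, pool_id = pid),
      error = function(e) NULL)
  }
  pools <- Filter(Negate(is.null), pools)
  rcfg <- resampling_config(B = cfg$resampling_B, size = nrow(sig),
                            seed = cfg$seed, tail = "right")
  scorad_les <- scorad[les]
  val_les <- subset_expr(val, samples = les)
  results <- lapply(pools, function(p) {
    p_eff <- if (nrow(p) >= nrow(sig)) p else NULL
    if (is.null(p_eff)) return(NULL)
    evaluate_signature(sig, p_eff, val_les, scorad_les, rcfg)
  })
  results <- Filter(Negate(is.null), results)
  report$resampling <- lapply(results, function(r)
    list(observed_r = r$observed_r, empirical_p = r$empirical_p,
         mean_resampled_r = mean(r$resampled_r)))
  if (all(c("Human", "Human+CHS") %in% names(results)))
    report$pool_comparison <- compare_pools(results[["Human+CHS"]], results[["Human"]])
  for (nm in names(results)) {
    writeLines(c("r", fmt_num(results[[nm]]$resampled_r)),
               out(paste0("resampled_r_", gsub("[^A-Za-z0-9]+", "_", nm), ".tsv")),
               useBytes = TRUE)
  }

  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(report)
}
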