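# Venet-style benchmark: the assembled signature's SCORAD correlation is
# placed in the distribution of 1000 random size-matched signatures drawn
# from each gene pool (Human, Human+CHS, Human+SSS), and the pools are
# compared against each other.
source("analysis/00_config.R")

md <- list(CHS = read_deg_table(file.path(OUT_DIR, "deg_mouse_CHS.tsv")),
           SSS = read_deg_table(file.path(OUT_DIR, "deg_mouse_SSS.tsv")))
hd <- list(DE = read_deg_table(file.path(OUT_DIR, "deg_human_DE.tsv")),
           SE = read_deg_table(file.path(OUT_DIR, "deg_human_SE.tsv")))
om <- read_ortholog_map(file.path(STUDY_DIR, "orthologs.tsv"))
sig <- read_signature(file.path(OUT_DIR, "signature.tsv"))
val <- read_expression_matrix(file.path(STUDY_DIR, "validation.tsv"), "log_intensity",
                              file.path(STUDY_DIR, "validation_annotation.tsv"))
ann <- val$samples
les <- ann$sample[ann$lesional == "lesional"]
scorad <- setNames(ann$scorad, ann$sample)[les]
val_les <- subset_expr(val, samples = les)

pools <- list(Human = build_gene_pool(hd, pool_id = "Human"))
for (nm in names(md)) {
  pid <- paste0("Human+", nm)
  pools[[pid]] <- build_gene_pool(hd, md[nm], om, pool_id = pid)
}

rcfg <- resampling_config(B = 1000, size = nrow(sig), seed = STUDY_SEED, tail = "right")
results <- lapply(pools, function(p) evaluate_signature(sig, p, val_les, scorad, rcfg))
for (nm in names(results)) {
  r <- results[[nm]]
  cat(sprintf("%-10s pool (%3d genes): mean resampled r = %.3f, signature r = %.3f, right-tail p = %.3f\n",
              nm, nrow(pools[[nm]]), mean(r$resampled_r), r$observed_r, r$empirical_p))
  writeLines(c("r", format(r$resampled_r, digits = 6)),
             file.path(OUT_DIR, sprintf("resampled_r_%s.tsv", gsub("[^A-Za-z0-9]+", "_", nm))))
}
cp <- compare_pools(results[["Human+CHS"]], results[["Human"]])
cat(sprintf("Human+CHS vs Human pools: mean r difference %.3f (t-test p = %.2g)\n",
            cp$mean_diff, cp$p))
cp2 <- compare_pools(results[["Human+CHS"]], results[["Human+SSS"]])
cat(sprintf("Human+CHS vs Human+SSS pools: mean r difference %.3f (t-test p = %.2g)\n",
            cp2$mean_diff, cp2$p))
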