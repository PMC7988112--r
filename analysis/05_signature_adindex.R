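# Assembles the cross-species signature from the called DEG tables, scores
# the validation cohort with the AD index, and tests severity correlation
# and paired treatment response.
source("analysis/00_config.R")

md <- list(CHS = read_deg_table(file.path(OUT_DIR, "deg_mouse_CHS.tsv")),
           SSS = read_deg_table(file.path(OUT_DIR, "deg_mouse_SSS.tsv")))
hd <- list(DE = read_deg_table(file.path(OUT_DIR, "deg_human_DE.tsv")),
           SE = read_deg_table(file.path(OUT_DIR, "deg_human_SE.tsv")))
om <- read_ortholog_map(file.path(STUDY_DIR, "orthologs.tsv"))

sig <- build_signature(md, hd, om)
write_signature(sig, file.path(OUT_DIR, "signature.tsv"))
truth <- read_signature(file.path(STUDY_DIR, "true_signature.tsv"))
hit <- merge(sig, truth, by = "gene")
cat(sprintf("signature: %d genes (%d up, %d down); recovers %d/%d planted, %d sign errors\n",
            nrow(sig), sum(sig$weight > 0), sum(sig$weight < 0),
            nrow(hit), nrow(truth), sum(hit$weight.x != hit$weight.y)))

val <- read_expression_matrix(file.path(STUDY_DIR, "validation.tsv"), "log_intensity",
                              file.path(STUDY_DIR, "validation_annotation.tsv"))
idx <- ad_index(val, sig)
ann <- val$samples
write.table(data.frame(sample = names(idx$index), index = idx$index,
                       row.names = NULL),
            file.path(OUT_DIR, "ad_index.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

scorad <- setNames(ann$scorad, ann$sample)
for (tissue in c("lesional", "nonlesional")) {
  s <- ann$sample[ann$lesional == tissue]
  cc <- severity_correlation(idx$index[s], scorad[s])
  cat(sprintf("AD index vs SCORAD, %s: r = %.3f (p = %.2g, n = %d)\n",
              tissue, cc$r, cc$p, cc$n))
}
for (tissue in c("lesional", "nonlesional")) {
  tt <- paired_timepoint_test(idx, ann, "baseline", "week2", tissue)
  cat(sprintf("paired baseline -> week2, %s: mean change %.2f (p = %.2g, %d pairs)\n",
              tissue, tt$mean_change, tt$p, tt$n_pairs))
}
tt12 <- paired_timepoint_test(idx, ann, "week2", "week12", "lesional")
cat(sprintf("paired week2 -> week12, lesional: mean change %.2f (p = %.2g)\n",
            tt12$mean_change, tt12$p))
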