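# Human differential expression: SAM permutation statistic on the log2
# intensities of each discovery cohort, q-value FDR, DEGs called at
# FDR < 10% and FC > 1.5.
source("analysis/00_config.R")

for (co in c("DE", "SE")) {
  x <- read_expression_matrix(file.path(STUDY_DIR, sprintf("human_%s.tsv", co)),
                              "log_intensity",
                              file.path(STUDY_DIR, sprintf("human_%s_annotation.tsv", co)))
  deg <- call_degs(sam_test(x, "control", "lesional", sam_config(seed = STUDY_SEED)),
                   0.10, 1.5)
  write_deg_table(deg, file.path(OUT_DIR, sprintf("deg_human_%s.tsv", co)))
  cat(sprintf("%s cohort: %d up, %d down\n", co,
              sum(deg$call == "up"), sum(deg$call == "down")))
}
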