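# Mouse differential expression: TPM-filtered counts, TMM-normalized
# negative-binomial exact tests for CHS vs VT and SSS vs NT, DEGs called at
# FDR < 5% and FC > 2.
source("analysis/00_config.R")

counts <- read_expression_matrix(file.path(STUDY_DIR, "mouse_counts.tsv"), "counts",
                                 file.path(STUDY_DIR, "mouse_annotation.tsv"))
tpm <- read_expression_matrix(file.path(STUDY_DIR, "mouse_tpm.tsv"), "tpm")
expressed <- filter_by_tpm(counts, tpm, 1)
cat(sprintf("%d of %d genes above 1 TPM\n", nrow(expressed$values), nrow(counts$values)))

for (ct in list(c("VT", "CHS"), c("NT", "SSS"))) {
  deg <- call_degs(nb_exact_test(expressed, ct[1], ct[2]), 0.05, 2)
  write_deg_table(deg, file.path(OUT_DIR, sprintf("deg_mouse_%s.tsv", ct[2])))
  cat(sprintf("%s vs %s: %d up, %d down\n", ct[2], ct[1],
              sum(deg$call == "up"), sum(deg$call == "down")))
}
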