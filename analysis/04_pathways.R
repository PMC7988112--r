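# FAIME pathway scores per sample, per-contrast pathway t-statistics, and
# the cross-species concordance correlations of the t-statistics.
source("analysis/00_config.R")

sets <- read_gene_sets(file.path(STUDY_DIR, "pathways.gmt"))
om <- read_ortholog_map(file.path(STUDY_DIR, "orthologs.tsv"))

counts <- read_expression_matrix(file.path(STUDY_DIR, "mouse_counts.tsv"), "counts",
                                 file.path(STUDY_DIR, "mouse_annotation.tsv"))
tpm <- read_expression_matrix(file.path(STUDY_DIR, "mouse_tpm.tsv"), "tpm")
expressed <- filter_by_tpm(counts, tpm, 1)
mscore <- suppressWarnings(faime_scores(expressed, map_gene_sets(sets, om, "mouse")))
contrasts <- list(
  CHS = pathway_contrast(mscore, expressed$samples, "VT", "CHS"),
  SSS = pathway_contrast(mscore, expressed$samples, "NT", "SSS"))

for (co in c("DE", "SE")) {
  x <- read_expression_matrix(file.path(STUDY_DIR, sprintf("human_%s.tsv", co)),
                              "log_intensity",
                              file.path(STUDY_DIR, sprintf("human_%s_annotation.tsv", co)))
  sc <- suppressWarnings(faime_scores(x, sets))
  contrasts[[co]] <- pathway_contrast(sc, x$samples, "control", "lesional")
}

long <- do.call(rbind, lapply(names(contrasts), function(nm)
  cbind(contrast = nm, contrasts[[nm]][, c("pathway", "t", "p_corrected")])))
write.table(long[order(long$pathway, long$contrast), ],
            file.path(OUT_DIR, "pathway_contrasts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (mn in c("CHS", "SSS")) for (hn in c("DE", "SE")) {
  cc <- contrast_correlation(contrasts[[mn]], contrasts[[hn]])
  cat(sprintf("pathway t-statistic concordance %s vs %s: r = %.3f (p = %.2g, n = %d)\n",
              mn, hn, cc$r, cc$p, cc$n_shared))
}
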