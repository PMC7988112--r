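# Generates the synthetic study: two mouse models with controls (NB counts),
# two human discovery cohorts (log2 intensities), a treatment validation
# cohort with SCORAD, plus the ortholog map and pathway GMT. Ground truth
# (planted DEGs and the implied true signature) is written alongside.
source("analysis/00_config.R")

cfg <- study_cfg()
pc <- write_simulated_study(cfg, STUDY_DIR, out_dir = file.path(OUT_DIR, "pipeline"))
truth <- attr(pc, "truth")
write_signature(truth$signature, file.path(STUDY_DIR, "true_signature.tsv"))

cat(sprintf("simulated %d genes; %d + %d planted shared mouse DEGs; true signature of %d genes\n",
            cfg$n_genes, length(truth$mouse_shared_up), length(truth$mouse_shared_down),
            nrow(truth$signature)))
cat("study files in", STUDY_DIR, "\n")
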