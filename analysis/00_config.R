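# Shared settings for the analysis scripts. Every script is run from the
# repository root, e.g.  Rscript analysis/01_simulate.R
suppressMessages(library(adsig))

STUDY_SEED <- 17
STUDY_DIR <- "results/study"       # simulated input files (01)
OUT_DIR <- "results"               # stage outputs (02-06)

study_cfg <- function() sim_config(seed = STUDY_SEED)

dir.create(OUT_DIR, recursive = TRUE, showWarnings = FALSE)
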