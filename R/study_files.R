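#' Write a complete simulated study to disk
#'
#' Generates all components of a synthetic study (mouse models, human
#' discovery cohorts, validation cohort, ortholog map, gene sets) and
#' writes them in the package's TSV/GMT formats, returning a
#' [pipeline_config()] pointing at the files — a one-call study fixture for
#' end-to-end runs.
#'
#' @param cfg A [sim_config()].
#' @param dir Directory to populate (created if needed).
#' @param out_dir Pipeline output directory (default `file.path(dir, "out")`).
#' @param ... Passed on to [pipeline_config()] (thresholds, stage configs).
#' @return A `pipeline_config`, with the study `truth` attached as the
#'   `"truth"` attribute.
#' @export
write_simulated_study <- function(cfg = sim_config(), dir,
                                  out_dir = file.path(dir, "out"), ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  ms <- simulate_mouse_study(cfg)
  write_expression_matrix(ms$counts, p("mouse_counts.tsv"), p("mouse_annotation.tsv"))
  write_expression_matrix(ms$tpm, p("mouse_tpm.tsv"))
  hs <- simulate_human_cohorts(cfg)
  human <- list()
  for (nm in names(hs$cohorts)) {
    ep <- p(sprintf("human_%s.tsv", nm)); ap <- p(sprintf("human_%s_annotation.tsv", nm))
    write_expression_matrix(hs$cohorts[[nm]], ep, ap)
    human[[nm]] <- list(expr = ep, annotation = ap)
  }
  val <- simulate_validation_cohort(cfg)
  write_expression_matrix(val, p("validation.tsv"), p("validation_annotation.tsv"))
  fx <- simulate_fixtures(cfg)
  write_ortholog_map(fx$ortholog_map, p("orthologs.tsv"))
  write_gene_sets(fx$gene_sets, p("pathways.gmt"))
  pc <- pipeline_config(
    mouse_counts = p("mouse_counts.tsv"), mouse_tpm = p("mouse_tpm.tsv"),
    mouse_annotation = p("mouse_annotation.tsv"),
    human = human,
    validation = list(expr = p("validation.tsv"),
                      annotation = p("validation_annotation.tsv")),
    gmt = p("pathways.gmt"), orthologs = p("orthologs.tsv"),
    out_dir = out_dir, seed = cfg$seed, ...)
  attr(pc, "truth") <- ms$truth
  pc
}
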