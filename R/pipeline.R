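#' Run the full axon-imaging pipeline on a synthetic cohort
#'
#' Generates a seeded cohort (schedule, ground truth, recording), runs
#' [analyze_axons()], and writes the per-axon profile CSV and the population
#' JSON report. The same `(config, ...)` always produces byte-identical
#' output files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param alpha Responsiveness BH level.
#' @param truth Optional [make_axon_truth()] result; generated from `config`
#'   when `NULL`.
#' @return Invisibly, a list with `profiles`, `truth` and the written `paths`.
#' @export
run_axon_pipeline <- function(config, out_dir, alpha = 0.01, truth = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(truth)) truth <- make_axon_truth(config)
  sched <- make_stimulus_schedule(config)
  rec <- simulate_axon_population(config, sched, truth)
  prof <- analyze_axons(rec, alpha = alpha)
  profile_path <- file.path(out_dir, "axon_profiles.csv")
  write_text_table(as.data.frame(prof), profile_path)
  pop <- attr(prof, "population")
  rp <- attr(prof, "response_probability")
  report <- list(
    n_axons = nrow(prof),
    n_trials = nrow(sched),
    fraction_responsive = mean(prof$sensory_class != "non_responsive"),
    fraction_unisensory = mean(prof$sensory_class == "unisensory"),
    fraction_multisensory = mean(prof$sensory_class == "multisensory"),
    fraction_blank_responsive = mean(prof$blank_responsive),
    auc_threshold = rp$threshold,
    kruskal_H = pop$kruskal$H,
    kruskal_p = pop$kruskal$p
  )
  report_path <- file.path(out_dir, "population_report.json")
  write_report_json(report, report_path)
  invisible(list(profiles = prof, truth = truth,
                 paths = c(profiles = profile_path, report = report_path)))
}
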