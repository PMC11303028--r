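# The scaled-down simulation study used by the replicate-level checks.
# Run once per session and memoised: both the fossil-benefit and the
# predictor-sign checks read the same study.
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- run_simulation_study(
      seed = 1, n_trees = 20, n_extant = 100,
      abc_n_candidates = 300, abc_keep = 20,
      scenarios = list(fossils25 = list(frac_known = 0.5,
                                        frac_included = 0.25,
                                        mode = "biased")),
      model = "DEC", restarts = 2, n_bins = 4, n_batches = 10
    )
  }
  .study_cache$study
}
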