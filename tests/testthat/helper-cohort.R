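# Shared end-to-end synthetic study, computed once per test run and reused
# by the acceptance blocks (full pipeline on the default 15 + 15 cohort,
# coarse time-frequency grid).

.cohort_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.cohort_cache$study)) {
    spec <- cohort_spec(seed = 101)
    .cohort_cache$study <- run_synthetic_study(
      spec, dir = file.path(tempdir(), "acceptance_cohort"),
      tf = tf_config_coarse(), n_reps = 50)
  }
  .cohort_cache$study
}
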