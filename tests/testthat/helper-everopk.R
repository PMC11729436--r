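## small shared fixtures, built fresh per test run

refined_pop <- function() pop_params()

## compact steady-state-record dataset: fast to fit, used across modules
small_dataset <- function(n = 12, n_troughs = 4, seed = 421, pop = pop_params(),
                          ...) {
  generate_dataset(cohort_config(n = n, n_troughs = n_troughs, ...), pop,
                   seed = seed)
}

fixture_path <- function() {
  system.file("extdata", "synthetic_5subj.csv", package = "everopk")
}
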