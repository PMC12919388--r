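# The reference-scale cohort used across the acceptance checks: generated
# once per test run at the study size N = 10,637 under a single fixed seed,
# then shared.

reference_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$cohort)) {
      cache$cohort <- generate_cohort(REFERENCE_COHORT_SIZE, seed = 1L)
    }
    cache$cohort
  }
})
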