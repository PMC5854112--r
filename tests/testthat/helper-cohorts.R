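# Shared developmental cohorts for the heavier end-to-end tests; built once
# per test run and cached.
.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohorts <- function() {
  if (is.null(.cohort_cache$pair)) {
    base <- leaf_params(noise_amp = 4, seed = 1)  # 0.4% boundary noise
    wt <- generate_cohort(base, 50, blade_range = c(210, 790),
                          genotype_tooth_scale = 1,
                          genotype = "wild_type", seed = 101)
    mut <- generate_cohort(base, 50, blade_range = c(210, 790),
                           genotype_tooth_scale = 0.5,
                           genotype = "mutant", seed = 202)
    .cohort_cache$pair <- list(
      wt = wt, mut = mut,
      m_wt = measure_cohort(wt),
      m_mut = measure_cohort(mut)
    )
  }
  .cohort_cache$pair
}
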