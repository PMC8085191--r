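# shared fixtures, built once per test run and memoized

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# canonical total-blood / parent-fraction truth used across files
ref_triexp <- function() triexp_params(0.5, c(60, 8, 1.5), c(4, 0.4, 0.015))
ref_pf <- function() parent_fraction_params(0.05, 1.5, 12)

ref_cp <- function() fixture("ref_cp", function() {
  g <- (0:5400) / 60
  new_input_function(true_aif(ref_triexp(), g) * parent_fraction(ref_pf(), g),
                     provenance = "true")
})

ref_wb <- function() fixture("ref_wb", function() {
  g <- (0:5400) / 60
  new_input_function(true_aif(ref_triexp(), g), provenance = "whole_blood")
})

# noise-free blood table on the study sampling schedule
ref_blood <- function() fixture("ref_blood", function() {
  parent <- function(t) true_aif(ref_triexp(), t) * parent_fraction(ref_pf(), t)
  measured_blood(parent, ref_pf(),
                 times_min = c(seq(0.25, 10, by = 0.25), 20, 30, 45, 60, 90),
                 durations_min = c(rep(0.25, 40), rep(0.5, 5)))
})

# small stochastic cohort for fast pipeline-level tests
small_config <- function(seed = 303, ...) {
  cohort_config(n_subjects = 6L, fraction_pd = 4 / 6, n_test_retest = 2L,
                seed = seed, ...)
}

small_cohort <- function() fixture("small_cohort",
                                   function() generate_cohort(small_config()))
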