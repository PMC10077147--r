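# Small synthetic worlds reused across test files.

small_cohort_config <- function(n_controls = 120L, n_patients = 24L,
                                seed = 1L) {
  cohort_gen_config(n_controls = n_controls, n_patients = n_patients,
                    seed = seed)
}

# three correlated continuous variables, the first bimodal with MCAR at 20%
bimodal_config <- function(seed, n = 2000L, missing_rate = 0.2) {
  mix <- list(weights = c(0.6, 0.4), means = c(2, 10), sds = c(1, 2))
  std <- list(weights = 1, means = 0, sds = 1)
  vars <- list(
    o2 = variable_spec("o2", "continuous", mix, mix,
                       missing_rate = missing_rate),
    a = variable_spec("a", "continuous", std, std),
    b = variable_spec("b", "continuous", std, std))
  R <- matrix(c(1, .8, .6, .8, 1, .4, .6, .4, 1), 3,
              dimnames = list(names(vars), names(vars)))
  cohort_gen_config(n_controls = n - 10L, n_patients = 10L,
                    variables = vars, correlation = R, seed = seed)
}

# a tiny mixed-type matrix with known missingness for contract tests
mixed_fixture <- function(seed = 4L, n0 = 120L, n1 = 30L) {
  generate_cohort(small_cohort_config(n0, n1, seed = seed))
}
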