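#' Specification of one synthetic clinical variable
#'
#' Describes how a variable is distributed in each class of the synthetic
#' cohort.  Continuous variables are Gaussian mixtures per class (a single
#' component reduces to a plain Gaussian); categorical variables carry
#' per-level probabilities per class.  `missing_rate` is the MCAR masking
#' fraction later applied by [apply_mcar()].
#'
#' @param name variable name.
#' @param vtype `"continuous"` or `"categorical"`.
#' @param class0_params,class1_params for continuous variables a list with
#'   `weights`, `means`, `sds` (equal-length numeric vectors, weights summing
#'   to 1); for categorical variables a named numeric vector of level
#'   probabilities (names = levels, summing to 1, same level set in both
#'   classes).
#' @param missing_rate MCAR missingness fraction in `[0, 1]`.
#' @param unit clinical unit label (optional).
#' @param imputation_only logical; `TRUE` marks variables included only to
#'   support imputation, which the post-imputation restriction step removes
#'   before classification.
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, vtype, class0_params, class1_params,
                          missing_rate = 0, unit = NA_character_,
                          imputation_only = FALSE) {
  stopifnot(vtype %in% c("continuous", "categorical"),
            missing_rate >= 0, missing_rate <= 1)
  chk_cont <- function(p) {
    stopifnot(is.list(p), all(c("weights", "means", "sds") %in% names(p)))
    stopifnot(length(p$weights) == length(p$means),
              length(p$means) == length(p$sds))
    assert_prob_vector(p$weights, paste0(name, " mixture weights"))
    if (any(p$sds <= 0)) stop(name, ": mixture SDs must be > 0")
    p
  }
  if (vtype == "continuous") {
    class0_params <- chk_cont(class0_params)
    class1_params <- chk_cont(class1_params)
  } else {
    stopifnot(!is.null(names(class0_params)),
              identical(names(class0_params), names(class1_params)))
    assert_prob_vector(class0_params, paste0(name, " class0 probabilities"))
    assert_prob_vector(class1_params, paste0(name, " class1 probabilities"))
  }
  structure(list(name = name, vtype = vtype,
                 class0_params = class0_params, class1_params = class1_params,
                 missing_rate = missing_rate, unit = unit,
                 imputation_only = imputation_only),
            class = "variable_spec")
}

gauss <- function(mean, sd) list(weights = 1, means = mean, sds = sd)
renorm <- function(p) p / sum(p)

#' Default synthetic-cohort variable catalogue
#'
#' The nine model variables of the shock classifier plus two
#' imputation-support variables, parameterised with the published per-class
#' summary statistics of an intensive-care acute-coronary-syndrome
#' population: per-class means/SDs for continuous variables, per-class level
#' frequencies for categorical ones, and per-variable missingness rates.
#' Class 0 is the control group (no cardiogenic shock), class 1 the patient
#' group (developed cardiogenic shock).  Oxygen flow is deliberately bimodal
#' (low-flow nasal cannula vs. high-flow mask regimes) to exercise
#' multimodal imputation; its mixture parameters are package choices, as is
#' body temperature (near-degenerate between classes, included to exercise
#' unit conversion and repair).
#'
#' @return named list of [variable_spec()] objects.
#' @export
default_variable_specs <- function() {
  specs <- list(
    variable_spec("heart_rate", "continuous",
                  gauss(82.1, 16.343), gauss(94.1, 18.912),
                  missing_rate = 0.0289, unit = "bpm"),
    variable_spec("respiratory_rate", "continuous",
                  gauss(17.1, 5.549), gauss(20.1, 5.917),
                  missing_rate = 0.027, unit = "bpm"),
    variable_spec("spo2", "continuous",
                  gauss(97.8, 3.037), gauss(96.3, 4.699),
                  missing_rate = 0.0344, unit = "%"),
    variable_spec("glucose", "continuous",
                  gauss(157.8, 80.429), gauss(227.5, 135.491),
                  missing_rate = 0.0187, unit = "mg/dl"),
    variable_spec("systolic_bp", "continuous",
                  gauss(125.6, 24.112), gauss(108.9, 20.538),
                  missing_rate = 0.3066, unit = "mmHg"),
    variable_spec("age", "continuous",
                  gauss(67.0, 12.401), gauss(71.0, 11.997),
                  missing_rate = 0.235, unit = "y"),
    variable_spec("o2_flow", "continuous",
                  list(weights = c(0.75, 0.25), means = c(2.5, 10),
                       sds = c(1.2, 3.0)),
                  list(weights = c(0.45, 0.55), means = c(3.0, 12),
                       sds = c(1.5, 3.5)),
                  missing_rate = 0.1238, unit = "lpm"),
    variable_spec("sex", "categorical",
                  c(male = 0.6446, female = 0.3554),
                  c(male = 0.6230, female = 0.3770),
                  missing_rate = 0.1774),
    variable_spec("ekg", "categorical",
                  renorm(c(anterior_stemi_lbbb = 0.1761, other_stemi = 0.2485,
                           nstemi = 0.4718, other = 0.1036)),
                  # printed class-1 frequencies sum to 100.01%; renormalised
                  renorm(c(anterior_stemi_lbbb = 0.3279, other_stemi = 0.3115,
                           nstemi = 0.2869, other = 0.0738)),
                  missing_rate = 0),
    variable_spec("chf_history", "categorical",
                  c(no = 0.6432, yes = 0.3568),
                  c(no = 0.3279, yes = 0.6721),
                  missing_rate = 0),
    variable_spec("heart_rhythm", "categorical",
                  c(sinus_tachycardia = 0.1027, sinus_bradycardia = 0.0530,
                    ventricular_tachycardia = 0.0014, av_block_1 = 0.0085,
                    other = 0.8344),
                  c(sinus_tachycardia = 0.2869, sinus_bradycardia = 0.0164,
                    ventricular_tachycardia = 0.0082, av_block_1 = 0.0164,
                    other = 0.6721),
                  missing_rate = 0.0224, imputation_only = TRUE),
    variable_spec("temperature", "continuous",
                  gauss(36.8, 0.6), gauss(36.9, 0.8),
                  missing_rate = 0.0646, unit = "C", imputation_only = TRUE)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_controls,n_patients group sizes (default 2130 controls / 123
#'   patients, the roughly 1:17 imbalance of the study cohort).
#' @param variables list of [variable_spec()]s
#'   (default [default_variable_specs()]).
#' @param correlation optional rank-correlation matrix across the continuous
#'   variables (Gaussian copula); default identity (independence).  Must be
#'   symmetric positive semi-definite with unit diagonal, dimnames matching
#'   the continuous variable names.
#' @param seed master seed.
#' @return object of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(n_controls = 2130L, n_patients = 123L,
                              variables = default_variable_specs(),
                              correlation = NULL, seed = 1L) {
  stopifnot(n_controls >= 1, n_patients >= 1, length(variables) >= 1)
  stopifnot(all(vapply(variables, inherits, TRUE, "variable_spec")))
  cont <- vapply(variables, function(v) v$vtype == "continuous", TRUE)
  if (!is.null(correlation)) {
    cn <- names(variables)[cont]
    if (!is.matrix(correlation) || nrow(correlation) != length(cn) ||
        !isTRUE(all.equal(correlation, t(correlation))) ||
        any(abs(diag(correlation) - 1) > 1e-8))
      stop("correlation must be a symmetric matrix with unit diagonal, ",
           "one row per continuous variable")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("correlation matrix is not positive semi-definite")
    if (is.null(dimnames(correlation)))
      dimnames(correlation) <- list(cn, cn)
  }
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 variables = variables, correlation = correlation,
                 seed = as.integer(seed)),
            class = "cohort_gen_config")
}
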