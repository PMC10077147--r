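test_that("per-class continuous means converge to the specified values", {
  hr <- default_variable_specs()[["heart_rate"]]
  cfg <- cohort_gen_config(n_controls = 20000L, n_patients = 20000L,
                           variables = list(heart_rate = hr), seed = 101L)
  g <- generate_feature_matrix(cfg)
  x <- g$fm$data$heart_rate
  m0 <- mean(x[g$labels == 0]); m1 <- mean(x[g$labels == 1])
  se0 <- 16.343 / sqrt(20000); se1 <- 18.912 / sqrt(20000)
  expect_lt(abs(m0 - 82.1), 3 * se0)
  expect_lt(abs(m1 - 94.1), 3 * se1)
  expect_true(all(g$labels %in% 0:1))
  expect_false(any(missing_mask(g$fm)))
})

test_that("group-size boundaries are enforced", {
  expect_error(cohort_gen_config(n_controls = 100L, n_patients = 0L))
  cfg <- cohort_gen_config(n_controls = 5L, n_patients = 1L, seed = 2L)
  g <- generate_feature_matrix(cfg)
  expect_identical(sum(g$labels == 1L), 1L)
  expect_identical(nrow(g$fm$data), 6L)
})

test_that("categorical frequencies match the specification (chi-squared GOF)", {
  ekg <- default_variable_specs()[["ekg"]]
  cfg <- cohort_gen_config(n_controls = 50000L, n_patients = 1L,
                           variables = list(ekg = ekg), seed = 33L)
  g <- generate_feature_matrix(cfg)
  obs <- table(g$fm$data$ekg[g$labels == 0])
  p <- ekg$class0_params
  stat <- sum((obs - 50000 * p)^2 / (50000 * p))
  expect_lt(stat, stats::qchisq(0.99, df = length(p) - 1))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_cohort_config(seed = 77L)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(a$fm$data, b$fm$data)
  expect_identical(a$truth, b$truth)
  ea <- generate_event_table(cfg); eb <- generate_event_table(cfg)
  expect_identical(ea$events, eb$events)
  expect_identical(ea$coded, eb$coded)
})

test_that("the Gaussian copula induces the requested rank correlation", {
  std <- list(weights = 1, means = 0, sds = 1)
  vars <- list(x = variable_spec("x", "continuous", std, std),
               y = variable_spec("y", "continuous", std, std))
  R <- matrix(c(1, .7, .7, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  cfg <- cohort_gen_config(5000L, 10L, variables = vars, correlation = R,
                           seed = 5L)
  g <- generate_feature_matrix(cfg)
  rho <- cor(g$fm$data$x, g$fm$data$y, method = "spearman")
  # Gaussian copula identity: rho_S = (6/pi) asin(rho/2)
  expect_lt(abs(rho - 6 / pi * asin(0.7 / 2)), 0.05)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(cohort_gen_config(10L, 10L, variables = vars,
                                 correlation = bad), "semi-definite")
})

test_that("apply_mcar boundary rates behave exactly", {
  g <- mixed_fixture()
  fm0 <- apply_mcar(g$fm_complete,
                    stats::setNames(0, "heart_rate"), seed = 1L)
  expect_identical(fm0$data, g$fm_complete$data)
  fm1 <- apply_mcar(g$fm_complete, c(heart_rate = 1), seed = 1L)
  expect_true(all(is.na(fm1$data$heart_rate)))
  expect_error(apply_mcar(g$fm_complete, c(heart_rate = 1.2)), "0, 1")
  expect_error(apply_mcar(g$fm_complete, c(nonsense = 0.2)), "named")
})

test_that("MCAR at 7.86% over 84 variables x 2253 rows hits the overall rate", {
  std <- list(weights = 1, means = 0, sds = 1)
  vars <- lapply(sprintf("v%02d", 1:84), function(nm)
    variable_spec(nm, "continuous", std, std, missing_rate = 0.0786))
  names(vars) <- sprintf("v%02d", 1:84)
  cfg <- cohort_gen_config(2130L, 123L, variables = vars, seed = 8L)
  g <- generate_cohort(cfg)
  frac <- mean(missing_mask(g$fm))
  se <- sqrt(0.0786 * (1 - 0.0786) / (84 * 2253))
  expect_lt(abs(frac - 0.0786), 3 * se)
})

test_that("the MCAR mask is independent of the class label", {
  cfg <- small_cohort_config(n_controls = 800L, n_patients = 200L, seed = 21L)
  g <- generate_cohort(cfg)
  mask <- missing_mask(g$fm)[, "systolic_bp"]  # 30.66% rate
  r <- cor(as.numeric(mask), g$labels)
  expect_lt(abs(r), 3 / sqrt(length(g$labels)))
  # observed cells are untouched by masking
  obs <- !mask
  expect_identical(g$fm$data$systolic_bp[obs], g$fm_complete$data$systolic_bp[obs])
})

test_that("event emission covers codes, diagnoses and the round-trip", {
  cfg <- small_cohort_config(n_controls = 50L, n_patients = 10L, seed = 3L)
  sim <- generate_event_table(cfg)
  # each variable has >= 1 event per stay; some subjects have both codes
  ev_hr <- sim$events[startsWith(sim$events$item_code, "heart_rate"), ]
  per_stay <- table(ev_hr$stay_id)
  expect_true(all(per_stay >= 1))
  expect_true(any(per_stay == 2))
  two <- names(per_stay)[per_stay == 2][1]
  pair <- ev_hr[ev_hr$stay_id == two, ]
  expect_identical(length(unique(pair$item_code)), 2L)
  expect_false(any(duplicated(pair$charttime)))
  # every patient-class subject carries the cardiogenic-shock code
  dx <- sim$coded[sim$coded$type == "diagnosis", ]
  pat <- sim$fm$subject_id[sim$labels == 1]
  expect_true(all(pat %in% dx$subject_id[dx$icd9_code == "78551"]))
  expect_false(any(dx$icd9_code[!dx$subject_id %in% pat] %in%
                     c("78551", "78550")))
  expect_error(generate_event_table(cfg, code_map = list()), "code_map")
})

test_that("clean(generate_event_table(cfg)) reconstructs the matrix cell-for-cell", {
  cfg <- small_cohort_config(n_controls = 40L, n_patients = 8L, seed = 3L)
  sim <- generate_event_table(cfg)
  cl <- clean_events(sim$events, default_clusters(cfg$variables))
  expect_identical(cl$fm$subject_id, sim$fm$subject_id)
  for (nm in names(sim$fm$data)) {
    a <- cl$fm$data[[nm]]; b <- sim$fm$data[[nm]]
    if (is.factor(b)) expect_identical(as.character(a), as.character(b))
    else expect_equal(a, b, tolerance = 1e-9)
  }
})
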