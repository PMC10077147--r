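dx_tab <- function(...) {
  codes <- c(...)
  data.frame(subject_id = rep("s1", length(codes)), icd9_code = codes,
             stringsAsFactors = FALSE)
}

test_that("strict cohort selection follows the coded rules", {
  spec <- cohort_spec(mode = "strict")
  grp <- function(dx, pr)
    as.character(select_cohort(dx_tab(dx), dx_tab(pr), spec)$group)
  expect_identical(select_cohort(dx_tab("78551", "41001"), dx_tab("0066"),
                                 spec)$group |> as.character(), "patient")
  expect_identical(select_cohort(dx_tab("4139"), dx_tab("8855"),
                                 spec)$group |> as.character(), "control")
  # shared dx without any procedure: excluded under strict
  no_proc <- data.frame(subject_id = character(0), icd9_code = character(0))
  expect_identical(select_cohort(dx_tab("4139"), no_proc,
                                 spec)$group |> as.character(), "excluded")
  # shock code but no procedure: excluded under strict
  expect_identical(select_cohort(dx_tab("78551", "41001"), no_proc,
                                 spec)$group |> as.character(), "excluded")
})

test_that("relaxed mode includes on any qualifying diagnosis, ignoring procedures", {
  spec <- cohort_spec(mode = "relaxed")
  no_proc <- data.frame(subject_id = character(0), icd9_code = character(0))
  r <- select_cohort(dx_tab("4139"), no_proc, spec)
  expect_identical(as.character(r$group), "control")
  r2 <- select_cohort(dx_tab("78550"), no_proc, spec)
  expect_identical(as.character(r2$group), "patient")
  r3 <- select_cohort(dx_tab("99999"), no_proc, spec)
  expect_identical(as.character(r3$group), "excluded")
})

test_that("selection partitions subjects into exactly one group", {
  cfg <- small_cohort_config(n_controls = 60L, n_patients = 15L, seed = 9L)
  sim <- generate_event_table(cfg, frac_relaxed_only = 0.2)
  r <- select_cohort(sim$coded, sim$coded, cohort_spec())
  expect_identical(nrow(r), length(unique(sim$coded$subject_id)))
  expect_false(any(duplicated(r$subject_id)))
  expect_true(all(r$group %in% c("patient", "control", "excluded")))
  # relaxed-only subjects (no procedures) are excluded strictly, included relaxed
  relax <- select_cohort(sim$coded, sim$coded, cohort_spec(mode = "relaxed"))
  expect_gt(sum(relax$group != "excluded"), sum(r$group != "excluded"))
})

test_that("ICD-9 normalization and range expansion", {
  expect_identical(normalize_icd9("410.01"), "41001")
  expect_error(normalize_icd9("V45.81", context = "row 3"), "row 3")
  rng <- expand_icd9_range(41000, 41092)
  expect_identical(length(rng), 93L)
  expect_identical(rng[1], "41000")
  expect_identical(rng[93], "41092")
  expect_error(cohort_spec(patient_only_dx = "4139"), "disjoint")
})

test_that("first-recorded aggregation picks earliest event after conversion", {
  cl <- variable_cluster("sbp", c("codeA", "codeB"), unit = "mmHg")
  ev <- data.frame(subject_id = "s1", stay_id = "s1",
                   item_code = c("codeA", "codeB"),
                   charttime = as.POSIXct(c("2008-01-01 01:00:00",
                                            "2008-01-01 02:00:00"), tz = "UTC"),
                   value = c("120", "118"), unit = "mmHg")
  fm <- aggregate_first_recorded(ev, list(cl))
  expect_equal(fm$data$sbp, 120)
  # single event -> its value; permutation invariance
  fm2 <- aggregate_first_recorded(ev[2:1, ], list(cl))
  expect_equal(fm2$data$sbp, 120)
  fm3 <- aggregate_first_recorded(ev[2, ], list(cl))
  expect_equal(fm3$data$sbp, 118)
  # tie on timestamp: lexicographic item_code order wins
  ev$charttime <- ev$charttime[c(1, 1)]
  fm4 <- aggregate_first_recorded(ev, list(cl))
  expect_equal(fm4$data$sbp, 120)  # codeA < codeB
  # a code in two clusters is a configuration error
  cl2 <- variable_cluster("other", "codeA")
  expect_error(aggregate_first_recorded(ev, list(cl, cl2)),
               "more than one cluster")
})

test_that("unit conversion is exact and unknown pairs are informative errors", {
  expect_equal(convert_unit(98.6, "F", "C"), 37)
  expect_equal(convert_unit(32, "F", "C"), 0)
  expect_identical(convert_unit(5.5, "lpm", "lpm"), 5.5)
  expect_error(convert_unit(1, "furlong", "m"), "known")
})

test_that("decimal-shift repair and implausible-value deletion", {
  temp <- variable_cluster("temperature", "t", unit = "C",
                           plausible_range = c(30, 43),
                           hard_range = c(25, 45))
  r <- repair_or_drop(c(375, 5, 37, NA), temp)
  expect_equal(r$value, c(37.5, NA, 37, NA))
  expect_identical(r$action, c("repaired", "deleted", "kept", NA))
})

test_that("cleaning is idempotent", {
  cfg <- small_cohort_config(n_controls = 40L, n_patients = 8L, seed = 13L)
  sim <- generate_event_table(cfg)
  clusters <- default_clusters(cfg$variables)
  once <- clean_events(sim$events, clusters)$fm
  # re-apply the repair stage to the already-clean matrix
  again <- once
  for (cl in clusters) {
    if (cl$type != "continuous") next
    again$data[[cl$target]] <- repair_or_drop(again$data[[cl$target]], cl)$value
  }
  expect_identical(again$data, once$data)
})

test_that("missingness profiling counts correctly", {
  d <- data.frame(a = c(1, NA, 3), b = c(NA, NA, 6), c = c(1, 2, 3),
                  d = c(NA, NA, 3))
  fm <- feature_matrix(d)
  p <- missingness_profile(fm)
  expect_equal(unname(p$per_variable), c(1 / 3, 2 / 3, 0, 2 / 3))
  expect_equal(p$overall, 5 / 12)
  full <- feature_matrix(data.frame(x = 1:10))
  expect_equal(missingness_profile(full)$overall, 0)
  expect_error(missingness_profile(feature_matrix(data.frame(x = numeric(0)))),
               "empty")
})

test_that("feature matrix CSV round-trips through the sidecar format", {
  g <- mixed_fixture(seed = 6L, n0 = 30L, n1 = 8L)
  path <- file.path(tempdir(), "fm.csv")
  write_feature_matrix(g$fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$data$heart_rate, g$fm$data$heart_rate)
  expect_identical(as.character(back$data$ekg), as.character(g$fm$data$ekg))
  expect_identical(levels(back$data$ekg), levels(g$fm$data$ekg))
  expect_identical(back$meta$type, g$fm$meta$type)
})
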