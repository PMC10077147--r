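test_that("KS statistic matches the brute-force ECDF oracle", {
  # exhaustive over all sample pairs of length <= 3 on the alphabet {1,2,3}
  alphabet <- 1:3
  combos <- function(len) {
    if (len == 1) return(as.list(alphabet))
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
  }
  samples <- unlist(lapply(1:3, combos), recursive = FALSE)
  for (a in samples) for (b in samples)
    expect_equal(ks_two_sample(a, b)$D, ks_brute(a, b))
  # random longer samples with ties
  set.seed(10)
  for (i in 1:50) {
    a <- sample(1:5, 8, replace = TRUE); b <- sample(1:5, 6, replace = TRUE)
    expect_equal(ks_two_sample(a, b)$D, ks_brute(a, b))
  }
})

test_that("KS handles the hand-computable fixtures", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$D, 1 / 3)
  expect_error(ks_two_sample(numeric(0), 1), "empty")
})

test_that("asymptotic KS p-values agree with the base-R reference at moderate n", {
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(120); b <- rnorm(150, mean = runif(1, 0, 0.5))
    ours <- ks_two_sample(a, b)$p
    ref <- suppressWarnings(stats::ks.test(a, b)$p.value)
    expect_equal(ours, ref, tolerance = 0.03)
  }
  # permutation mode is consistent with the asymptotic value
  set.seed(12)
  a <- rnorm(40); b <- rnorm(40, 0.8)
  pp <- ks_two_sample(a, b, permutation = TRUE, n_perm = 500L)$p
  pa <- ks_two_sample(a, b)$p
  expect_lt(abs(pp - pa), 0.05)
})

test_that("Benjamini-Yekutieli adjustment matches hand computation and oracles", {
  # hand fixture: c(3) = 11/6, adj = 0.01 * 3 * 11/6 = 0.055 for all three
  adj <- by_adjust(c(0.01, 0.02, 0.03), q = 0.05)
  expect_equal(adj$p_adj, c(0.055, 0.055, 0.055))
  expect_identical(adj$reject, rep(FALSE, 3))
  # single p: c(1) = 1 so adjusted = p
  expect_equal(by_adjust(0.01)$p_adj, 0.01)
  # all-zero p-values are rejected at any level
  expect_true(all(by_adjust(rep(0, 5), q = 1e-6)$reject))
  expect_error(by_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # literal step-up definition + the stats::p.adjust reference
  set.seed(13)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    ours <- by_adjust(p)$p_adj
    expect_equal(ours, by_brute(p))
    expect_equal(ours, stats::p.adjust(p, method = "BY"))
    # conservativeness vs Benjamini-Hochberg, and rank preservation
    expect_true(all(ours >= stats::p.adjust(p, method = "BH") - 1e-12))
    expect_identical(order(ours, p), order(p, p))
  }
})

make_eval_world <- function(seed, shift = 0, n = 200L, miss = 60L) {
  # one continuous variable with `miss` missing cells; "imputed" values are
  # drawn from the observed distribution shifted by `shift`
  set.seed(seed)
  x <- rnorm(n)
  fm <- feature_matrix(data.frame(v = c(x[seq_len(n - miss)],
                                        rep(NA_real_, miss))))
  comp <- fm
  comp$data$v[is.na(comp$data$v)] <- rnorm(miss, mean = shift)
  iset <- structure(list(completed = list(comp), method = "mice",
                         config = list(), log = character(0)),
                    class = "imputation_set")
  list(fm = fm, iset = iset)
}

test_that("evaluate_imputation_set builds a complete annotated grid", {
  w_null <- make_eval_world(1, shift = 0)
  w_bad <- make_eval_world(2, shift = 3)
  rep1 <- evaluate_imputation_set(w_bad$fm, list(w_bad$iset))
  expect_identical(nrow(rep1$results), 1L)
  expect_true(rep1$results$significant)
  expect_identical(rep1$results$stars, "***")
  # mean-filling a bimodal variable is rejected
  g <- generate_cohort(bimodal_config(3, n = 500L))
  mfill <- g$fm
  mfill$data$o2[is.na(mfill$data$o2)] <- mean(mfill$data$o2, na.rm = TRUE)
  iset <- structure(list(completed = list(mfill), method = "knn",
                         config = list(), log = character(0)),
                    class = "imputation_set")
  repm <- evaluate_imputation_set(g$fm, list(iset))
  expect_true(repm$results$significant[repm$results$variable == "o2"])
  # a variable with zero initially-missing cells is skipped with a log entry
  expect_true(any(grepl("skip", repm$log)))
})

test_that("evaluation compares only initially-missing positions", {
  w <- make_eval_world(4, shift = 0)
  shifted <- w$iset
  # adversarially corrupt the imputed dataset at *observed* positions only
  obs <- !is.na(w$fm$data$v)
  shifted$completed[[1]]$data$v[obs] <- shifted$completed[[1]]$data$v[obs] + 50
  r1 <- evaluate_imputation_set(w$fm, list(w$iset))
  r2 <- evaluate_imputation_set(w$fm, list(shifted))
  expect_identical(r1$results$D, r2$results$D)
  expect_identical(r1$results$p_raw, r2$results$p_raw)
})

test_that("under a true null the grid rarely rejects", {
  rejections <- vapply(1:20, function(s) {
    w <- make_eval_world(100 + s, shift = 0, n = 560L, miss = 60L)
    any(evaluate_imputation_set(w$fm, list(w$iset))$results$significant)
  }, TRUE)
  expect_gte(mean(!rejections), 0.95)
})

test_that("significance stars follow the adjusted-p thresholds", {
  expect_identical(shockpipe:::significance_stars(c(0.5, 0.04, 0.009, 5e-4)),
                   c("", "*", "**", "***"))
})

test_that("count_significant tallies margins consistently", {
  res <- data.frame(
    variable = rep(c("v1", "v2", "v3"), times = 2),
    dataset = rep(c("d1", "d2"), each = 3),
    D = 0.1, p_raw = 0.5,
    p_adj = c(0.01, 0.02, 0.9, 0.9, 0.9, 0.9),
    stars = "", significant = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  rep <- structure(list(results = res, alpha = 0.05), class = "eval_report")
  cd <- count_significant(rep, "dataset")
  expect_identical(unname(cd), c(2L, 0L))
  cv <- count_significant(rep, "variable")
  expect_identical(sum(cd), sum(cv))  # double-counting identity
  # all-null grid gives zeros
  res$significant <- FALSE
  rep0 <- structure(list(results = res, alpha = 0.05), class = "eval_report")
  expect_true(all(count_significant(rep0, "dataset") == 0L))
})

test_that("select_best_method prefers the lowest mean D with fixed tie order", {
  mk <- function(var, ds, D) data.frame(variable = var, dataset = ds, D = D,
                                        p_raw = 0.5, p_adj = 0.5, stars = "",
                                        significant = FALSE)
  res <- rbind(mk("v", c("mice_1", "mice_2"), c(0.04, 0.06)),
               mk("v", "knn", 0.10), mk("v", "soft_impute", 0.2),
               mk("w", c("mice_1", "mice_2"), c(0.3, 0.3)),
               mk("w", "knn", 0.05),
               mk("t", c("mice_1", "mice_2"), c(0.1, 0.1)),
               mk("t", "knn", 0.1))
  rep <- structure(list(results = res, alpha = 0.05), class = "eval_report")
  best <- select_best_method(rep)
  expect_identical(best$method[best$variable == "v"], "mice")  # mean .05 < .1
  expect_identical(best$method[best$variable == "w"], "knn")   # strictly best
  expect_identical(best$method[best$variable == "t"], "mice")  # exact tie
})
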