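test_that("encode_mixed round-trips and standardises", {
  g <- mixed_fixture(seed = 11L, n0 = 60L, n1 = 15L)
  enc <- encode_mixed(g$fm)
  # z-scored observed continuous columns have mean 0, SD 1
  z <- enc$X[, enc$col_map[["heart_rate"]]]
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z, na.rm = TRUE), 1, tolerance = 1e-9)
  # a 4-level categorical becomes 4 numeric columns
  expect_identical(length(enc$col_map[["ekg"]]), 4L)
  # decode on an arbitrary completion restores observed cells exactly
  Xc <- enc$X; Xc[is.na(Xc)] <- 0.3
  back <- enc$decode(Xc)
  mm <- missing_mask(g$fm)
  for (nm in names(g$fm$data)) {
    obs <- !mm[, nm]
    expect_identical(back$data[[nm]][obs], g$fm$data[[nm]][obs])
  }
  # single-level categorical is dropped with a warning
  d <- data.frame(x = c(1, 2, NA), g = factor(c("a", "a", "a")))
  expect_warning(encode_mixed(feature_matrix(d)), "single-level")
})

test_that("pmm_draw selects among the k nearest-predicted donors", {
  # k = 1: nearest donor, deterministic
  expect_identical(pmm_draw(2.1, c(5, 2, 9), c(50, 20, 90), k = 1), 20)
  # donors predicted 1..6, target 0, k = 5: the 6th is never drawn
  set.seed(1)
  draws <- replicate(200, pmm_draw(0, 1:6, c(10, 20, 30, 40, 50, 60), k = 5))
  expect_true(all(draws %in% c(10, 20, 30, 40, 50)))
  expect_true(all(c(10, 20, 30, 40, 50) %in% draws))
  # tie at the k-th slot: donor index order decides the candidate set
  set.seed(2)
  d2 <- replicate(200, pmm_draw(0, c(1, 2, 2, 2), c(10, 20, 30, 40), k = 2))
  expect_true(all(d2 %in% c(10, 20)))  # index order keeps donor 2, not 3/4
  expect_error(pmm_draw(0, numeric(0), numeric(0)), "empty donor")
})

test_that("MICE contracts: m datasets, observed untouched, donor support", {
  g <- mixed_fixture(seed = 12L)
  cfg <- imputation_config("mice", m = 3L, seed = 5L)
  iset <- mice_impute(g$fm, cfg)
  expect_identical(length(iset$completed), 3L)
  mm <- missing_mask(g$fm)
  for (comp in iset$completed) {
    expect_false(any(missing_mask(comp)))
    for (nm in names(g$fm$data)) {
      obs <- !mm[, nm]
      expect_identical(comp$data[[nm]][obs], g$fm$data[[nm]][obs])
      if (g$fm$meta$type[match(nm, g$fm$meta$name)] == "continuous") {
        # PMM support property: imputations are observed values
        expect_true(all(comp$data[[nm]][!obs] %in% g$fm$data[[nm]][obs]))
      }
    }
  }
  # reproducible under the same seed, different under another
  iset2 <- mice_impute(g$fm, cfg)
  expect_identical(iset$completed[[1]]$data, iset2$completed[[1]]$data)
  iset3 <- mice_impute(g$fm, imputation_config("mice", m = 1L, seed = 6L))
  expect_false(identical(iset$completed[[1]]$data, iset3$completed[[1]]$data))
})

test_that("MICE handles the degenerate cases the contract names", {
  # complete input: m identical copies, zero sweeps
  d <- data.frame(a = rnorm(30), b = rnorm(30))
  fm <- feature_matrix(d)
  iset <- mice_impute(fm, imputation_config("mice", m = 2L))
  expect_identical(iset$completed[[1]]$data, d)
  expect_match(iset$log, "zero sweeps")
  # an all-missing column is an error naming the column
  d2 <- data.frame(a = rnorm(5), bad = rep(NA_real_, 5))
  expect_error(mice_impute(feature_matrix(d2),
                           imputation_config("mice", m = 1L)), "bad")
})

test_that("KNN imputation averages / votes over the nearest donors", {
  # one complete neighbour identical on observed coordinates: value copied
  d <- data.frame(x = c(1, 1, 8), y = c(5, NA, 9))
  fm <- feature_matrix(d)
  out <- knn_impute(fm, imputation_config("knn", knn_k = 1L))
  expect_equal(out$completed[[1]]$data$y[2], 5)
  # two equidistant neighbours with values 10 and 20, k = 2 -> 15
  d2 <- data.frame(x = c(-1, 1, 0), y = c(10, 20, NA))
  out2 <- knn_impute(feature_matrix(d2), imputation_config("knn", knn_k = 2L))
  expect_equal(out2$completed[[1]]$data$y[3], 15)
  # k >= n - 1: grand mean of the observed donors
  set.seed(7)
  d3 <- data.frame(x = rnorm(12), y = c(rnorm(11), NA))
  out3 <- knn_impute(feature_matrix(d3), imputation_config("knn", knn_k = 50L))
  expect_equal(out3$completed[[1]]$data$y[12], mean(d3$y[1:11]))
  # categorical mode with ties resolved by level order
  d4 <- data.frame(x = c(0, 0.1, -0.1, 5), g = factor(c("b", "a", NA, "a"),
                                                      levels = c("a", "b")))
  out4 <- knn_impute(feature_matrix(d4), imputation_config("knn", knn_k = 2L))
  expect_identical(as.character(out4$completed[[1]]$data$g[3]), "a")
})

test_that("SoftImpute converges to the nuclear-norm completion (convex oracle)", {
  # brute-force oracle: the lambda->0 limit minimises the nuclear norm among
  # exact completions; for [[1,2],[2,x]] that is x = 1 (not the rank-1 x = 4)
  nuc <- function(x) sum(svd(matrix(c(1, 2, 2, x), 2))$d)
  oracle <- stats::optimize(nuc, c(-10, 10))$minimum
  fm <- feature_matrix(data.frame(a = c(1, 2), b = c(2, NA)))
  s <- soft_impute(fm, imputation_config("soft_impute", lambda = 1e-6,
                                         max_iter = 500L, tol = 1e-12,
                                         standardize = FALSE))
  expect_equal(s$completed[[1]]$data$b[2], oracle, tolerance = 1e-4)
  # fully observed input is returned unchanged
  full <- feature_matrix(data.frame(a = 1:3, b = 4:6))
  expect_identical(soft_impute(full)$completed[[1]]$data, full$data)
  # lambda >= top singular value: all-zero low-rank estimate at first iterate
  fz <- feature_matrix(data.frame(a = c(3, 0), b = c(0, NA)))
  sz <- soft_impute(fz, imputation_config("soft_impute", lambda = 10,
                                          max_iter = 20L, standardize = FALSE))
  expect_equal(sz$completed[[1]]$data$b[2], 0)
})

test_that("SoftImpute objective is non-increasing at the target lambda", {
  set.seed(9)
  M <- matrix(rnorm(40 * 6), 40) %*% diag(c(3, 2, 1, .5, .2, .1))
  Mm <- M; Mm[sample(length(M), 40)] <- NA
  obs <- !is.na(Mm)
  # tol is deliberately unattainable here: the contract is a warning plus
  # the best iterate, and the objective path must still be monotone
  expect_warning(
    res <- shockpipe:::soft_impute_core(Mm, obs, lambda = 0.5,
                                        max_iter = 200L, tol = 1e-9),
    "no convergence")
  expect_true(all(diff(res$objective) <= 1e-8))
})

test_that("IterativeSVD recovers exact low-rank structure", {
  set.seed(42)
  U <- matrix(rnorm(200 * 2), 200); V <- matrix(rnorm(20 * 2), 20)
  M <- U %*% t(V)
  mask <- matrix(runif(200 * 20) < 0.1, 200)
  Mm <- M; Mm[mask] <- NA
  r <- iterative_svd_impute(feature_matrix(as.data.frame(Mm)),
                            imputation_config("iterative_svd", rank = 2L,
                                              max_iter = 1000L, tol = 1e-10,
                                              standardize = FALSE))
  Xc <- as.matrix(r$completed[[1]]$data)
  expect_lt(max(abs(Xc[mask] - M[mask])), 1e-4)
  # rank-1 matrix with one missing entry: exact rank-1 closure (-> 4)
  fm <- feature_matrix(data.frame(a = c(1, 2), b = c(2, NA)))
  r1 <- iterative_svd_impute(fm, imputation_config("iterative_svd", rank = 1L,
                                                   max_iter = 500L,
                                                   tol = 1e-12,
                                                   standardize = FALSE))
  expect_equal(r1$completed[[1]]$data$b[2], 4, tolerance = 1e-6)
  # no missing cells: input returned as-is
  full <- feature_matrix(data.frame(a = rnorm(5), b = rnorm(5)))
  expect_identical(iterative_svd_impute(full,
                                        imputation_config("iterative_svd",
                                                          rank = 1L))$completed[[1]]$data,
                   full$data)
  # rank >= min(dim) is a configuration error
  fm2 <- feature_matrix(as.data.frame(Mm))
  expect_error(iterative_svd_impute(fm2,
                                    imputation_config("iterative_svd",
                                                      rank = 25L)), "rank")
})

test_that("all four engines satisfy the completion contract on mixed data", {
  g <- mixed_fixture(seed = 13L)
  mm <- missing_mask(g$fm)
  engines <- list(imputation_config("mice", m = 2L, seed = 2L),
                  imputation_config("knn"),
                  imputation_config("soft_impute", seed = 2L),
                  imputation_config("iterative_svd", rank = 6L))
  for (cfg in engines) {
    iset <- impute(g$fm, cfg)
    for (comp in iset$completed) {
      expect_false(any(missing_mask(comp)))
      for (nm in names(g$fm$data)) {
        obs <- !mm[, nm]
        expect_identical(comp$data[[nm]][obs], g$fm$data[[nm]][obs])
      }
    }
  }
})
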