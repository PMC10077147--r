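#' Classifier configuration
#'
#' Defaults follow the published model: traditional gradient-boosted
#' decision trees with 100 estimators, 31 leaves each, balanced class
#' weight, no hyperparameter optimisation.
#'
#' @param n_estimators boosting rounds (>= 1).
#' @param num_leaves leaves per tree (>= 2).
#' @param class_weight `"balanced"` or `"none"`.
#' @param seed seed (the learner itself is deterministic; kept for
#'   interface symmetry).
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(n_estimators = 100L, num_leaves = 31L,
                              class_weight = c("balanced", "none"),
                              seed = 1L) {
  class_weight <- match.arg(class_weight)
  stopifnot(n_estimators >= 1, num_leaves >= 2)
  structure(list(n_estimators = as.integer(n_estimators),
                 num_leaves = as.integer(num_leaves),
                 class_weight = class_weight, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Cross-validation configuration
#' @param n_splits stratified folds (default 5).
#' @param n_repeats independent shuffles (default 50).
#' @param seed master CV seed.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(n_splits = 5L, n_repeats = 50L, seed = 1L) {
  stopifnot(n_splits >= 2, n_repeats >= 1)
  structure(list(n_splits = as.integer(n_splits),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_config")
}

#' Bivariate screening of variables against the class label
#'
#' Categorical variables: chi-squared test on the contingency table
#' (textbook `sum (O - E)^2 / E`, no continuity correction).  Continuous
#' variables: Welch unpaired t-test when both groups pass a Shapiro–Wilk
#' normality check (alpha 0.05, deterministic quantile subsample capped at
#' 500), Mann–Whitney U otherwise.  Variables with a single observed
#' level/value are skipped with a log entry.
#'
#' @param fm a complete (imputed) [feature_matrix()].
#' @param labels binary class labels.
#' @param shapiro_alpha,shapiro_cap normality-check knobs.
#' @return data.frame `variable`, `test`, `statistic`, `p` (attribute
#'   `log` lists skipped variables).
#' @export
bivariate_screen <- function(fm, labels, shapiro_alpha = 0.05,
                             shapiro_cap = 500L) {
  stopifnot(inherits(fm, "feature_matrix"),
            length(labels) == nrow(fm$data))
  log <- character(0)
  rows <- list(); k <- 0L
  for (j in seq_len(ncol(fm$data))) {
    nm <- fm$meta$name[j]; x <- fm$data[[j]]
    if (fm$meta$type[j] == "categorical") {
      tab <- table(x, labels)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) < 2) { log <- c(log, paste("skip", nm)); next }
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      stat <- sum((tab - E)^2 / E)
      p <- stats::pchisq(stat, df = (nrow(tab) - 1) * (ncol(tab) - 1),
                         lower.tail = FALSE)
      test <- "chi-squared"
    } else {
      g0 <- x[labels == 0]; g1 <- x[labels == 1]
      if (stats::sd(x) == 0) { log <- c(log, paste("skip", nm)); next }
      normal <- shapiro_ok(g0, shapiro_alpha, shapiro_cap) &&
        shapiro_ok(g1, shapiro_alpha, shapiro_cap)
      if (normal) {
        ht <- stats::t.test(g0, g1)
        stat <- unname(ht$statistic); p <- ht$p.value; test <- "t"
      } else {
        ht <- suppressWarnings(stats::wilcox.test(g0, g1))
        stat <- unname(ht$statistic); p <- ht$p.value; test <- "Mann-Whitney"
      }
    }
    k <- k + 1L
    rows[[k]] <- data.frame(variable = nm, test = test, statistic = stat,
                            p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "log") <- log
  out
}

shapiro_ok <- function(x, alpha, cap) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
  if (length(x) > cap)  # deterministic quantile subsample
    x <- stats::quantile(x, probs = seq(0, 1, length.out = cap),
                         names = FALSE, type = 8)
  tryCatch(stats::shapiro.test(x)$p.value > alpha, error = function(e) FALSE)
}

#' Shock index
#'
#' Heart rate divided by systolic blood pressure — a bedside hemodynamic
#' descriptor elevated in circulatory failure.  Non-positive blood pressure
#' yields `NA`.
#' @param heart_rate,systolic_bp numeric vectors (bpm, mmHg).
#' @return numeric vector.
#' @export
shock_index <- function(heart_rate, systolic_bp) {
  out <- heart_rate / systolic_bp
  out[!is.na(systolic_bp) & systolic_bp <= 0] <- NA_real_
  out
}

#' Train the shock classifier
#'
#' Thin wrapper around [gbt_fit()] with the published defaults.
#' @param X complete numeric feature matrix.
#' @param y binary labels.
#' @param config a [classifier_config()].
#' @return fitted scorer (`shockpipe_gbt`); `predict(fit, X)` yields the
#'   class-1 probability per row.
#' @export
train_classifier <- function(X, y, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  gbt_fit(X, y, objective = "binary", class_weight = config$class_weight,
          n_estimators = config$n_estimators, num_leaves = config$num_leaves)
}

#' ROC curve and AUC
#'
#' AUC by the Mann–Whitney identity — the probability a random positive
#' outscores a random negative, ties counted half — computed from average
#' ranks; the curve is the stepwise (FPR, TPR) path over unique score
#' thresholds (descending).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels (both classes present).
#' @return list `auc`, `curve` (data.frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc needs both classes")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- !duplicated(s)
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- c(which(grp[-1]) , length(s))  # last index of each tie group
  curve <- data.frame(threshold = c(Inf, s[last]),
                      fpr = c(0, fp[last] / n0),
                      tpr = c(0, tp[last] / n1))
  list(auc = auc, curve = curve)
}

#' Stratified fold assignment
#'
#' Shuffles within each class and deals fold ids round-robin, so per-fold
#' class counts deviate from perfect proportionality by at most one.
#' @keywords internal
stratified_folds <- function(y, n_splits) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_splits), length(idx))
  }
  fold
}

#' Repeated stratified K-fold cross-validation over imputed datasets
#'
#' The experiment engine: for every completed dataset, `n_repeats`
#' independent stratified shuffles each yield `n_splits` folds; within each
#' training fold the rebalancer (SMOTE + ENN) is applied — never to the
#' validation fold, which stays at the natural class ratio — the classifier
#' is trained and the held-out rows scored.  Reports per-run AUC and
#' accuracy (0.5 threshold) plus mean, SD and a normal-approximation 95% CI
#' pooled over all runs and per dataset.
#'
#' @param imputed_sets list of complete numeric matrices (or a named list
#'   of [feature_matrix()]es, encoded internally), all sharing `y` and row
#'   order.
#' @param y binary labels.
#' @param cv a [cv_config()].
#' @param clf_config a [classifier_config()].
#' @param resample a [resample_config()] or `NULL` to skip rebalancing.
#' @param scorer optional custom scorer `function(X_train, y_train,
#'   X_valid) -> scores` replacing rebalance+GBT (used e.g. for univariate
#'   reference scorers on identical folds).
#' @param categorical logical per-column flag passed to SMOTE.
#' @param keep_curves store each run's ROC curve (memory-heavy; default
#'   FALSE).
#' @return object of class `cv_report`: `runs` (data.frame dataset, repeat,
#'   fold, auc, accuracy), `summary`, `per_dataset`, and the fold
#'   definitions used (`folds`), enabling paired comparisons.
#' @export
repeated_stratified_cv <- function(imputed_sets, y, cv = cv_config(),
                                   clf_config = classifier_config(),
                                   resample = resample_config(),
                                   scorer = NULL, categorical = NULL,
                                   keep_curves = FALSE) {
  stopifnot(inherits(cv, "cv_config"))
  y <- as.integer(y)
  if (min(table(y)) < cv$n_splits)
    stop("minority class count must be >= n_splits for stratification")
  mats <- lapply(imputed_sets, function(d) {
    if (inherits(d, "feature_matrix")) encode_mixed(d)$X else as.matrix(d)
  })
  if (is.null(names(mats)) || any(!nzchar(names(mats))))
    names(mats) <- paste0("dataset_", seq_along(mats))

  # fold assignments are drawn once per repeat and shared by all datasets
  folds <- lapply(seq_len(cv$n_repeats), function(r)
    with_seed(child_seed(cv$seed, "cv-folds", r),
              stratified_folds(y, cv$n_splits)))

  runs <- list(); curves <- list(); k <- 0L
  for (ds in names(mats)) {
    X <- mats[[ds]]
    for (r in seq_len(cv$n_repeats)) {
      fold <- folds[[r]]
      for (f in seq_len(cv$n_splits)) {
        tr <- which(fold != f); va <- which(fold == f)
        if (length(unique(y[va])) < 2 || length(unique(y[tr])) < 2)
          stop("fold without both classes")
        if (is.null(scorer)) {
          Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
          if (!is.null(resample)) {
            rs_cfg <- resample
            rs_cfg$seed <- child_seed(resample$seed, paste0("cv-", ds), r * 1000L + f)
            rs <- smote_enn(Xtr, ytr, rs_cfg, categorical = categorical)
            # leakage guard: map provenance back to original row ids and
            # assert no validation row ever enters the training material
            origin <- c(tr[stats::na.omit(rs$source_row)],
                        tr[as.vector(rs$parents)])
            if (length(intersect(origin, va)))
              stop("resampling leakage: validation rows in training material")
            Xtr <- rs$X; ytr <- rs$y
          }
          fit <- train_classifier(Xtr, ytr, clf_config)
          sc <- predict(fit, X[va, , drop = FALSE])
        } else {
          sc <- scorer(X[tr, , drop = FALSE], y[tr], X[va, , drop = FALSE])
        }
        ra <- roc_auc(sc, y[va])
        acc <- mean((sc >= 0.5) == (y[va] == 1))
        k <- k + 1L
        runs[[k]] <- data.frame(dataset = ds, rep = r, fold = f,
                                auc = ra$auc, accuracy = acc,
                                stringsAsFactors = FALSE)
        if (keep_curves) curves[[k]] <- ra$curve
      }
    }
  }
  runs <- do.call(rbind, runs)
  agg <- function(v) {
    m <- mean(v); s <- stats::sd(v)
    c(mean = m, sd = s, ci_lo = m - 1.96 * s, ci_hi = m + 1.96 * s)
  }
  per_dataset <- do.call(rbind, lapply(split(runs, runs$dataset), function(d)
    data.frame(dataset = d$dataset[1], n_runs = nrow(d),
               t(agg(d$auc)), accuracy_mean = mean(d$accuracy))))
  rownames(per_dataset) <- NULL
  structure(list(runs = runs,
                 summary = list(auc = agg(runs$auc),
                                accuracy = agg(runs$accuracy),
                                n_runs = nrow(runs)),
                 per_dataset = per_dataset, folds = folds,
                 curves = if (keep_curves) curves else NULL,
                 cv = cv),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  a <- x$summary$auc; ac <- x$summary$accuracy
  cat(sprintf("<cv_report> %d runs; AUC %.3f +/- %.3f (CI95%% %.3f-%.3f); accuracy %.3f +/- %.3f\n",
              x$summary$n_runs, a["mean"], a["sd"], a["ci_lo"], a["ci_hi"],
              ac["mean"], ac["sd"]))
  invisible(x)
}

#' Write a CV report as CSV + JSON summary
#' @param report a `cv_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$runs, file.path(dir, "cv_runs.csv"))
  data.table::fwrite(report$per_dataset, file.path(dir, "cv_per_dataset.csv"))
  jsonlite::write_json(
    list(auc = as.list(report$summary$auc),
         accuracy = as.list(report$summary$accuracy),
         n_runs = report$summary$n_runs),
    file.path(dir, "cv_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
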