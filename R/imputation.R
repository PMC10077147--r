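#' Configuration for the imputation engines
#'
#' @param method `"mice"`, `"knn"`, `"soft_impute"` or `"iterative_svd"`.
#' @param m number of completed datasets (MICE only; default 10, a stated
#'   balance between computational time and statistical power).
#' @param max_iter chained-equation sweeps (MICE) or completion iterations
#'   (SVD methods).
#' @param pmm_k donor candidates for predictive mean matching (default 5:
#'   the five closest predicted values are the candidate pool).
#' @param knn_k neighbours for KNN imputation.
#' @param lambda soft-threshold shrinkage for SoftImpute (`"auto"` picks it
#'   by a cross-validated grid on held-out observed entries).
#' @param rank target rank for IterativeSVD.
#' @param tol relative-change convergence threshold (> 0).
#' @param standardize z-score continuous columns before matrix completion
#'   (default `TRUE`; set `FALSE` to complete a raw numeric matrix — note
#'   centering perturbs low-rank structure by a rank-one term, so exact
#'   low-rank recovery needs `FALSE`).
#' @param seed stream seed for the stochastic methods.
#' @param model_factory,classifier_factory conditional-model factories for
#'   MICE (see [gbt_regressor()]); defaults are light gradient-boosted
#'   ensembles.
#' @return object of class `imputation_config`.
#' @export
imputation_config <- function(method = c("mice", "knn", "soft_impute",
                                         "iterative_svd"),
                              m = 10L, max_iter = NULL, pmm_k = 5L,
                              knn_k = 5L, lambda = "auto", rank = 10L,
                              tol = 1e-3, standardize = TRUE, seed = 1L,
                              model_factory = gbt_regressor(),
                              classifier_factory = gbt_classifier()) {
  method <- match.arg(method)
  if (is.null(max_iter)) max_iter <- if (method == "mice") 5L else 200L
  stopifnot(m >= 1, pmm_k >= 1, knn_k >= 1, rank >= 1, tol > 0, max_iter >= 1)
  if (is.numeric(lambda)) stopifnot(lambda >= 0)
  structure(list(method = method, m = as.integer(m),
                 max_iter = as.integer(max_iter), pmm_k = as.integer(pmm_k),
                 knn_k = as.integer(knn_k), lambda = lambda,
                 rank = as.integer(rank), tol = tol,
                 standardize = isTRUE(standardize), seed = as.integer(seed),
                 model_factory = model_factory,
                 classifier_factory = classifier_factory),
            class = "imputation_config")
}

new_imputation_set <- function(completed, method, config, log = character(0)) {
  stopifnot(length(completed) >= 1)
  for (fm in completed)
    if (any(missing_mask(fm))) stop("internal: completed matrix has NAs")
  structure(list(completed = completed, method = method,
                 config = config[setdiff(names(config),
                                         c("model_factory",
                                           "classifier_factory"))],
                 log = log),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> method=%s, %d completed dataset(s), %d x %d\n",
              x$method, length(x$completed),
              nrow(x$completed[[1]]$data), ncol(x$completed[[1]]$data)))
  invisible(x)
}

#' Dispatch an imputation configuration to its engine
#' @param fm a [feature_matrix()] with missing cells.
#' @param config an [imputation_config()].
#' @return an `imputation_set`.
#' @export
impute <- function(fm, config) {
  stopifnot(inherits(config, "imputation_config"))
  switch(config$method,
         mice = mice_impute(fm, config),
         knn = knn_impute(fm, config),
         soft_impute = soft_impute(fm, config),
         iterative_svd = iterative_svd_impute(fm, config))
}

# ---------------------------------------------------------------------------
# mixed-type numeric encoding

#' Encode a mixed-type feature matrix numerically
#'
#' Continuous columns are z-scored on their observed cells; categorical
#' columns become one-hot blocks (missing rows blank across the block).
#' Matrix-completion engines operate on this representation.  The returned
#' decoder inverts the transform: continuous cells are de-standardised,
#' categorical blocks decoded by argmax, and observed cells always
#' round-trip exactly (the decoder re-installs the original values).
#'
#' @param fm a [feature_matrix()].
#' @param standardize z-score continuous columns (default `TRUE`).
#' @return list: `X` (numeric matrix with `NA` at missing cells), `decode`
#'   (`function(Xc)` mapping a completed numeric matrix back to a
#'   [feature_matrix()]), `col_map` (list of output-column indices per
#'   variable).
#' @export
encode_mixed <- function(fm, standardize = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  blocks <- list(); col_map <- list(); centers <- list(); scales <- list()
  dropped <- character(0)
  at <- 0L
  for (j in seq_len(ncol(fm$data))) {
    nm <- fm$meta$name[j]; x <- fm$data[[j]]
    if (fm$meta$type[j] == "continuous") {
      mu <- mean(x, na.rm = TRUE); sd <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(sd) || sd == 0) sd <- 1
      if (!is.finite(mu)) mu <- 0
      if (!standardize) { mu <- 0; sd <- 1 }
      blocks[[nm]] <- matrix((x - mu) / sd, ncol = 1,
                             dimnames = list(NULL, nm))
      centers[[nm]] <- mu; scales[[nm]] <- sd
      col_map[[nm]] <- at + 1L; at <- at + 1L
    } else {
      lv <- levels(x)
      if (length(lv) < 2) {
        warning("dropping single-level categorical '", nm, "' from encoding")
        dropped <- c(dropped, nm)
        next
      }
      oh <- matrix(NA_real_, length(x), length(lv),
                   dimnames = list(NULL, paste(nm, lv, sep = ".")))
      obs <- !is.na(x)
      for (k in seq_along(lv)) oh[obs, k] <- as.numeric(x[obs] == lv[k])
      blocks[[nm]] <- oh
      col_map[[nm]] <- at + seq_along(lv); at <- at + length(lv)
    }
  }
  X <- do.call(cbind, blocks)
  meta <- fm$meta; data_orig <- fm$data
  decode <- function(Xc) {
    stopifnot(ncol(Xc) == ncol(X))
    out <- data_orig
    for (j in seq_len(ncol(out))) {
      nm <- meta$name[j]
      if (nm %in% dropped) next
      miss <- is.na(data_orig[[j]])
      if (!any(miss)) next
      if (meta$type[j] == "continuous") {
        out[[j]][miss] <- Xc[miss, col_map[[nm]]] * scales[[nm]] + centers[[nm]]
      } else {
        lv <- levels(data_orig[[j]])
        sub <- Xc[miss, col_map[[nm]], drop = FALSE]
        out[[j]][miss] <- lv[max.col(sub, ties.method = "first")]
      }
    }
    feature_matrix(out, meta, subject_id = fm$subject_id)
  }
  list(X = X, decode = decode, col_map = col_map, dropped = dropped)
}

# ---------------------------------------------------------------------------
# MICE with PMM

#' Predictive-mean-matching donor draw
#'
#' Given the model prediction for a missing cell and the predictions on the
#' observed donors, selects the `k` donors with the smallest absolute
#' prediction distance (ties broken by donor index order) and returns the
#' observed value of one of them uniformly at random — so every imputation
#' is an actually observed value, preserving the empirical support of the
#' variable (including multimodality).
#'
#' @param pred_missing scalar prediction for the cell being imputed.
#' @param pred_observed predictions on the donor rows.
#' @param donor_values observed values of the donor rows.
#' @param k candidate pool size (clipped to the donor count; default 5).
#' @return one imputed value.
#' @export
pmm_draw <- function(pred_missing, pred_observed, donor_values, k = 5L) {
  nd <- length(donor_values)
  if (nd < 1) stop("empty donor set")
  stopifnot(length(pred_observed) == nd)
  k <- min(as.integer(k), nd)
  ord <- order(abs(pred_observed - pred_missing), seq_len(nd))
  cand <- ord[seq_len(k)]
  donor_values[cand[sample.int(k, 1L)]]
}

#' Multiple imputation by chained equations (tree-boosted, PMM)
#'
#' Fills each incomplete variable in turn from all the others, sweeping
#' until convergence: continuous targets are modelled by the regression
#' factory and imputed by 5-candidate predictive mean matching; categorical
#' targets are modelled by the classification factory and drawn from the
#' predicted class distribution.  `m` independent stochastic chains (own
#' initial fills and donor draws) give `m` completed datasets.  Visit order
#' is ascending missingness; the initial fill is a random draw from the
#' observed values; convergence is declared when the mean absolute change
#' of imputed continuous cells between sweeps (on the z-scored scale) drops
#' below `tol`.
#'
#' @param fm a [feature_matrix()] with missing cells.
#' @param config an [imputation_config()] (`method = "mice"`).
#' @return an `imputation_set` of `config$m` completed matrices.
#' @export
mice_impute <- function(fm, config = imputation_config("mice")) {
  stopifnot(inherits(fm, "feature_matrix"))
  mm <- missing_mask(fm)
  all_missing <- colnames(mm)[colSums(!mm) == 0]
  if (length(all_missing))
    stop("column(s) entirely missing: ", paste(all_missing, collapse = ", "))
  n <- nrow(fm$data)
  miss_counts <- colSums(mm)
  targets <- names(sort(miss_counts[miss_counts > 0]))  # ascending visit order
  log <- character(0)
  sds <- vapply(seq_len(ncol(fm$data)), function(j)
    if (fm$meta$type[j] == "continuous") {
      s <- stats::sd(fm$data[[j]], na.rm = TRUE)
      if (is.finite(s) && s > 0) s else 1
    } else NA_real_, 0)
  names(sds) <- fm$meta$name

  if (length(targets) == 0)
    return(new_imputation_set(rep(list(fm), config$m), "mice", config,
                              "no missing cells; zero sweeps"))

  run_chain <- function(chain) {
    with_seed(child_seed(config$seed, "mice-chain", chain), {
      cur <- fm$data
      for (nm in targets) {  # initial fill: random draws from observed
        miss <- mm[, nm]
        obs_vals <- cur[[nm]][!miss]
        cur[[nm]][miss] <- sample(obs_vals, sum(miss), replace = TRUE)
      }
      for (sweep in seq_len(config$max_iter)) {
        delta <- 0; ncont <- 0L
        for (nm in targets) {
          miss <- mm[, nm]
          j <- match(nm, fm$meta$name)
          pred_fm <- feature_matrix(cur[, -j, drop = FALSE],
                                    fm$meta[-j, , drop = FALSE],
                                    subject_id = fm$subject_id)
          Xfull <- encode_mixed(pred_fm)$X
          Xobs <- Xfull[!miss, , drop = FALSE]
          Xmis <- Xfull[miss, , drop = FALSE]
          if (fm$meta$type[j] == "continuous") {
            y <- cur[[nm]]
            fitted <- config$model_factory(Xobs, fm$data[[nm]][!miss])
            p_obs <- fitted$predict(Xobs)
            p_mis <- fitted$predict(Xmis)
            donors <- fm$data[[nm]][!miss]
            new_vals <- vapply(seq_along(p_mis), function(i)
              pmm_draw(p_mis[i], p_obs, donors, config$pmm_k), 0)
            delta <- delta + sum(abs(new_vals - cur[[nm]][miss])) / sds[nm]
            ncont <- ncont + sum(miss)
            cur[[nm]][miss] <- new_vals
          } else {
            fitted <- config$classifier_factory(Xobs, fm$data[[nm]][!miss])
            P <- fitted$predict(Xmis)
            lv <- fitted$levels
            draws <- vapply(seq_len(nrow(P)), function(i)
              lv[sample.int(length(lv), 1L, prob = pmax(P[i, ], 1e-12))], "")
            cur[[nm]][miss] <- draws
          }
        }
        mac <- if (ncont > 0) delta / ncont else 0
        log <<- c(log, sprintf("chain %d sweep %d mean_abs_change %.6g",
                               chain, sweep, mac))
        if (ncont > 0 && mac < config$tol) break
        if (ncont == 0 && sweep >= 2) break
      }
      feature_matrix(cur, fm$meta, subject_id = fm$subject_id)
    })
  }

  completed <- lapply(seq_len(config$m), run_chain)
  new_imputation_set(completed, "mice", config, log)
}

# ---------------------------------------------------------------------------
# KNN imputation

#' k-nearest-neighbour imputation
#'
#' Distances are Euclidean over the standardised continuous coordinates the
#' two rows both observe, rescaled by `sqrt(p_total / p_shared)` (the
#' standard incomplete-data Euclidean convention, so rows sharing few
#' coordinates are not spuriously close).  A missing continuous cell gets
#' the mean of its `k` nearest donors' observed values; a categorical cell
#' gets the donor mode (ties broken by level order).  Fully deterministic.
#'
#' @param fm a [feature_matrix()].
#' @param config an [imputation_config()] (`knn_k` used).
#' @return an `imputation_set` with one completed matrix.
#' @export
knn_impute <- function(fm, config = imputation_config("knn")) {
  stopifnot(inherits(fm, "feature_matrix"))
  mm <- missing_mask(fm)
  if (!any(mm))
    return(new_imputation_set(list(fm), "knn", config, "nothing to impute"))
  cont <- fm$meta$type == "continuous"
  Z <- vapply(which(cont), function(j) {
    x <- fm$data[[j]]
    mu <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    (x - mu) / s
  }, numeric(nrow(fm$data)))
  Z <- matrix(Z, nrow = nrow(fm$data))
  ptot <- ncol(Z)
  n <- nrow(fm$data)
  obsZ <- !is.na(Z)

  # pairwise nan-Euclidean distances (moderate n; vectorised per row)
  Z0 <- Z; Z0[!obsZ] <- 0
  sq <- Z0^2
  D2 <- matrix(Inf, n, n)
  shared <- tcrossprod(obsZ * 1)                       # counts of shared coords
  cross <- tcrossprod(Z0)
  a2 <- sq %*% t(obsZ * 1)                             # sum over shared of z_i^2
  b2 <- (obsZ * 1) %*% t(sq)
  D2 <- a2 + b2 - 2 * cross
  D2[shared == 0] <- Inf
  ok <- shared > 0
  D2[ok] <- pmax(D2[ok], 0) * ptot / shared[ok]
  diag(D2) <- Inf

  out <- fm$data
  for (j in seq_len(ncol(out))) {
    miss <- mm[, j]
    if (!any(miss)) next
    donors_j <- which(!miss)
    for (i in which(miss)) {
      d <- D2[i, donors_j]
      usable <- is.finite(d)
      if (!any(usable)) {
        if (all(!is.finite(D2[i, -i])))
          stop("row ", i, " shares no observed coordinates with any other row")
        stop("no usable donor for row ", i, ", variable ",
             fm$meta$name[j])
      }
      dv <- donors_j[usable]
      ord <- dv[order(d[usable], dv)]
      nn <- ord[seq_len(min(config$knn_k, length(ord)))]
      if (fm$meta$type[j] == "continuous") {
        out[[j]][i] <- mean(fm$data[[j]][nn])
      } else {
        tab <- table(factor(fm$data[[j]][nn], levels = levels(fm$data[[j]])))
        out[[j]][i] <- names(tab)[which.max(tab)]  # ties -> level order
      }
    }
  }
  new_imputation_set(list(feature_matrix(out, fm$meta,
                                         subject_id = fm$subject_id)),
                     "knn", config)
}

# ---------------------------------------------------------------------------
# SVD-based matrix completion

svt <- function(M, lambda) {
  s <- svd(M)
  d <- pmax(s$d - lambda, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' SoftImpute: nuclear-norm-regularised matrix completion
#'
#' Iterates `Z <- SVT_lambda(P_obs(X) + P_miss(Z))` — replace the missing
#' entries of the data by the current estimate, soft-threshold the singular
#' values by `lambda` — until the relative Frobenius change drops below
#' `tol`.  Operates on the [encode_mixed()] representation; observed cells
#' are restored exactly on output and categorical blocks decoded by argmax.
#' `lambda = "auto"` selects the shrinkage on a held-out 10% of observed
#' entries over a geometric grid below the top singular value.
#'
#' @param fm a [feature_matrix()].
#' @param config an [imputation_config()].
#' @return an `imputation_set` with one completed matrix.
#' @export
soft_impute <- function(fm, config = imputation_config("soft_impute")) {
  stopifnot(inherits(fm, "feature_matrix"))
  mm <- missing_mask(fm)
  if (!any(mm))
    return(new_imputation_set(list(fm), "soft_impute", config,
                              "nothing to impute"))
  enc <- encode_mixed(fm, standardize = config$standardize)
  X <- enc$X
  obs <- !is.na(X)
  lambda <- config$lambda
  if (identical(lambda, "auto"))
    lambda <- select_lambda(X, obs, config)
  res <- soft_impute_core(X, obs, lambda, config$max_iter, config$tol)
  Xc <- res$Z
  Xc[obs] <- X[obs]  # observed-restore
  new_imputation_set(list(enc$decode(Xc)), "soft_impute",
                     c(config, lambda_used = lambda), res$log)
}

soft_impute_core <- function(X, obs, lambda, max_iter, tol) {
  # Proximal (MM) iteration Z <- SVT_lambda(P_obs(X) + P_miss(Z)).  A small
  # lambda moves the iterate only O(lambda) per step, so the target lambda
  # is approached through the standard warm-start continuation path: a
  # geometric ladder from just below the top singular value down to lambda,
  # re-using each solution as the next start.
  Z <- X; Z[!obs] <- 0
  log <- character(0)
  s1 <- svd(Z, nu = 0, nv = 0)$d[1]
  lams <- if (lambda >= 0.7 * s1 || s1 == 0) lambda
          else unique(c(exp(seq(log(0.7 * s1), log(max(lambda, 1e-12)),
                                length.out = 25L)), lambda))
  converged <- FALSE
  objective <- NULL
  for (li in seq_along(lams)) {
    lam <- lams[li]
    final <- li == length(lams)
    if (final) objective <- numeric(0)
    for (it in seq_len(max_iter)) {
      W <- X; W[!obs] <- Z[!obs]
      Znew <- svt(W, lam)
      if (final) {
        sv <- svd(Znew, nu = 0, nv = 0)$d
        objective <- c(objective,
                       0.5 * sum((X[obs] - Znew[obs])^2) + lam * sum(sv))
      }
      num <- sqrt(sum((Znew - Z)^2)); den <- max(sqrt(sum(Z^2)), 1e-12)
      Z <- Znew
      if (num / den < tol) {
        if (final) {
          converged <- TRUE
          log <- c(log, sprintf("converged at lambda=%.4g iter %d (rel change %.3g)",
                                lam, it, num / den))
        }
        break
      }
    }
  }
  if (!converged) {
    log <- c(log, sprintf("warning: no convergence in %d iters at final lambda; best iterate returned",
                          max_iter))
    warning("soft_impute: no convergence in ", max_iter,
            " iterations; best iterate returned")
  }
  list(Z = Z, log = log, objective = objective)
}

select_lambda <- function(X, obs, config) {
  oidx <- which(obs)
  ho_n <- max(1L, floor(0.1 * length(oidx)))
  with_seed(child_seed(config$seed, "lambda-cv"), {
    ho <- sample(oidx, ho_n)
  })
  obs_tr <- obs; obs_tr[ho] <- FALSE
  if (any(colSums(obs_tr) == 0)) return(stats::sd(X[obs], na.rm = TRUE))
  Z0 <- X; Z0[!obs_tr] <- 0
  smax <- svd(Z0, nu = 0, nv = 0)$d[1]
  grid <- smax * c(0.5, 0.25, 0.1, 0.05, 0.02)
  errs <- vapply(grid, function(l) {
    fit <- soft_impute_core(X * ifelse(obs_tr, 1, NA), obs_tr, l,
                            max_iter = min(config$max_iter, 100L),
                            tol = max(config$tol, 1e-4))
    mean((fit$Z[ho] - X[ho])^2)
  }, 0)
  grid[which.min(errs)]
}

#' IterativeSVD: fixed-rank matrix completion
#'
#' Initialises missing entries at column means, then alternates a rank-`r`
#' truncated-SVD reconstruction with re-clamping of the observed entries,
#' until the relative Frobenius change of the reconstruction drops below
#' `tol`.  Observed cells are exact on output.
#'
#' @param fm a [feature_matrix()].
#' @param config an [imputation_config()] (`rank` used; must be smaller
#'   than both matrix dimensions of the encoded representation).
#' @return an `imputation_set` with one completed matrix.
#' @export
iterative_svd_impute <- function(fm,
                                 config = imputation_config("iterative_svd")) {
  stopifnot(inherits(fm, "feature_matrix"))
  mm <- missing_mask(fm)
  if (!any(mm))
    return(new_imputation_set(list(fm), "iterative_svd", config,
                              "nothing to impute; 0 iterations"))
  enc <- encode_mixed(fm, standardize = config$standardize)
  X <- enc$X
  obs <- !is.na(X)
  r <- config$rank
  if (r >= min(dim(X)))
    stop("rank (", r, ") must be < min matrix dimension (", min(dim(X)), ")")
  mu <- colMeans(X, na.rm = TRUE); mu[!is.finite(mu)] <- 0
  Z <- X
  for (j in seq_len(ncol(Z))) Z[!obs[, j], j] <- mu[j]
  log <- character(0)
  for (it in seq_len(config$max_iter)) {
    s <- svd(Z, nu = r, nv = r)
    R <- s$u %*% (s$d[seq_len(r)] * t(s$v))
    Znew <- X; Znew[!obs] <- R[!obs]
    num <- sqrt(sum((Znew - Z)^2)); den <- max(sqrt(sum(Z^2)), 1e-12)
    Z <- Znew
    if (num / den < config$tol) {
      log <- c(log, sprintf("converged at iter %d", it)); break
    }
  }
  Xc <- Z; Xc[obs] <- X[obs]
  new_imputation_set(list(enc$decode(Xc)), "iterative_svd", config, log)
}

#' Write an imputation set as CSVs plus a JSON manifest
#' @param iset an `imputation_set`.
#' @param dir output directory.
#' @param prefix dataset-file prefix (default the method name).
#' @return `dir`, invisibly.
#' @export
write_imputation_set <- function(iset, dir, prefix = iset$method) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(iset$completed)) {
    f <- file.path(dir, sprintf("%s_%d.csv", prefix, i))
    write_feature_matrix(iset$completed[[i]], f)
    files <- c(files, f)
  }
  manifest <- list(method = iset$method, files = basename(files),
                   config = iset$config, log = iset$log)
  jsonlite::write_json(manifest, file.path(dir, paste0(prefix, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
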