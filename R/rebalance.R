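#' Resampling configuration
#'
#' @param smote_k neighbours used for SMOTE interpolation (default 5, as in
#'   the original algorithm).
#' @param target_ratio minority:majority ratio after over-sampling
#'   (default 1.0 — fully balanced before cleaning).
#' @param enn_k neighbours for the Edited-Nearest-Neighbours vote
#'   (default 3, as in the original algorithm).
#' @param enn_votes `"all"` (vote on the combined post-SMOTE set; matches
#'   the combined SMOTE+ENN method) or `"original"`.
#' @param seed stream seed.
#' @return object of class `resample_config`.
#' @export
resample_config <- function(smote_k = 5L, target_ratio = 1.0, enn_k = 3L,
                            enn_votes = c("all", "original"), seed = 1L) {
  enn_votes <- match.arg(enn_votes)
  stopifnot(smote_k >= 1, enn_k >= 1,
            target_ratio > 0, target_ratio <= 1)
  structure(list(smote_k = as.integer(smote_k), target_ratio = target_ratio,
                 enn_k = as.integer(enn_k), enn_votes = enn_votes,
                 seed = as.integer(seed)),
            class = "resample_config")
}

#' Exact k-nearest neighbours with deterministic tie-breaking
#'
#' FNN's kd-tree answers are re-ranked by (distance, index) so equal
#' distances are always resolved in index order — required for the
#' brute-force-matching determinism of the resamplers.  Queries request a
#' margin of extra candidates; on the small fixtures where ties matter the
#' margin covers the whole reference set.
#' @keywords internal
exact_knn <- function(ref, query, k, self_index = NULL) {
  n <- nrow(ref)
  kq <- min(n, k + 10L + !is.null(self_index))
  nn <- FNN::get.knnx(ref, query, k = kq)
  out <- matrix(0L, nrow(query), k)
  for (i in seq_len(nrow(query))) {
    cand <- nn$nn.index[i, ]; dd <- nn$nn.dist[i, ]
    if (!is.null(self_index)) {
      keep <- cand != self_index[i]
      cand <- cand[keep]; dd <- dd[keep]
    }
    o <- order(dd, cand)
    out[i, ] <- cand[o][seq_len(k)]
  }
  out
}

#' SMOTE synthetic minority over-sampling
#'
#' Each synthetic row is `x + delta * (x_nn - x)` with `delta ~ U(0, 1)`,
#' where `x` is a minority row sampled with replacement and `x_nn` one of
#' its `k` nearest minority neighbours (Euclidean on z-scored continuous
#' features).  Columns flagged categorical are copied from the seed row
#' rather than interpolated, so level indicators stay valid.
#'
#' @param X_minority numeric matrix of minority rows (>= 2 rows).
#' @param n_new number of synthetic rows to create.
#' @param k neighbour count (clipped to `nrow - 1`).
#' @param categorical logical vector per column (default none).
#' @return list `X` (synthetic rows) and `parents` (two-column matrix of
#'   minority row indices each synthetic row interpolates between).
#' @export
smote_oversample <- function(X_minority, n_new, k = 5L, categorical = NULL) {
  X_minority <- as.matrix(X_minority)
  n <- nrow(X_minority)
  if (n < 2) stop("SMOTE needs at least two minority rows")
  if (n_new == 0)
    return(list(X = X_minority[0, , drop = FALSE],
                parents = matrix(integer(0), 0, 2)))
  categorical <- categorical %||% rep(FALSE, ncol(X_minority))
  k <- min(as.integer(k), n - 1L)
  Z <- scale(X_minority[, !categorical, drop = FALSE])
  if (ncol(Z) == 0) Z <- matrix(0, n, 1)
  Z[, !is.finite(colSums(Z))] <- 0  # constant columns
  nn <- exact_knn(Z, Z, k, self_index = seq_len(n))
  seed_rows <- sample.int(n, n_new, replace = TRUE)
  nbr_pick <- sample.int(k, n_new, replace = TRUE)
  nbr_rows <- nn[cbind(seed_rows, nbr_pick)]
  delta <- stats::runif(n_new)
  Xs <- X_minority[seed_rows, , drop = FALSE] +
    delta * (X_minority[nbr_rows, , drop = FALSE] -
             X_minority[seed_rows, , drop = FALSE])
  if (any(categorical))
    Xs[, categorical] <- X_minority[seed_rows, categorical, drop = FALSE]
  list(X = Xs, parents = cbind(seed_rows, nbr_rows))
}

#' Edited-Nearest-Neighbours cleaning
#'
#' Removes every row whose `k` nearest neighbours (self excluded) carry a
#' majority label different from its own.  A single pass: all votes are
#' computed on the input set before any removal (no cascade).
#'
#' @param X numeric matrix.
#' @param y labels (length `nrow(X)`).
#' @param k neighbour count (must be < `nrow(X)`).
#' @return integer vector of surviving row indices.
#' @export
enn_clean <- function(X, y, k = 3L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= n) stop("enn_clean: k must be smaller than the number of rows")
  nn <- exact_knn(X, X, k, self_index = seq_len(n))
  keep <- vapply(seq_len(n), function(i) {
    votes <- y[nn[i, ]]
    tab <- table(votes)
    top <- names(tab)[tab == max(tab)]
    # removed only when the neighbourhood majority strictly disagrees
    if (length(top) > 1) TRUE else top == as.character(y[i])
  }, TRUE)
  which(keep)
}

#' Combined SMOTE over-sampling + ENN cleaning
#'
#' Over-samples the minority class to `target_ratio` times the majority
#' count, then runs a single ENN pass over the combined set (original +
#' synthetic), removing misclassified rows of either class.  This is the
#' classic combined resampler for imbalanced clinical cohorts; applied
#' inside each cross-validation training fold only (see
#' [repeated_stratified_cv()]), never to validation data.
#'
#' @param X numeric matrix of features.
#' @param y binary labels; the minority class is identified by count.
#' @param config a [resample_config()].
#' @param categorical logical per-column flag for SMOTE copying.
#' @return object of class `resampled_set`: `X`, `y`, `provenance`
#'   (`"original"`/`"synthetic"` per surviving row), `source_row` (index
#'   into the input `X` for originals, `NA` for synthetics), `parents`
#'   (input-row parents of every synthetic row created), `removed`
#'   (combined-set indices removed by ENN) and final class counts.
#' @export
smote_enn <- function(X, y, config = resample_config(), categorical = NULL) {
  stopifnot(inherits(config, "resample_config"))
  X <- as.matrix(X)
  y <- as.integer(y)
  cls <- sort(unique(y))
  if (length(cls) != 2) stop("smote_enn needs binary labels")
  n_by <- table(factor(y, levels = cls))
  minority <- cls[which.min(n_by)]; majority <- cls[which.max(n_by)]
  min_idx <- which(y == minority)
  n_new <- max(0L, as.integer(round(config$target_ratio * max(n_by))) -
                 length(min_idx))
  with_seed(child_seed(config$seed, "smote"), {
    sm <- smote_oversample(X[min_idx, , drop = FALSE], n_new,
                           k = config$smote_k, categorical = categorical)
  })
  Xall <- rbind(X, sm$X)
  yall <- c(y, rep(minority, nrow(sm$X)))
  prov <- c(rep("original", nrow(X)), rep("synthetic", nrow(sm$X)))
  src <- c(seq_len(nrow(X)), rep(NA_integer_, nrow(sm$X)))
  vote_set <- if (config$enn_votes == "all") seq_len(nrow(Xall))
              else seq_len(nrow(X))
  # single-pass ENN: vote among the chosen reference set
  ref <- Xall[vote_set, , drop = FALSE]
  k <- min(config$enn_k, nrow(ref) - 1L)
  # self-position of each query row inside the reference set (0 = absent)
  self_pos <- match(seq_len(nrow(Xall)), vote_set, nomatch = 0L)
  nn <- exact_knn(ref, Xall, k, self_index = self_pos)
  keep <- vapply(seq_len(nrow(Xall)), function(i) {
    nbrs <- vote_set[nn[i, ]]
    votes <- yall[nbrs]
    tab <- table(votes)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) TRUE else top == as.character(yall[i])
  }, TRUE)
  removed <- which(!keep)
  structure(list(X = Xall[keep, , drop = FALSE], y = yall[keep],
                 provenance = prov[keep], source_row = src[keep],
                 parents = if (nrow(sm$parents))
                   matrix(min_idx[sm$parents], ncol = 2) else sm$parents,
                 removed = removed,
                 counts = table(factor(yall[keep], levels = cls)),
                 minority = minority, majority = majority),
            class = "resampled_set")
}

#' @export
print.resampled_set <- function(x, ...) {
  cat(sprintf("<resampled_set> %d rows (%d synthetic), %d removed by ENN; counts: %s\n",
              nrow(x$X), sum(x$provenance == "synthetic"), length(x$removed),
              paste(names(x$counts), as.integer(x$counts), sep = "=",
                    collapse = ", ")))
  invisible(x)
}
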