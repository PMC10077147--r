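# Independent brute-force oracles.  These deliberately re-derive each
# statistic from its definition, sharing no code with the implementation.

ks_brute <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(vapply(grid, function(x) abs(mean(a <= x) - mean(b <= x)), 0))
}

auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

by_brute <- function(p) {
  # literal step-up definition: adj_i = min_{j >= i} min(1, p_(j) m c(m) / j)
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(ps[i:m] * m * cm / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

enn_brute_1d <- function(x, y, k) {
  n <- length(x)
  keep <- logical(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i]); d[i] <- Inf
    nn <- order(d, seq_len(n))[seq_len(k)]
    tab <- table(y[nn])
    top <- names(tab)[tab == max(tab)]
    keep[i] <- length(top) > 1 || top == as.character(y[i])
  }
  which(keep)
}

chisq_brute <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# point-in-convex-polygon (2-D), hull given by chull vertex order
in_hull_2d <- function(pt, hull_pts) {
  h <- hull_pts[grDevices::chull(hull_pts), , drop = FALSE]
  n <- nrow(h)
  signs <- vapply(seq_len(n), function(i) {
    a <- h[i, ]; b <- h[(i %% n) + 1, ]
    (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
  }, 0)
  all(signs <= 1e-9) || all(signs >= -1e-9)
}
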