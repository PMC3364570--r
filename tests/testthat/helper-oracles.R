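# Independent reference implementations used as oracles.  These deliberately
# use naive loop-based code paths, distinct from the package internals.

# Whole-sample mirror of an index (1-based), scalar version.
mirror1 <- function(i, n) {
  if (n == 1) return(1)
  p <- 2 * (n - 1)
  m <- (i - 1) %% p
  if (m >= n) m <- p - m
  m + 1
}

# Naive separable filtering with whole-sample symmetric extension, centered
# odd-length filter; direct O(n m k) loops.
naive_filter2 <- function(M, f) {
  n <- nrow(M); m <- ncol(M)
  half <- (length(f) - 1) / 2
  tmp <- matrix(0, n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    acc <- 0
    for (t in seq_along(f))
      acc <- acc + f[t] * M[mirror1(i + t - 1 - half, n), j]
    tmp[i, j] <- acc
  }
  out <- matrix(0, n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    acc <- 0
    for (t in seq_along(f))
      acc <- acc + f[t] * tmp[i, mirror1(j + t - 1 - half, m)]
    out[i, j] <- acc
  }
  out
}

# Naive one-level Laplacian pyramid analysis: returns list(a, b) using the
# package's published 9/7 filters but an independent computation.
naive_lp_once <- function(x) {
  fl <- ivusseg:::lp_filters()
  sm <- naive_filter2(x, fl$h)
  a <- sm[seq(1, nrow(sm), 2), seq(1, ncol(sm), 2), drop = FALSE]
  # upsample and interpolate with 2*g, separably, loops
  g2 <- 2 * fl$g
  n <- nrow(x); m <- ncol(x)
  U <- matrix(0, n, m)
  U[seq(1, n, 2), seq(1, m, 2)] <- a
  half <- (length(g2) - 1) / 2
  tmp <- matrix(0, n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    acc <- 0
    for (t in seq_along(g2))
      acc <- acc + g2[t] * U[mirror1(i + t - 1 - half, n), j]
    tmp[i, j] <- acc
  }
  pred <- matrix(0, n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    acc <- 0
    for (t in seq_along(g2))
      acc <- acc + g2[t] * tmp[i, mirror1(j + t - 1 - half, m)]
    pred[i, j] <- acc
  }
  list(a = a, b = x - pred)
}

# Direct evaluation of one explicit level-set step: loops straight over the
# evolution equation with central differences, replicated borders, 5-point
# Laplacian, |grad phi| floored at 1e-10 and the cosine-regularized Dirac.
oracle_evolve_step <- function(phi, g, mu, lam, nu, alpha, dt) {
  n <- nrow(phi); m <- ncol(phi)
  cl <- function(i, k) min(max(i, 1), k)
  nx <- matrix(0, n, m); ny <- matrix(0, n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    px <- (phi[i, cl(j + 1, m)] - phi[i, cl(j - 1, m)]) / 2
    py <- (phi[cl(i + 1, n), j] - phi[cl(i - 1, n), j]) / 2
    nrm <- sqrt(px^2 + py^2)
    if (nrm < 1e-10) nrm <- 1e-10
    nx[i, j] <- px / nrm
    ny[i, j] <- py / nrm
  }
  gnx <- g * nx; gny <- g * ny
  out <- matrix(0, n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    lap <- phi[i, cl(j + 1, m)] + phi[i, cl(j - 1, m)] +
      phi[cl(i + 1, n), j] + phi[cl(i - 1, n), j] - 4 * phi[i, j]
    curv <- (nx[i, cl(j + 1, m)] - nx[i, cl(j - 1, m)]) / 2 +
      (ny[cl(i + 1, n), j] - ny[cl(i - 1, n), j]) / 2
    divg <- (gnx[i, cl(j + 1, m)] - gnx[i, cl(j - 1, m)]) / 2 +
      (gny[cl(i + 1, n), j] - gny[cl(i - 1, n), j]) / 2
    s <- phi[i, j]
    del <- if (abs(s) <= alpha) (1 + cos(pi * s / alpha)) / (2 * alpha) else 0
    out[i, j] <- s + dt * (mu * (lap - curv) + lam * del * divg +
                             nu * g[i, j] * del)
  }
  out
}

# Exhaustive circular-Hough scoring oracle: for every center/radius in the
# given ranges, count edge points within half a pixel of the circle.
oracle_cht_best <- function(mask, xc_range, yc_range, r_range) {
  ep <- which(mask, arr.ind = TRUE)
  best <- NULL; best_n <- -1
  for (r in r_range) for (yc in yc_range) for (xc in xc_range) {
    d <- sqrt((ep[, 2] - 1 - xc)^2 + (ep[, 1] - 1 - yc)^2)
    cnt <- sum(abs(d - r) <= 0.5)
    if (cnt > best_n) { best_n <- cnt; best <- c(xc, yc, r) }
  }
  list(param = best, count = best_n)
}

# Brute-force minimum distance from points to a densely resampled polyline.
oracle_min_dist <- function(px, py, ref_x, ref_y) {
  vapply(seq_along(px), function(i)
    min(sqrt((ref_x - px[i])^2 + (ref_y - py[i])^2)), numeric(1))
}
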