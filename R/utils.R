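# Internal numerical helpers shared across modules.
#
# Image convention used throughout the package: a grayscale image is a numeric
# matrix `img[row, col]` with row 1 at the top.  Point coordinates are
# pixel-centered and 0-based: x = col - 1 (rightward), y = row - 1 (downward).

#' Validate a grayscale image matrix
#'
#' @param img object to check.
#' @param min_dim minimum number of rows and columns required.
#' @param arg name used in error messages.
#' @return the image, invisibly.
#' @keywords internal
check_image <- function(img, min_dim = 1L, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop(sprintf("`%s` must be at least %dx%d (got %dx%d)",
                 arg, min_dim, min_dim, nrow(img), ncol(img)), call. = FALSE)
  invisible(img)
}

# Whole-sample symmetric (mirror) index into 1..n: E(1-k) = E(1+k), E(n+k) = E(n-k).
mirror_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  m <- (idx - 1L) %% period
  m <- ifelse(m >= n, period - m, m)
  m + 1L
}

# Filter the COLUMNS of a matrix with a 1D filter `f` (odd or even length),
# whole-sample symmetric extension.  `origin` is the 1-based index of the
# filter tap aligned with the output sample (default: center).
filter_cols_sym <- function(M, f, origin = (length(f) + 1L) %/% 2L) {
  n <- nrow(M); nf <- length(f)
  lead <- origin - 1L; lag <- nf - origin
  idx <- mirror_index((1L - lead):(n + lag), n)
  P <- M[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(M))
  for (t in seq_len(nf)) {
    out <- out + f[t] * P[(t):(t + n - 1L), , drop = FALSE]
  }
  out
}

# Separable symmetric filtering along both dimensions.
filter_sep_sym <- function(M, f, origin = (length(f) + 1L) %/% 2L) {
  t(filter_cols_sym(t(filter_cols_sym(M, f, origin)), f, origin))
}

# Gaussian smoothing (separable, mirror boundaries).
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  filter_sep_sym(img, k)
}

# Central-difference gradients with replicated (Neumann) borders.
# Returns list(gx, gy): gx = d/dx (along columns), gy = d/dy (along rows).
grad_central <- function(img) {
  n <- nrow(img); m <- ncol(img)
  cl <- c(1L, 1L:(m - 1L)); cr <- c(2L:m, m)
  rt <- c(1L, 1L:(n - 1L)); rb <- c(2L:n, n)
  list(gx = (img[, cr, drop = FALSE] - img[, cl, drop = FALSE]) / 2,
       gy = (img[rb, , drop = FALSE] - img[rt, , drop = FALSE]) / 2)
}

# Mirror-pad a matrix on the bottom/right to reach target dimensions.
pad_mirror_br <- function(M, nr, nc) {
  M[mirror_index(seq_len(nr), nrow(M)), mirror_index(seq_len(nc), ncol(M)),
    drop = FALSE]
}

# Deterministic child seed streams: maps a base seed and stream index to a
# reproducible integer seed < 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647
}

# Run `expr` with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
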