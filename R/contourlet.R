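# Contourlet transform: Laplacian pyramid (LP) across scales followed by a
# directional filter bank (DFB) on each detail band.
#
# LP filters are the biorthogonal CDF 9/7 pair, normalized to unit DC gain so
# a constant image passes through the pyramid unchanged.  The DFB is realized
# lattice-free in the DFT domain: 2^l ideal fan (wedge) masks that partition
# the frequency plane, so each directional subband stays on its detail-band
# grid, reconstruction is the pointwise sum of subbands, and perfect
# reconstruction holds to machine precision.

# CDF 9/7 analysis low-pass (9 taps) and synthesis low-pass (7 taps),
# normalized to sum 1.  Both have a zero at the Nyquist frequency, so the two
# polyphase components each sum to 1/2 and constants are reproduced exactly.
lp_filters <- function() {
  h <- c(0.026748757410810, -0.016864118442875, -0.078223266528988,
         0.266864118442872, 0.602949018236358, 0.266864118442872,
         -0.078223266528988, -0.016864118442875, 0.026748757410810)
  g <- c(-0.045635881557127, -0.028771763114250, 0.295635881557127,
         0.557543526228500, 0.295635881557127, -0.028771763114250,
         -0.045635881557127)
  list(h = h / sum(h), g = g / sum(g))
}

# Low-pass filter + dyadic downsample along both dimensions (keep samples at
# 0-based even positions), symmetric extension.
lp_analysis_once <- function(img) {
  f <- lp_filters()$h
  sm <- filter_sep_sym(img, f)
  sm[seq(1L, nrow(sm), by = 2L), seq(1L, ncol(sm), by = 2L), drop = FALSE]
}

# Upsample by 2 (zeros at odd positions) and interpolate with the synthesis
# filter scaled by 2, separably.  `dim_out` disambiguates odd target sizes.
lp_predict <- function(a, dim_out) {
  g2 <- 2 * lp_filters()$g
  U <- matrix(0, dim_out[1], ncol(a))
  U[seq(1L, by = 2L, length.out = nrow(a)), ] <- a
  U <- filter_cols_sym(U, g2)
  V <- matrix(0, dim_out[2], nrow(U))
  V[seq(1L, by = 2L, length.out = ncol(a)), ] <- t(U)
  t(filter_cols_sym(V, g2))
}

#' Laplacian pyramid decomposition
#'
#' Splits an image into `levels` detail (band-pass) images `b_1..b_J` and the
#' coarsest low-pass approximation `a_J`, halving resolution per level.
#' Reconstruction by [lp_reconstruct()] is exact by construction: each detail
#' band is the residual of the image against the interpolated coarser level.
#'
#' @param image numeric matrix; both dimensions must be even multiples such
#'   that every level down to `a_J` has at least 8 rows and columns.
#' @param levels number of pyramid levels `J >= 1`.
#' @return a list with `lowpass` (list `a_1..a_J`) and `detail`
#'   (list `b_1..b_J`).
#' @examples
#' x <- matrix(rnorm(64 * 64), 64)
#' p <- lp_decompose(x, 3)
#' dim(p$lowpass[[3]])  # ~8x8
#' @export
lp_decompose <- function(image, levels) {
  check_image(image, min_dim = 8L)
  stopifnot(levels >= 1)
  lows <- vector("list", levels)
  dets <- vector("list", levels)
  a <- image
  for (j in seq_len(levels)) {
    if (ceiling(nrow(a) / 2) < 8L || ceiling(ncol(a) / 2) < 8L)
      stop(sprintf(
        "image too small for %d pyramid levels: level %d band would be %dx%d (< 8x8)",
        levels, j, ceiling(nrow(a) / 2), ceiling(ncol(a) / 2)), call. = FALSE)
    nxt <- lp_analysis_once(a)
    dets[[j]] <- a - lp_predict(nxt, dim(a))
    lows[[j]] <- nxt
    a <- nxt
  }
  list(lowpass = lows, detail = dets)
}

#' Laplacian pyramid reconstruction
#'
#' Inverts [lp_decompose()]: `a_{j-1} = b_j + predict(a_j)`, iterated up the
#' pyramid.  For coefficients straight out of the analysis the round trip is
#' exact to floating-point precision.
#'
#' @param a_J coarsest low-pass band.
#' @param details list of detail bands `b_1..b_J` (finest first).
#' @return the reconstructed image.
#' @export
lp_reconstruct <- function(a_J, details) {
  a <- a_J
  for (j in rev(seq_along(details))) {
    b <- details[[j]]
    expect_dim <- dim(b)
    if (!all(dim(a) == ceiling(expect_dim / 2)))
      stop(sprintf("pyramid shape mismatch at level %d: lowpass %dx%d vs detail %dx%d",
                   j, nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
    a <- b + lp_predict(a, expect_dim)
  }
  a
}

# Directional wedge index (0-based) of each DFT bin for an n x m grid split
# into 2^l orientation wedges.  Wedges are symmetric under frequency negation
# so masked subbands are real.  Wedge 0 starts at orientation -pi/2
# (the vertical-frequency axis), so a horizontal grating lands in wedge 0.
dfb_wedge_index <- function(n, m, l) {
  wy <- ifelse(seq_len(n) - 1L > n %/% 2L, seq_len(n) - 1L - n, seq_len(n) - 1L)
  wx <- ifelse(seq_len(m) - 1L > m %/% 2L, seq_len(m) - 1L - m, seq_len(m) - 1L)
  FY <- matrix(wy, n, m)
  FX <- matrix(wx, n, m, byrow = TRUE)
  th <- atan2(FY, FX)                 # (-pi, pi]
  th <- ifelse(th < -pi / 2, th + pi, th)
  th <- ifelse(th >= pi / 2, th - pi, th)  # fold to [-pi/2, pi/2)
  k <- floor((th + pi / 2) / (pi / 2^l))
  pmin(pmax(k, 0), 2^l - 1)
}

#' Directional filter bank decomposition
#'
#' Splits a band into `2^l` directional subbands, each carrying one
#' orientation wedge of the frequency plane.  The decomposition is lattice
#' free: every subband has the shape of the input and
#' [dfb_reconstruct()] is the pointwise sum, which inverts exactly because
#' the wedge masks partition the frequency plane.
#'
#' @param detail numeric matrix (a band-pass band, typically).
#' @param l number of directional levels (`2^l` subbands), `l >= 1`.
#' @return list of `2^l` matrices; subband `k+1` covers orientations
#'   `[-pi/2 + k*pi/2^l, -pi/2 + (k+1)*pi/2^l)`.
#' @export
dfb_decompose <- function(detail, l) {
  check_image(detail, arg = "detail")
  stopifnot(l >= 1)
  if (nrow(detail) < 2^l || ncol(detail) < 2^l)
    stop(sprintf("band %dx%d too small for %d directional levels",
                 nrow(detail), ncol(detail), l), call. = FALSE)
  Fh <- stats::fft(detail)
  k <- dfb_wedge_index(nrow(detail), ncol(detail), l)
  lapply(0:(2^l - 1), function(kk) {
    Re(stats::fft(Fh * (k == kk), inverse = TRUE)) / length(detail)
  })
}

#' Directional filter bank reconstruction
#'
#' @param subbands list of matrices from [dfb_decompose()].
#' @return the reconstructed band (their pointwise sum).
#' @export
dfb_reconstruct <- function(subbands) {
  stopifnot(is.list(subbands), length(subbands) >= 1)
  d <- dim(subbands[[1]])
  out <- matrix(0, d[1], d[2])
  for (s in subbands) {
    if (!all(dim(s) == d))
      stop("directional subbands have inconsistent shapes", call. = FALSE)
    out <- out + s
  }
  out
}

#' Contourlet decomposition
#'
#' Full contourlet analysis: a `J`-level Laplacian pyramid, then an
#' `l_j`-level directional filter bank on each detail band `b_j`, giving
#' `2^{l_j}` directional subbands `c_{j,k}` per scale plus the low-pass
#' band `a_J`.  Inputs whose dimensions are not divisible by `2^J` are
#' mirror-padded (recorded in the result and cropped on reconstruction).
#'
#' @param image numeric matrix, at least 8x8 at the coarsest scale.
#' @param levels number of pyramid levels `J`.
#' @param dfb_levels integer vector of length `J`: directional levels
#'   `l_1..l_J` per scale (finest first).
#' @return an object of class `contourlet_coeffs` with elements `lowpass`
#'   (`a_J`), `lowpass_all` (`a_1..a_J`, kept for multiresolution
#'   initialization), `bandpass` (list over scales of lists of directional
#'   subbands), `levels`, `dfb_levels`, `dim` (original size) and `pad`.
#' @examples
#' co <- contourlet_decompose(matrix(rnorm(96 * 96), 96), 3, c(2, 2, 3))
#' sum(lengths(co$bandpass))  # 4 + 4 + 8 = 16 subbands
#' @export
contourlet_decompose <- function(image, levels, dfb_levels) {
  check_image(image)
  stopifnot(levels >= 1, length(dfb_levels) == levels, all(dfb_levels >= 1))
  d0 <- dim(image)
  mult <- 2^levels
  nr <- ceiling(d0[1] / mult) * mult
  nc <- ceiling(d0[2] / mult) * mult
  padded <- if (nr != d0[1] || nc != d0[2]) pad_mirror_br(image, nr, nc) else image
  lp <- lp_decompose(padded, levels)
  bandpass <- lapply(seq_len(levels), function(j)
    dfb_decompose(lp$detail[[j]], dfb_levels[j]))
  structure(list(lowpass = lp$lowpass[[levels]],
                 lowpass_all = lp$lowpass,
                 bandpass = bandpass,
                 levels = levels,
                 dfb_levels = as.integer(dfb_levels),
                 dim = d0,
                 pad = c(nr - d0[1], nc - d0[2]),
                 image = padded),
            class = "contourlet_coeffs")
}

#' Contourlet reconstruction
#'
#' Inverts [contourlet_decompose()]: each scale's directional subbands are
#' recombined by [dfb_reconstruct()] into the detail band, the Laplacian
#' pyramid is collapsed, and any mirror padding is cropped.
#'
#' @param coeffs a `contourlet_coeffs` object (subbands may have been
#'   modified, e.g. by [ad_filter()]).
#' @return the reconstructed image on the original grid.
#' @export
contourlet_reconstruct <- function(coeffs) {
  stopifnot(inherits(coeffs, "contourlet_coeffs"))
  if (length(coeffs$bandpass) != coeffs$levels)
    stop("inconsistent contourlet coefficients: wrong number of scales",
         call. = FALSE)
  details <- lapply(seq_len(coeffs$levels), function(j) {
    sb <- coeffs$bandpass[[j]]
    if (length(sb) != 2^coeffs$dfb_levels[j])
      stop(sprintf("scale %d: expected %d directional subbands, got %d",
                   j, 2^coeffs$dfb_levels[j], length(sb)), call. = FALSE)
    dfb_reconstruct(sb)
  })
  out <- lp_reconstruct(coeffs$lowpass, details)
  out[seq_len(coeffs$dim[1]), seq_len(coeffs$dim[2]), drop = FALSE]
}

#' @export
print.contourlet_coeffs <- function(x, ...) {
  cat(sprintf("<contourlet_coeffs> %dx%d image, J=%d, DFB levels (%s), %d subbands\n",
              x$dim[1], x$dim[2], x$levels,
              paste(x$dfb_levels, collapse = ","),
              sum(2^x$dfb_levels)))
  invisible(x)
}

#' Dump contourlet coefficients for inspection
#'
#' Writes each subband as a normalized PNG plus a JSON manifest (levels,
#' directional levels, padding, shapes) into a directory.
#'
#' @param coeffs a `contourlet_coeffs` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
dump_coeffs <- function(coeffs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm01 <- function(m) {
    rg <- range(m)
    if (diff(rg) == 0) matrix(0, nrow(m), ncol(m)) else (m - rg[1]) / diff(rg)
  }
  png::writePNG(norm01(coeffs$lowpass), file.path(dir, "lowpass.png"))
  shapes <- list(lowpass = dim(coeffs$lowpass))
  for (j in seq_len(coeffs$levels)) {
    for (k in seq_along(coeffs$bandpass[[j]])) {
      nm <- sprintf("band_j%d_k%d", j, k - 1L)
      png::writePNG(norm01(coeffs$bandpass[[j]][[k]]),
                    file.path(dir, paste0(nm, ".png")))
      shapes[[nm]] <- dim(coeffs$bandpass[[j]][[k]])
    }
  }
  jsonlite::write_json(
    list(levels = coeffs$levels, dfb_levels = coeffs$dfb_levels,
         dim = coeffs$dim, pad = coeffs$pad, shapes = shapes),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
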