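# Shared synthetic fixtures, built in code at test time.

# Binary disk image (0/1) on an n x n grid, 0-based center coordinates.
disk_image <- function(n, xc, yc, r, lo = 0, hi = 1) {
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  Y <- matrix(0:(n - 1), n, n)
  ifelse((X - xc)^2 + (Y - yc)^2 <= r^2, hi, lo)
}

# One-pixel-wide ideal ring mask (edge pixels at distance ~r from center).
ring_mask <- function(n, xc, yc, r) {
  th <- seq(0, 2 * pi, length.out = ceiling(4 * pi * r))
  px <- round(xc + r * cos(th)); py <- round(yc + r * sin(th))
  ok <- px >= 0 & px < n & py >= 0 & py < n
  mask <- matrix(FALSE, n, n)
  mask[cbind(py[ok] + 1, px[ok] + 1)] <- TRUE
  mask
}

as_edge_map <- function(mask) {
  structure(list(mask = mask, mag = mask * 1.0,
                 gx = mask * 0, gy = mask * 0), class = "edge_map")
}

# Small, fast phantom (192 px frame, same vessel scale as the default).
small_spec <- function(seed = 1L, speckle_scale = 1.0, ...) {
  phantom_spec(image_size = 192L, seed = seed, speckle_scale = speckle_scale,
               ...)
}

# Signed distance field of a circle on an n x n grid (0-based center).
sdf_circle <- function(n, xc, yc, r) {
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  Y <- matrix(0:(n - 1), n, n)
  sqrt((X - xc)^2 + (Y - yc)^2) - r
}
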