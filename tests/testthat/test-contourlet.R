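# Contourlet transform: pyramid, directional bank, perfect reconstruction.

test_that("Laplacian pyramid halves resolution and reconstructs exactly", {
  set.seed(101)
  x <- matrix(rnorm(64 * 64), 64)
  p <- lp_decompose(x, 3)
  expect_equal(dim(p$lowpass[[3]]), c(8, 8))
  expect_equal(length(p$detail), 3L)
  xr <- lp_reconstruct(p$lowpass[[3]], p$detail)
  expect_lt(max(abs(xr - x)), 1e-6)

  # constant image: low-pass carries the constant, detail vanishes
  cst <- lp_decompose(matrix(5, 32, 32), 2)
  expect_equal(range(cst$lowpass[[2]]), c(5, 5), tolerance = 1e-12)
  expect_lt(max(abs(cst$detail[[1]])), 1e-8)
  expect_lt(max(abs(cst$detail[[2]])), 1e-8)
})

test_that("LP analysis of an impulse matches a direct-convolution oracle", {
  x <- matrix(0, 32, 32)
  x[17, 17] <- 1
  p <- lp_decompose(x, 1)
  o <- naive_lp_once(x)
  expect_lt(max(abs(p$lowpass[[1]] - o$a)), 1e-12)
  expect_lt(max(abs(p$detail[[1]] - o$b)), 1e-12)
})

test_that("LP rejects images too small for the requested depth", {
  expect_error(lp_decompose(matrix(0, 16, 16), 2), "too small")
  expect_error(lp_reconstruct(matrix(0, 8, 8), list(matrix(0, 20, 20))),
               "mismatch")
})

test_that("DFB splits into 2^l directional subbands and reconstructs", {
  set.seed(102)
  x <- matrix(rnorm(48 * 48), 48)
  for (l in 1:3) {
    sb <- dfb_decompose(x, l)
    expect_length(sb, 2^l)
    expect_lt(max(abs(dfb_reconstruct(sb) - x)), 1e-6)
  }
  # linearity: reconstruction of single subbands sums to the full one
  sb <- dfb_decompose(x, 2)
  parts <- lapply(seq_along(sb), function(k) {
    z <- lapply(sb, function(s) s * 0); z[[k]] <- sb[[k]]
    dfb_reconstruct(z)
  })
  expect_lt(max(abs(Reduce(`+`, parts) - x)), 1e-10)
  # all-zero subbands reconstruct to zero
  expect_equal(dfb_reconstruct(lapply(sb, function(s) s * 0)),
               matrix(0, 48, 48))
})

test_that("a horizontal grating concentrates in the vertical-frequency wedge", {
  n <- 64
  x <- matrix(sin(2 * pi * 6 * (0:(n - 1)) / n), n, n)  # varies along rows
  sb <- dfb_decompose(x, 2)
  energies <- vapply(sb, function(s) sum(s^2), numeric(1))
  # oracle: locate the vertical-frequency axis wedge from the 2D FFT
  Fh <- abs(stats::fft(x))^2
  k <- ivusseg:::dfb_wedge_index(n, n, 2)
  oracle_energy <- vapply(0:3, function(kk) sum(Fh[k == kk]), numeric(1))
  expect_equal(which.max(energies), which.max(oracle_energy))
  expect_gt(max(energies) / sum(energies), 0.8)
})

test_that("contourlet analysis has the advertised layout and inverts", {
  set.seed(103)
  x <- matrix(rnorm(96 * 96), 96)
  co <- contourlet_decompose(x, 3, c(2, 2, 3))
  expect_equal(lengths(co$bandpass), c(4L, 4L, 8L))
  expect_equal(sum(lengths(co$bandpass)), 16L)
  expect_lt(max(abs(contourlet_reconstruct(co) - x)), 1e-6)

  z <- contourlet_decompose(matrix(0, 64, 64), 2, c(2, 2))
  expect_equal(max(abs(z$lowpass)), 0)
  expect_equal(max(abs(unlist(z$bandpass))), 0)
})

test_that("decomposition is linear coefficient-wise", {
  set.seed(104)
  x <- matrix(rnorm(64 * 64), 64)
  y <- matrix(rnorm(64 * 64), 64)
  a <- 2.5; b <- -1.25
  cxy <- contourlet_decompose(a * x + b * y, 2, c(1, 2))
  cx <- contourlet_decompose(x, 2, c(1, 2))
  cy <- contourlet_decompose(y, 2, c(1, 2))
  expect_lt(max(abs(cxy$lowpass - (a * cx$lowpass + b * cy$lowpass))), 1e-9)
  for (j in 1:2) for (k in seq_along(cxy$bandpass[[j]]))
    expect_lt(max(abs(cxy$bandpass[[j]][[k]] -
                        (a * cx$bandpass[[j]][[k]] + b * cy$bandpass[[j]][[k]]))),
              1e-9)
})

test_that("odd-sized inputs are mirror-padded, recorded, and cropped back", {
  set.seed(105)
  x <- matrix(rnorm(100 * 85), 100, 85)
  co <- contourlet_decompose(x, 2, c(2, 2))
  expect_equal(co$pad, c(0, 3))
  expect_equal(dim(contourlet_reconstruct(co)), c(100L, 85L))
  expect_lt(max(abs(contourlet_reconstruct(co) - x)), 1e-6)
})
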