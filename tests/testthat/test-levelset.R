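# Level-set machinery: regularized delta/Heaviside, edge indicator, the
# discrete evolution step, and contour extraction.

test_that("regularized Dirac and Heaviside satisfy their closed forms", {
  a <- 1.5
  expect_equal(dirac_reg(0, a), 1 / a)
  expect_equal(dirac_reg(c(-a, a), a), c(0, 0))
  expect_equal(dirac_reg(2 * a, a), 0)
  expect_equal(heaviside_reg(0, a), 0.5)
  expect_equal(heaviside_reg(c(-2 * a, 2 * a), a), c(0, 1))

  # quadrature: delta integrates to one, and is the derivative of H
  s <- seq(-a, a, length.out = 1e4 + 1)
  d <- dirac_reg(s, a)
  int <- sum((d[-1] + d[-length(d)]) / 2) * (s[2] - s[1])
  expect_equal(int, 1, tolerance = 1e-6)
  h <- heaviside_reg(s, a)
  dh <- diff(h) / diff(s)
  expect_equal(dh, dirac_reg((s[-1] + s[-length(s)]) / 2, a),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("edge indicator is one on constants and matches the formula", {
  expect_equal(edge_indicator(matrix(2, 16, 16), 1.5),
               matrix(1, 16, 16))

  # direct evaluation on a small instance
  set.seed(301)
  x <- matrix(rnorm(5 * 5, sd = 3), 5)
  sig <- 0.8
  sm <- naive_filter2(x, local({
    half <- max(1, ceiling(3 * sig)); k <- exp(-((-half):half)^2 / (2 * sig^2))
    k / sum(k)
  }))
  cl <- function(i, k) min(max(i, 1), k)
  g_oracle <- matrix(0, 5, 5)
  for (j in 1:5) for (i in 1:5) {
    gx <- (sm[i, cl(j + 1, 5)] - sm[i, cl(j - 1, 5)]) / 2
    gy <- (sm[cl(i + 1, 5), j] - sm[cl(i - 1, 5), j]) / 2
    g_oracle[i, j] <- 1 / (1 + gx^2 + gy^2)
  }
  expect_equal(edge_indicator(x, sig), g_oracle, tolerance = 1e-12)

  # a strong step edge drives g below 1/2 on the edge line
  step <- matrix(rep(c(0, 8), each = 16 * 8), 16, 16)
  g <- edge_indicator(step, 1.0)
  expect_lt(min(g[, 8:9]), 0.5)
  expect_true(all(g > 0 & g <= 1))
})

test_that("binary initialization encodes the region with +/-C", {
  mask <- disk_image(32, 15.5, 15.5, 8) > 0
  f <- init_phi(mask, C = 4)
  expect_equal(sort(unique(as.vector(f$phi))), c(-4, 4))
  expect_true(all(f$phi[mask] == -4) && all(f$phi[!mask] == 4))
  # the zero level set of phi0 traces the mask boundary within a pixel
  ctr <- zero_contour(f$phi)
  r <- sqrt((ctr$x - 15.5)^2 + (ctr$y - 15.5)^2)
  expect_lt(max(abs(r - 8)), 1.2)
  expect_error(init_phi(matrix(FALSE, 8, 8), 4), "non-empty")
  expect_error(init_phi(matrix(TRUE, 8, 8), 4), "non-empty")
})

test_that("one evolution step reproduces a direct evaluation of the flow", {
  set.seed(302)
  for (rep in 1:5) {
    phi <- matrix(rnorm(16 * 16, sd = 3), 16)
    g <- matrix(runif(16 * 16, 0.05, 1), 16)
    p <- levelset_params(mu = 0.04, lam = 5, nu = c(-1.5, 1.5)[rep %% 2 + 1],
                         alpha = 1.5, dt = 5)
    f <- structure(list(phi = phi, iteration = 0L), class = "levelset_field")
    got <- evolve_step(f, g, p)$phi
    want <- oracle_evolve_step(phi, g, p$mu, p$lam, p$nu, p$alpha, p$dt)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("a signed-distance field with neutral forces is near-stationary", {
  phi <- sdf_circle(96, 47.5, 47.5, 24)
  g1 <- matrix(1, 96, 96)
  p <- levelset_params(mu = 0.04, lam = 1e-9, nu = 0, dt = 5)
  f <- structure(list(phi = phi, iteration = 0L), class = "levelset_field")
  stepped <- evolve_step(f, g1, p)$phi
  # measure in a band around the contour, away from the center singularity
  # of the distance function (where the penalty residual is O(1/r^3))
  band <- abs(phi) < 10
  expect_lt(max(abs(stepped - phi)[band]), 1e-3 * p$dt * p$mu)
})

test_that("the balloon sign controls monotone area change", {
  g1 <- matrix(1, 48, 48)
  mask <- disk_image(48, 23.5, 23.5, 8) > 0
  area <- function(phi) sum(phi < 0)
  for (nu in c(-1.5, 1.5)) {
    p <- levelset_params(mu = 0.04, lam = 1e-9, nu = nu, dt = 5,
                         max_iter = 50, refine_iter = 0, tol = 1e-12)
    f <- init_phi(mask, 4)
    areas <- numeric(10)
    for (k in 1:10) {
      for (i in 1:5) f <- evolve_step(f, g1, p)
      areas[k] <- area(f$phi)
    }
    if (nu < 0) expect_true(all(diff(areas) >= 0) && areas[10] > areas[1])
    else expect_true(all(diff(areas) <= 0) && areas[10] < areas[1])
  }
})

test_that("zero level set extraction is subpixel-accurate", {
  phi <- sdf_circle(96, 47.25, 46.75, 20)
  ctr <- zero_contour(phi)
  ref <- circle_contour(47.25, 46.75, 20, 3600)
  expect_lt(md_rmd(ctr, ref)$MD, 0.5)
})

test_that("segmentation of a sharp phantom from a perturbed start recovers truth", {
  ph <- generate_phantom(small_spec(seed = 33, speckle_scale = 0))
  img <- ph$image * 255
  # initialization = truth
  res0 <- segment(img, ph$lumen_truth, ph$media_truth)
  expect_lt(md_rmd(res0$lumen, ph$lumen_truth)$MD, 1)
  expect_lt(md_rmd(res0$media, ph$media_truth)$MD, 1)

  # initial circles perturbed outward by ~3 px
  cen <- ph$spec$center
  lc <- cen + ph$spec$lumen_offset
  res1 <- segment(img,
                  circle_contour(lc[1], lc[2], ph$spec$lumen_radius + 3),
                  circle_contour(cen[1], cen[2], ph$spec$media_radius + 3))
  expect_lt(md_rmd(res1$lumen, ph$lumen_truth)$MD, 1.5)
  expect_lt(md_rmd(res1$media, ph$media_truth)$MD, 1.5)
  expect_true(all(points_in_contour(res1$lumen$x, res1$lumen$y, res1$media)))
})

test_that("segment rejects an initial lumen outside the media contour", {
  img <- matrix(0.5, 64, 64)
  expect_error(
    segment(img, circle_contour(32, 32, 20), circle_contour(32, 32, 10)),
    "inside")
})
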