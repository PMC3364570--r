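# Canny edge maps, circular Hough transform, circle selection and the
# multiresolution initializer.

test_that("Canny traces an ideal disk boundary as a thin ring", {
  img <- disk_image(128, 63.5, 63.5, 30, lo = 0.1, hi = 0.9)
  em <- edge_map(img, 0.1, 0.3, 1.5)
  ep <- which(em$mask, arr.ind = TRUE)
  expect_gt(nrow(ep), 60)
  r <- sqrt((ep[, 2] - 1 - 63.5)^2 + (ep[, 1] - 1 - 63.5)^2)
  expect_lt(mean(abs(r - 30)), 1)
  expect_true(all(abs(r - 30) < 3))
})

test_that("Canny on a constant image warns and returns no edges", {
  expect_warning(em <- edge_map(matrix(1, 32, 32)), "constant")
  expect_false(any(em$mask))
  expect_error(cht_accumulate(em, init_constraints(5, 10, 5)), "no edges")
})

test_that("the disk boundary survives moderate additive noise", {
  set.seed(501)
  img <- disk_image(128, 63.5, 63.5, 30, lo = 0.1, hi = 0.9) +
    matrix(rnorm(128 * 128, sd = 0.05), 128)
  em <- edge_map(img, 0.1, 0.3, 1.5)
  ep <- which(em$mask, arr.ind = TRUE)
  r <- sqrt((ep[, 2] - 1 - 63.5)^2 + (ep[, 1] - 1 - 63.5)^2)
  # the ring remains the dominant edge structure
  expect_gt(mean(abs(r - 30) < 2), 0.6)
})

test_that("the accumulator peaks at the true circle parameters", {
  em <- as_edge_map(ring_mask(128, 50, 50, 30))
  acc <- cht_accumulate(em, init_constraints(15, 40, 25))
  peak <- cht_peaks(acc)[1, ]
  expect_equal(c(peak$x_c, peak$y_c, peak$r), c(50, 50, 30), tolerance = 1e-9)

  # two concentric rings give two local maxima at the same center
  em2 <- as_edge_map(ring_mask(128, 60, 64, 20) | ring_mask(128, 60, 64, 35))
  pk2 <- cht_peaks(cht_accumulate(em2, init_constraints(15, 40, 25)))
  rs <- sort(pk2$r[pk2$x_c == 60 & pk2$y_c == 64])
  expect_true(all(c(20, 35) %in% rs))
})

test_that("a quarter-occluded ring is still recovered exactly", {
  # 25% of the arc removed, as a guide-wire shadow surrogate
  th <- seq(0, 1.5 * pi, length.out = 400)
  mask <- matrix(FALSE, 64, 64)
  px <- round(31 + 14 * cos(th)); py <- round(33 + 14 * sin(th))
  mask[cbind(py + 1, px + 1)] <- TRUE
  acc <- cht_accumulate(as_edge_map(mask), init_constraints(10, 20, 10))
  peak <- cht_peaks(acc)[1, ]
  oracle <- oracle_cht_best(mask, 25:37, 27:39, 10:20)
  expect_equal(unname(oracle$param), c(31, 33, 14))
  expect_lt(max(abs(c(peak$x_c, peak$y_c, peak$r) - oracle$param)), 1)
})

test_that("lumen circle selection follows distance, score, then radius", {
  cand <- data.frame(x_c = c(50, 80), y_c = c(50, 80), r = c(20, 25),
                     score = c(90, 95))
  sel <- select_lumen_circle(cand, c(52, 49))
  expect_equal(c(sel$x_c, sel$y_c, sel$r), c(50, 50, 20))
  # single candidate
  expect_equal(select_lumen_circle(cand[2, ], c(0, 0))$r, 25)
  # equidistant candidates: higher score wins
  tie <- data.frame(x_c = c(40, 60), y_c = c(50, 50), r = c(18, 22),
                    score = c(40, 70))
  expect_equal(select_lumen_circle(tie, c(50, 50))$score, 70)
  # equal score too: smaller radius wins
  tie2 <- data.frame(x_c = c(40, 60), y_c = c(50, 50), r = c(22, 18),
                     score = c(40, 40))
  expect_equal(select_lumen_circle(tie2, c(50, 50))$r, 18)
  expect_error(select_lumen_circle(tie[0, ], c(0, 0)), "no lumen")
})

test_that("media selection respects constraints and boundary strength", {
  lum <- data.frame(x_c = 50, y_c = 50, r = 18, score = 50)
  # all candidates farther than D_c: constraint error
  far <- data.frame(x_c = 90, y_c = 90, r = 30, score = 99)
  expect_error(select_media_circle(far, lum, init_constraints(15, 40, 10)),
               "widen")
  # candidates must be larger than the lumen
  small <- data.frame(x_c = 50, y_c = 50, r = 15, score = 99)
  expect_error(select_media_circle(small, lum, init_constraints(10, 40, 10)),
               "widen")
  # between two admissible concentric candidates, the one with the stronger
  # boundary gradient wins
  img <- disk_image(200, 99.5, 99.5, 55, lo = 0.2, hi = 0.2)
  img[disk_image(200, 99.5, 99.5, 55) > 0] <- 0.8   # strong edge at r=55
  img[disk_image(200, 99.5, 99.5, 90) > 0 &
        disk_image(200, 99.5, 99.5, 55) == 0] <- 0.25  # faint edge at r=90
  em <- edge_map(img, 0.05, 0.1, 1.0)
  cand <- data.frame(x_c = c(99.5, 99.5), y_c = c(99.5, 99.5), r = c(55, 90),
                     score = c(60, 60))
  lum2 <- data.frame(x_c = 99.5, y_c = 99.5, r = 20, score = 10)
  sel <- select_media_circle(cand, lum2, init_constraints(15, 95, 25), em$mag)
  expect_equal(sel$r, 55)
})

test_that("lumen center estimation lands in the blood pool", {
  ph <- generate_phantom(phantom_spec(seed = 61))
  est <- estimate_lumen_center(ph$image, exclude_radius = 12,
                               search_radius = 42)
  lc <- ph$spec$center + ph$spec$lumen_offset
  expect_lt(sqrt((est$x - lc[1])^2 + (est$y - lc[2])^2), 5)

  # off-center lumen
  ph2 <- generate_phantom(phantom_spec(seed = 62, lumen_offset = c(6, -4)))
  est2 <- estimate_lumen_center(ph2$image, exclude_radius = 12,
                                search_radius = 42)
  lc2 <- ph2$spec$center + c(6, -4)
  expect_lt(sqrt((est2$x - lc2[1])^2 + (est2$y - lc2[2])^2), 10)

  # degenerate input falls back to the frame center with low confidence
  flat <- estimate_lumen_center(matrix(0.4, 64, 64))
  expect_equal(c(flat$x, flat$y), c(31.5, 31.5))
  expect_equal(flat$confidence, "low")
})

test_that("multiresolution initialization recovers clean-phantom circles", {
  # truly circular interfaces: recovery within the accumulator resolution
  none <- list(amp = numeric(0), phase = numeric(0))
  ph <- generate_phantom(phantom_spec(seed = 63, speckle_scale = 0,
                                      lumen_harmonics = none,
                                      media_harmonics = none))
  co <- contourlet_decompose(ph$image, 3, c(2, 2, 3))
  init <- suppressWarnings(multiresolution_initialize(co))
  lc <- ph$spec$center + ph$spec$lumen_offset
  expect_lt(sqrt((init$lumen_circle$x_c - lc[1])^2 +
                   (init$lumen_circle$y_c - lc[2])^2), 2)
  expect_lt(abs(init$lumen_circle$r - ph$spec$lumen_radius), 2)
  expect_lt(sqrt((init$media_circle$x_c - ph$spec$center[1])^2 +
                   (init$media_circle$y_c - ph$spec$center[2])^2), 2)
  expect_lte(abs(init$media_circle$r - ph$spec$media_radius), 2)

  # eccentric interfaces: the fitted circle still tracks the boundary
  ph2 <- generate_phantom(phantom_spec(seed = 63, speckle_scale = 0))
  co2 <- contourlet_decompose(ph2$image, 3, c(2, 2, 3))
  init2 <- suppressWarnings(multiresolution_initialize(co2))
  expect_lt(md_rmd(init2$lumen, ph2$lumen_truth)$MD, 3)
  expect_lt(md_rmd(init2$media, ph2$media_truth)$MD, 3)
})

test_that("initialization stays within 5 px under default speckle", {
  for (seed in c(64, 65)) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    co <- contourlet_decompose(ph$image, 3, c(2, 2, 3))
    init <- suppressWarnings(multiresolution_initialize(co))
    lc <- ph$spec$center + ph$spec$lumen_offset
    expect_lt(sqrt((init$lumen_circle$x_c - lc[1])^2 +
                     (init$lumen_circle$y_c - lc[2])^2), 5)
    expect_lt(abs(init$lumen_circle$r - ph$spec$lumen_radius), 5)
    expect_lt(abs(init$media_circle$r - ph$spec$media_radius), 5)
    # the returned pair always nests
    lum <- init$lumen
    expect_true(all(points_in_contour(lum$x, lum$y, init$media)))
  }
})
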