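# Polar-domain IVUS phantom simulator.

test_that("a fixed seed reproduces the phantom bitwise", {
  a <- generate_phantom(small_spec(seed = 5))
  b <- generate_phantom(small_spec(seed = 5))
  expect_identical(a$image, b$image)
  expect_identical(a$lumen_truth, b$lumen_truth)
  c <- generate_phantom(small_spec(seed = 6))
  expect_false(identical(a$image, c$image))
})

test_that("the noise-free limit is piecewise constant with exact lumen value", {
  # speckle off and ring-down off: inside the lumen (outside the guide-wire
  # sector) the image equals the lumen echogenicity exactly
  ph <- generate_phantom(small_spec(seed = 7, speckle_scale = 0,
                                    ringdown_amp = 0))
  spec <- ph$spec
  cen <- spec$center + spec$lumen_offset
  probe_r <- (spec$catheter_radius + spec$lumen_radius * 0.8) / 2
  th <- seq(0.1, 2 * pi, length.out = 12)
  th <- th[abs(((th - spec$wire_angle + pi) %% (2 * pi)) - pi) >
             spec$wire_width]
  px <- round(cen[1] + probe_r * cos(th)); py <- round(cen[2] + probe_r * sin(th))
  vals <- ph$image[cbind(py + 1, px + 1)]
  expect_equal(vals, rep(unname(spec$echogenicity[["lumen"]]), length(vals)),
               tolerance = 1e-9)
  # adventitia far field is exactly the adventitia echogenicity
  expect_equal(unname(ph$image[5, 96]),
               unname(spec$echogenicity[["adventitia"]]), tolerance = 1e-9)
})

test_that("ground-truth containment holds across a jittered batch", {
  phs <- phantom_batch(8, small_spec(), seed = 3)
  for (ph in phs) {
    expect_true(all(points_in_contour(ph$lumen_truth$x, ph$lumen_truth$y,
                                      ph$media_truth)))
    gap <- sapply(seq_len(nrow(ph$lumen_truth)), function(i)
      point_to_contour_distance(c(ph$lumen_truth$x[i], ph$lumen_truth$y[i]),
                                ph$media_truth)$D)
    expect_gt(min(gap), 4)
  }
})

test_that("polar-domain speckle in a homogeneous layer is Rayleigh", {
  ph <- generate_phantom(phantom_spec(seed = 11))
  raw <- ph$polar$raw
  layer <- ph$polar$layer
  adv <- ph$spec$echogenicity[["adventitia"]]
  v <- raw[layer == adv]
  set.seed(99)
  v <- sample(v, 5000)
  scale <- adv * sqrt(2 / pi)
  ks <- suppressWarnings(
    stats::ks.test(v, function(q) 1 - exp(-q^2 / (2 * scale^2))))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("batches are reproducible and span the jitter range", {
  b1 <- phantom_batch(20, small_spec(), seed = 4)
  b2 <- phantom_batch(20, small_spec(), seed = 4)
  expect_identical(lapply(b1, `[[`, "image"), lapply(b2, `[[`, "image"))
  expect_length(b1, 20)
  lr <- vapply(b1, function(p) p$spec$lumen_radius, numeric(1))
  mr <- vapply(b1, function(p) p$spec$media_radius, numeric(1))
  expect_gt(max(lr) - min(lr), 1.5)     # jitter half-width is 2 px
  expect_gt(max(mr) - min(mr), 1.5)
  expect_true(all(lr >= 14 & lr <= 18 & mr >= 34 & mr <= 38))
})

test_that("invalid geometry is rejected before synthesis", {
  expect_error(phantom_spec(lumen_radius = 33, media_radius = 36), "gap")
  expect_error(phantom_spec(media_radius = 200), "frame edge")
  expect_error(phantom_spec(catheter_radius = 20), "catheter")
})
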