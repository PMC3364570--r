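# MD / RMD contour metrics.

test_that("point-to-contour distance is exact segment-wise geometry", {
  sq <- as_contour(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  d <- point_to_contour_distance(c(2, 0.5), sq)
  expect_equal(d$D, 1)
  expect_equal(unname(d$q), c(1, 0.5))
  # a point on the contour has zero distance
  expect_equal(point_to_contour_distance(c(0.5, 0), sq)$D, 0)
  # a dense circle polygon behaves like the analytic circle
  circ <- circle_contour(10, -4, 25, 3600)
  set.seed(401)
  for (i in 1:20) {
    p <- c(runif(1, -40, 60), runif(1, -50, 40))
    expect_equal(point_to_contour_distance(p, circ)$D,
                 abs(sqrt(sum((p - c(10, -4))^2)) - 25), tolerance = 1e-3)
  }
  expect_error(point_to_contour_distance(c(0, 0), structure(
    data.frame(x = 1, y = 1), class = c("ivus_contour", "data.frame"))),
    "at least 3")
})

test_that("concentric circles give the closed-form MD and RMD", {
  ref <- circle_contour(100, 100, 50, 3600)
  det <- circle_contour(100, 100, 55, 3600)
  cmp <- md_rmd(det, ref)
  expect_equal(cmp$MD, 5, tolerance = 1e-4)
  expect_equal(cmp$RMD, 10, tolerance = 1e-4)
  # identical contours
  self <- md_rmd(ref, ref)
  expect_equal(self$MD, 0, tolerance = 1e-9)
  expect_equal(self$RMD, 0, tolerance = 1e-9)
})

test_that("a shifted circle matches a dense numeric oracle", {
  ref <- circle_contour(0, 0, 50, 3600)
  det <- circle_contour(3, 4, 50, 720)
  cmp <- md_rmd(det, ref)
  oracle <- mean(oracle_min_dist(det$x, det$y, ref$x, ref$y))
  expect_equal(cmp$MD, oracle, tolerance = 0.01 * oracle)
  # for a small shift d, MD approaches (2/pi) * |d|
  expect_equal(cmp$MD, 2 * 5 / pi, tolerance = 0.1)
})

test_that("MD scales with the contours and RMD does not", {
  set.seed(402)
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  ref <- as_contour(data.frame(x = 30 * (1 + 0.1 * cos(3 * th)) * cos(th),
                               y = 30 * (1 + 0.1 * cos(3 * th)) * sin(th)))
  det <- as_contour(data.frame(x = 34 * cos(th + 0.01), y = 34 * sin(th + 0.01)))
  base <- md_rmd(det, ref)
  for (s in c(0.5, 2, 10)) {
    scl <- md_rmd(as_contour(data.frame(x = det$x * s, y = det$y * s)),
                  as_contour(data.frame(x = ref$x * s, y = ref$y * s)))
    expect_equal(scl$MD, s * base$MD, tolerance = 1e-9)
    expect_equal(scl$RMD, base$RMD, tolerance = 1e-9)
  }
  # common translation leaves MD unchanged
  tr <- md_rmd(as_contour(data.frame(x = det$x + 17, y = det$y - 8)),
               as_contour(data.frame(x = ref$x + 17, y = ref$y - 8)))
  expect_equal(tr$MD, base$MD, tolerance = 1e-9)
})

test_that("MD is stable under vertex-density refinement", {
  th1 <- seq(0, 2 * pi, length.out = 181)[-181]
  th2 <- seq(0, 2 * pi, length.out = 361)[-361]
  ref <- circle_contour(0, 0, 40, 720)
  d1 <- md_rmd(as_contour(data.frame(x = 44 * cos(th1), y = 44 * sin(th1))), ref)
  d2 <- md_rmd(as_contour(data.frame(x = 44 * cos(th2), y = 44 * sin(th2))), ref)
  expect_lt(abs(d1$MD - d2$MD) / d1$MD, 0.01)
})

test_that("symmetric distance averages both directions", {
  a <- circle_contour(0, 0, 50, 720)
  b <- circle_contour(0, 0, 54, 720)
  expect_equal(mean_symmetric_distance(a, b), 4, tolerance = 1e-3)
})
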