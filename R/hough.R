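# Initial contour extraction: Canny edge maps and a circular Hough transform
# (CHT) applied coarse-to-fine on the contourlet low-pass bands.  Both the
# lumen and the media-adventitia border are initialized as circles; radii and
# center constraints are expressed in full-resolution pixels and rescaled per
# pyramid level.

#' Constraints for the circle search
#'
#' @param r_min,r_max radius search range in full-resolution pixels.
#' @param D_c maximum distance between the media-adventitia circle center and
#'   the lumen center (pixels).
#' @return an object of class `init_constraints`.
#' @export
init_constraints <- function(r_min = 15, r_max = 40, D_c = 25) {
  stopifnot(r_min > 0, r_max > r_min, D_c >= 0)
  structure(list(r_min = r_min, r_max = r_max, D_c = D_c),
            class = "init_constraints")
}

#' Canny edge detection
#'
#' Standard Canny pipeline: Gaussian smoothing, central-difference gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' hysteresis thresholding (thresholds are fractions of the maximum gradient
#' magnitude; weak edges are kept only in connected components that contain a
#' strong edge).
#'
#' @param image numeric matrix.
#' @param low_thr,high_thr hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, `0 <= low_thr < high_thr`.
#' @param sigma Gaussian smoothing sigma (pixels).
#' @return an object of class `edge_map`: list with `mask` (logical matrix),
#'   `mag`, `gx`, `gy` (gradient magnitude and components).
#' @export
edge_map <- function(image, low_thr = 0.1, high_thr = 0.3, sigma = 1.5) {
  check_image(image)
  stopifnot(low_thr >= 0, low_thr < high_thr)
  sm <- gauss_smooth(image, sigma)
  g <- grad_central(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  # reference gradient for the relative thresholds: a high quantile rather
  # than the absolute maximum, which a single dominant artifact edge (the
  # ring-down halo) would otherwise dictate
  mx <- if (any(mag > 0)) as.numeric(stats::quantile(mag[mag > 0], 0.99)) else 0
  if (mx <= 0) {
    warning("constant image: empty edge map")
    return(structure(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                          mag = mag, gx = g$gx, gy = g$gy),
                     class = "edge_map"))
  }
  n <- nrow(mag); m <- ncol(mag)
  # quantize gradient orientation into 4 sectors and compare the two
  # neighbours along the gradient
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- (floor((ang + pi / 8) / (pi / 4)) %% 4)  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  shift <- function(M, dr, dc) {
    M[clamp_idx(seq_len(n) + dr, n), clamp_idx(seq_len(m) + dc, m), drop = FALSE]
  }
  n1 <- matrix(0, n, m); n2 <- matrix(0, n, m)
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    o <- offs[[as.character(s)]]
    sel <- sector == s
    a <- shift(mag, o[1], o[2]); b <- shift(mag, -o[1], -o[2])
    n1[sel] <- a[sel]; n2[sel] <- b[sel]
  }
  nms <- mag >= n1 & mag >= n2
  strong <- nms & (mag >= high_thr * mx)
  weak <- nms & (mag >= low_thr * mx)
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  mask <- weak & (matrix(lab %in% keep, n, m))
  structure(list(mask = mask, mag = mag, gx = g$gx, gy = g$gy),
            class = "edge_map")
}

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

# Unique integer perimeter offsets of a circle of radius r.
circle_offsets <- function(r) {
  k <- max(16L, ceiling(4 * pi * r))
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  o <- unique(cbind(round(r * cos(th)), round(r * sin(th))))
  o
}

#' Circular Hough transform accumulator
#'
#' For every edge pixel and every integer radius in `[r_min, r_max]`, votes
#' are cast for all centers at that distance (equivalently, a circle of
#' radius r is drawn around each edge point and every cell its perimeter
#' crosses is incremented).
#'
#' @param edges an [edge_map()].
#' @param constraints an [init_constraints()]; radii are used as given
#'   (rescale them before calling on a coarse band).
#' @return an object of class `cht_accumulator`: list with `votes` (3D
#'   integer array `[nrow, ncol, radius]`) and `radii`.
#' @export
cht_accumulate <- function(edges, constraints) {
  stopifnot(inherits(edges, "edge_map"), inherits(constraints, "init_constraints"))
  if (!any(edges$mask)) stop("no edges to vote", call. = FALSE)
  n <- nrow(edges$mask); m <- ncol(edges$mask)
  radii <- seq(max(1L, round(constraints$r_min)), round(constraints$r_max))
  ep <- which(edges$mask, arr.ind = TRUE)  # (row, col)
  votes <- array(0L, c(n, m, length(radii)))
  for (i in seq_along(radii)) {
    off <- circle_offsets(radii[i])
    cr <- rep(ep[, 1], each = nrow(off)) + rep(off[, 2], times = nrow(ep))
    cc <- rep(ep[, 2], each = nrow(off)) + rep(off[, 1], times = nrow(ep))
    ok <- cr >= 1L & cr <= n & cc >= 1L & cc <= m
    idx <- cr[ok] + (cc[ok] - 1L) * n
    votes[, , i] <- votes[, , i] + tabulate(idx, nbins = n * m)
  }
  structure(list(votes = votes, radii = radii, dim = c(n, m)),
            class = "cht_accumulator")
}

# 3x3x3 box smoothing of the vote array (replicated borders).
smooth_votes <- function(votes) {
  d <- dim(votes)
  out <- array(0, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    out <- out + votes[clamp_idx(seq_len(d[1]) + dy, d[1]),
                       clamp_idx(seq_len(d[2]) + dx, d[2]),
                       clamp_idx(seq_len(d[3]) + dz, d[3]), drop = FALSE]
  }
  out / 27
}

# Smoothed votes normalized by circumference: under uniform edge clutter raw
# votes grow linearly with the radius, which would bias every windowed search
# toward its largest radius; dividing each radius plane by r scores arc
# COVERAGE instead, leaving ideal-circle peaks in place.
scored_votes <- function(acc) {
  sm <- smooth_votes(acc$votes)
  for (i in seq_along(acc$radii)) sm[, , i] <- sm[, , i] / acc$radii[i]
  sm
}

#' Peak candidates from a CHT accumulator
#'
#' Votes are smoothed with a 3x3x3 box; local maxima above `rel_thr` times
#' the global maximum are kept and greedily non-max suppressed within a
#' (5 px, 5 px, 3 radii) neighbourhood.
#'
#' @param acc a [cht_accumulate()] result.
#' @param rel_thr relative vote threshold (default 0.5).
#' @param max_peaks cap on the number of returned candidates.
#' @param nms suppression half-widths `c(y, x, radius)` in accumulator cells;
#'   shrink these when peak-picking on a coarse band.
#' @return data frame of candidate circles: `x_c`, `y_c` (0-based center),
#'   `r`, `score` (smoothed votes), ordered by decreasing score.
#' @export
cht_peaks <- function(acc, rel_thr = 0.5, max_peaks = 25L, nms = c(5, 5, 3)) {
  stopifnot(inherits(acc, "cht_accumulator"))
  sm <- scored_votes(acc)
  thr <- rel_thr * max(sm)
  idx <- which(sm >= thr, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(x_c = numeric(), y_c = numeric(),
                                    r = numeric(), score = numeric()))
  sc <- sm[idx]
  ord <- order(-sc)
  idx <- idx[ord, , drop = FALSE]; sc <- sc[ord]
  taken <- matrix(NA_real_, 0, 3)
  out <- list()
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    if (nrow(taken)) {
      close <- abs(taken[, 1] - p[1]) <= nms[1] & abs(taken[, 2] - p[2]) <= nms[2] &
        abs(taken[, 3] - p[3]) <= nms[3]
      if (any(close)) next
    }
    taken <- rbind(taken, p)
    out[[length(out) + 1L]] <- data.frame(
      x_c = p[2] - 1, y_c = p[1] - 1, r = acc$radii[p[3]], score = sc[i])
    if (length(out) >= max_peaks) break
  }
  do.call(rbind, out)
}

#' Approximate lumen center from a low-pass band
#'
#' The lumen is the dark blood pool around the catheter.  The band is
#' thresholded at its Otsu level; among dark connected components that touch
#' the central third of the frame (excluding a catheter/ring-down disk around
#' the image center), the darkest is selected and its darkness-weighted
#' centroid returned.  Degenerate inputs fall back to the image center with
#' low confidence.
#'
#' @param band numeric matrix (contourlet low-pass band).
#' @param exclude_radius radius (pixels, at the band's scale) of the central
#'   catheter/ring-down zone excluded from the dark mask.
#' @param search_radius outer radius (same scale) of the annulus around the
#'   image center searched for the blood pool; `Inf` searches the central
#'   third of the frame.  The catheter sits at the image center inside the
#'   lumen, so restricting the search keeps radial artifacts (e.g. a
#'   guide-wire shadow running to the frame edge) from dragging the estimate.
#' @return list with `x`, `y` (0-based) and `confidence` (`"high"`/`"low"`).
#' @export
estimate_lumen_center <- function(band, exclude_radius = 0,
                                  search_radius = Inf) {
  check_image(band, arg = "band")
  n <- nrow(band); m <- ncol(band)
  center_fallback <- list(x = (m - 1) / 2, y = (n - 1) / 2, confidence = "low")
  rg <- range(band)
  if (diff(rg) <= 0) return(center_fallback)
  nm <- (band - rg[1]) / diff(rg)
  thr <- EBImage::otsu(EBImage::Image(nm), range = c(0, 1))
  dark <- nm < thr
  cy <- (n - 1) / 2; cx <- (m - 1) / 2
  X <- matrix(0:(m - 1), n, m, byrow = TRUE); Y <- matrix(0:(n - 1), n, m)
  R2 <- (X - cx)^2 + (Y - cy)^2
  if (exclude_radius > 0) dark[R2 <= exclude_radius^2] <- FALSE
  if (is.finite(search_radius)) {
    dark[R2 > search_radius^2] <- FALSE
  } else {
    third <- matrix(FALSE, n, m)
    third[seq.int(floor(n / 3) + 1L, ceiling(2 * n / 3)),
          seq.int(floor(m / 3) + 1L, ceiling(2 * m / 3))] <- TRUE
    dark <- dark & third
  }
  if (!any(dark)) return(center_fallback)
  sel <- which(dark, arr.ind = TRUE)
  w <- pmax(thr - nm[dark], 1e-9)
  list(x = sum((sel[, 2] - 1) * w) / sum(w),
       y = sum((sel[, 1] - 1) * w) / sum(w),
       confidence = "high")
}

#' Select the lumen circle among CHT candidates
#'
#' Picks the candidate whose center is nearest (Euclidean distance) to the
#' approximate lumen center; ties are broken by higher accumulator score,
#' then by smaller radius.
#'
#' @param candidates data frame from [cht_peaks()].
#' @param approx_center list or numeric `c(x, y)`.
#' @return one-row data frame (the selected circle).
#' @export
select_lumen_circle <- function(candidates, approx_center) {
  if (is.list(approx_center) && !is.null(approx_center$x))
    approx_center <- c(approx_center$x, approx_center$y)
  if (is.null(candidates) || !nrow(candidates))
    stop("no lumen circle found", call. = FALSE)
  d <- sqrt((candidates$x_c - approx_center[1])^2 +
            (candidates$y_c - approx_center[2])^2)
  ord <- order(d, -candidates$score, candidates$r)
  candidates[ord[1], , drop = FALSE]
}

# Mean gradient magnitude sampled along a circle (bilinear).
circle_gradient_score <- function(mag, x_c, y_c, r) {
  th <- seq(0, 2 * pi, length.out = max(32L, ceiling(2 * pi * r)) + 1L)[-1]
  bilinear_sample(mag, x_c + r * cos(th), y_c + r * sin(th))
}

# Bilinear interpolation of matrix M at 0-based (x, y); returns mean of
# in-bounds samples.
bilinear_sample <- function(M, x, y) {
  n <- nrow(M); m <- ncol(M)
  ok <- x >= 0 & x <= m - 1 & y >= 0 & y <= n - 1
  if (!any(ok)) return(0)
  x <- x[ok]; y <- y[ok]
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, m - 1); y1 <- pmin(y0 + 1, n - 1)
  fx <- x - x0; fy <- y - y0
  v <- (1 - fx) * (1 - fy) * M[cbind(y0 + 1, x0 + 1)] +
       fx * (1 - fy) * M[cbind(y0 + 1, x1 + 1)] +
       (1 - fx) * fy * M[cbind(y1 + 1, x0 + 1)] +
       fx * fy * M[cbind(y1 + 1, x1 + 1)]
  mean(v)
}

#' Select the media-adventitia circle among CHT candidates
#'
#' Among candidates whose center lies within `D_c` of the lumen center and
#' whose radius exceeds the lumen radius, circles are ranked by an equal
#' weighting of normalized accumulator votes and the mean gradient magnitude
#' along the circle (the "maximum change in intensity"); ties go to the
#' center nearest the lumen center.
#'
#' @param candidates data frame from [cht_peaks()].
#' @param lumen one-row data frame (the selected lumen circle).
#' @param constraints an [init_constraints()] at the band's scale.
#' @param mag gradient magnitude matrix (from [edge_map()]) for the boundary
#'   strength score; `NULL` ranks by votes alone.
#' @return one-row data frame (the selected circle).
#' @export
select_media_circle <- function(candidates, lumen, constraints, mag = NULL) {
  stopifnot(inherits(constraints, "init_constraints"))
  if (is.null(candidates) || !nrow(candidates))
    stop("no media-adventitia candidates; consider widening (r_min, r_max, D_c)",
         call. = FALSE)
  d <- sqrt((candidates$x_c - lumen$x_c)^2 + (candidates$y_c - lumen$y_c)^2)
  keep <- d <= constraints$D_c & candidates$r > lumen$r
  if (!any(keep))
    stop("no candidate circle satisfies the media-adventitia constraints; consider widening (r_min, r_max, D_c)",
         call. = FALSE)
  cand <- candidates[keep, , drop = FALSE]
  dk <- d[keep]
  gsc <- if (is.null(mag)) rep(0, nrow(cand)) else
    vapply(seq_len(nrow(cand)), function(i)
      circle_gradient_score(mag, cand$x_c[i], cand$y_c[i], cand$r[i]),
      numeric(1))
  vn <- cand$score / max(cand$score)
  gn <- if (max(gsc) > 0) gsc / max(gsc) else gsc
  score <- 0.5 * vn + 0.5 * gn
  ord <- order(-score, dk)
  cand[ord[1], , drop = FALSE]
}

# Best circle inside a windowed region of the accumulator: center within
# `win` pixels of (x0, y0) and radius within [r_lo, r_hi].  Returns NULL if
# the window holds no votes.
windowed_best_circle <- function(acc, x0, y0, r_lo, r_hi, win,
                                 mag = NULL, grad_weight = 0) {
  sm <- scored_votes(acc)
  rows <- which(abs(seq_len(acc$dim[1]) - 1 - y0) <= win)
  cols <- which(abs(seq_len(acc$dim[2]) - 1 - x0) <= win)
  rsel <- which(acc$radii >= r_lo & acc$radii <= r_hi)
  if (!length(rows) || !length(cols) || !length(rsel)) return(NULL)
  sub <- sm[rows, cols, rsel, drop = FALSE]
  if (max(sub) <= 0) return(NULL)
  # soft center prior: the window center is a tracked prediction, so distant
  # hypotheses must outvote it substantially; sd = window half-width keeps
  # the prior from locking in a one-cell error made at the coarser level
  pr <- exp(-(outer((rows - 1 - y0)^2, (cols - 1 - x0)^2, "+")) /
              (2 * win^2))
  sub <- sub * array(pr, dim(sub))
  if (grad_weight > 0 && !is.null(mag)) {
    # evaluate gradient score only at the top vote peaks inside the window
    ord <- order(-sub)[seq_len(min(10L, length(sub)))]
    pk <- arrayInd(ord, dim(sub))
    sc <- vapply(seq_len(nrow(pk)), function(i)
      circle_gradient_score(mag, cols[pk[i, 2]] - 1, rows[pk[i, 1]] - 1,
                            acc$radii[rsel[pk[i, 3]]]), numeric(1))
    v <- sub[ord]
    tot <- (1 - grad_weight) * v / max(v) +
      grad_weight * (if (max(sc) > 0) sc / max(sc) else sc)
    b <- pk[which.max(tot), ]
  } else {
    b <- arrayInd(which.max(sub), dim(sub))[1, ]
  }
  data.frame(x_c = cols[b[2]] - 1, y_c = rows[b[1]] - 1,
             r = acc$radii[rsel[b[3]]], score = max(sub))
}

#' Coarse-to-fine circle initialization on contourlet low-pass bands
#'
#' Runs Canny + CHT + circle selection on the coarsest low-pass band `a_J`,
#' then refines both circles level by level: at each finer level the found
#' circles are rescaled (centers and radii doubled) and the search is
#' restricted to a window around them (center within `D_c` at that level's
#' scale, radius within +/-20%), down to the full-resolution image.  A level
#' that fails falls back to the rescaled previous-level circle with a
#' warning; the pipeline is never aborted.  Per the selection rule, once the
#' media circle is known at the coarsest level the lumen search is re-run
#' with `r_max` set to half the media radius.
#'
#' @param coeffs a [contourlet_decompose()] result.
#' @param constraints an [init_constraints()] in full-resolution pixels.
#' @param canny_low,canny_high Canny hysteresis fractions.
#' @param sigma_full,sigma_coarse Canny smoothing at full resolution / on
#'   coarse bands (coarse bands are already low-pass).
#' @param catheter_radius radius (full-resolution pixels) of the central
#'   zone excluded from the lumen-center estimate.
#' @param n_vertices vertices of the returned circle polygons.
#' @return list with `lumen`, `media` (`ivus_contour` polygons at full
#'   resolution), `lumen_circle`, `media_circle` (one-row data frames) and
#'   `trace` (per-level circles).
#' @export
multiresolution_initialize <- function(coeffs, constraints = init_constraints(),
                                       canny_low = 0.1, canny_high = 0.3,
                                       sigma_full = 1.5, sigma_coarse = 1.0,
                                       catheter_radius = 12,
                                       n_vertices = 360L) {
  stopifnot(inherits(coeffs, "contourlet_coeffs"),
            inherits(constraints, "init_constraints"))
  J <- coeffs$levels
  bands <- c(rev(coeffs$lowpass_all), list(coeffs$image))  # a_J, ..., a_1, a_0
  scales <- 2^(J:0)
  trace <- list()
  lum <- med <- NULL

  for (li in seq_along(bands)) {
    s <- scales[li]
    band <- bands[[li]]
    sigma <- if (s > 1) sigma_coarse else sigma_full
    cs <- init_constraints(max(1, constraints$r_min / s),
                           max(2, constraints$r_max / s),
                           max(1, constraints$D_c / s))
    em <- tryCatch(edge_map(band, canny_low, canny_high, sigma),
                   warning = function(w) edge_map_quiet(band, canny_low, canny_high, sigma))
    level_failed <- FALSE
    if (is.null(lum)) {
      # coarsest level: unrestricted search + selection rules
      res <- tryCatch({
        acc <- cht_accumulate(em, cs)
        w <- max(1, round(5 / s)); wr <- max(1, round(3 / s))
        peaks <- cht_peaks(acc, nms = c(w, w, wr))
        ac <- estimate_lumen_center(band, exclude_radius = catheter_radius / s,
                                    search_radius = cs$r_max + 2)
        l0 <- select_lumen_circle(peaks, ac)
        m0 <- tryCatch(select_media_circle(peaks, l0, cs, em$mag),
                       error = function(e) NULL)
        if (is.null(m0)) {
          # no larger circle: the strongest circle near the lumen center IS
          # the media-adventitia border; the lumen is re-derived below
          m0 <- l0
        }
        # re-run lumen selection with r_max = media radius / 2
        dshr <- sqrt((peaks$x_c - m0$x_c)^2 + (peaks$y_c - m0$y_c)^2)
        shr <- peaks[peaks$r <= m0$r / 2 & dshr <= cs$D_c, , drop = FALSE]
        l0 <- if (nrow(shr)) select_lumen_circle(shr, ac) else
          data.frame(x_c = m0$x_c, y_c = m0$y_c, r = m0$r / 2,
                     score = m0$score)
        list(l = l0, m = m0)
      }, error = function(e) {
        stop(sprintf("initialization failed at the coarsest level: %s",
                     conditionMessage(e)), call. = FALSE)
      })
      lum <- res$l; med <- res$m
    } else {
      # finer level: rescale previous circles and search a window around them
      lum2 <- lum; lum2$x_c <- lum$x_c * 2; lum2$y_c <- lum$y_c * 2; lum2$r <- lum$r * 2
      med2 <- med; med2$x_c <- med$x_c * 2; med2$y_c <- med$y_c * 2; med2$r <- med$r * 2
      refined <- tryCatch({
        # restrict voting to a disk around the tracked vessel: far-field
        # clutter (guide-wire shadow lines, frame corners) neither helps nor
        # should slow the vote
        n_b <- nrow(band); m_b <- ncol(band)
        Xb <- matrix(0:(m_b - 1), n_b, m_b, byrow = TRUE)
        Yb <- matrix(0:(n_b - 1), n_b, m_b)
        lim <- 1.2 * med2$r + cs$D_c + 5
        em$mask <- em$mask &
          ((Xb - med2$x_c)^2 + (Yb - med2$y_c)^2 <= lim^2)
        acc <- cht_accumulate(em, init_constraints(
          max(1, min(cs$r_min, floor(0.8 * lum2$r))),
          ceiling(1.2 * med2$r), cs$D_c))
        # the previous level localizes the center to a couple of its pixels,
        # i.e. ~4-6 px here; the window shrinks accordingly as resolution grows
        win <- max(6, constraints$D_c / (2 * s))
        nm <- windowed_best_circle(acc, med2$x_c, med2$y_c,
                                   0.8 * med2$r, 1.2 * med2$r, win)
        med_ref <- if (is.null(nm)) med2 else nm
        # The media circle tracks reliably coarse-to-fine; the thin lumen
        # annulus is aliased by catheter/ring-down structure on coarse bands,
        # so the lumen is re-searched at every level anchored to the media
        # circle: center within D_c of it, radius within [r_min, media r / 2],
        # ranked by votes alone (a full edge arc outvotes the straight
        # gradient ridges of the guide-wire shadow sector).
        nl <- windowed_best_circle(acc, med_ref$x_c, med_ref$y_c,
                                   max(1, cs$r_min), med_ref$r / 2, cs$D_c)
        list(l = nl, m = nm)
      }, error = function(e) list(l = NULL, m = NULL))
      if (is.null(refined$l)) {
        warning(sprintf("lumen refinement failed at scale 1/%d; using rescaled circle", s))
        refined$l <- lum2
      }
      if (is.null(refined$m)) {
        warning(sprintf("media refinement failed at scale 1/%d; using rescaled circle", s))
        refined$m <- med2
      }
      lum <- refined$l; med <- refined$m
    }
    trace[[length(trace) + 1L]] <- list(scale = s, lumen = lum, media = med)
  }

  # enforce lumen strictly inside media
  dcen <- sqrt((lum$x_c - med$x_c)^2 + (lum$y_c - med$y_c)^2)
  if (dcen + lum$r >= med$r) {
    new_r <- med$r - dcen - 2
    if (new_r > 1) {
      warning("lumen circle clamped inside the media circle")
      lum$r <- new_r
    } else {
      warning("lumen circle incompatible with the media circle; falling back to a concentric half-radius start")
      lum$x_c <- med$x_c; lum$y_c <- med$y_c; lum$r <- med$r / 2
    }
  }
  list(lumen = circle_contour(lum$x_c, lum$y_c, lum$r, n_vertices),
       media = circle_contour(med$x_c, med$y_c, med$r, n_vertices),
       lumen_circle = lum, media_circle = med, trace = trace)
}

# edge_map with warnings suppressed (used when a coarse band is near-flat).
edge_map_quiet <- function(...) suppressWarnings(edge_map(...))
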