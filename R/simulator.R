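# Synthetic IVUS phantom generator based on a polar image-formation model.
# A radial layer map (lumen / media band / adventitia) is built from two
# quasi-circular ground-truth interfaces, multiplied by Rayleigh-distributed
# speckle correlated by a small polar-domain kernel, augmented with a bright
# ring-down halo around the catheter and a guide-wire shadow sector (the two
# artifacts are merged into one model), and scan-converted to Cartesian.

#' Phantom specification
#'
#' All geometry is in full-resolution pixels of an `image_size` square frame.
#' The two interfaces are `r(theta) = r0 * (1 + sum_m a_m cos(m theta + phase_m))`
#' around a common vessel center; the defaults put both radii inside the
#' pipeline's circle-search range (15, 40) with the lumen radius below half
#' the media radius, matching the search rule that caps the lumen radius at
#' half the found media radius.
#'
#' @param image_size square image side (default 384).
#' @param center vessel center `c(x, y)`, 0-based (default image center).
#' @param lumen_offset lumen center offset from the vessel center.
#' @param lumen_radius,media_radius base radii (pixels).
#' @param lumen_harmonics,media_harmonics named lists with `amp` and `phase`
#'   vectors for Fourier harmonics m = 2, 3, ... (relative amplitudes).
#' @param echogenicity mean intensities `c(lumen, media, adventitia)` on a
#'   0..1 scale (dark blood pool, echolucent media band, bright adventitia).
#' @param speckle_scale multiplicative speckle strength: 1 = fully developed
#'   Rayleigh speckle (unit-mean), 0 = noise-free.
#' @param speckle_corr polar correlation lengths `c(radial, angular)` of the
#'   speckle smoothing kernel, in polar-grid bins; 0 disables smoothing.
#' @param catheter_radius radius of the central catheter dead zone.
#' @param ringdown_amp,ringdown_decay peak added intensity and radial decay
#'   length (pixels) of the ring-down halo just outside the catheter.
#' @param wire_angle,wire_width,wire_attenuation guide-wire sector: angular
#'   position and full width (radians) and the multiplicative attenuation of
#'   echoes beyond the catheter in that sector.
#' @param seed RNG seed; a fixed seed makes the phantom bit-reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 384L,
                         center = NULL,
                         lumen_offset = c(0, 0),
                         lumen_radius = 16,
                         media_radius = 36,
                         lumen_harmonics = list(amp = c(0.10, 0.05),
                                                phase = c(0.7, 2.1)),
                         media_harmonics = list(amp = c(0.07, 0.035),
                                                phase = c(1.9, 0.4)),
                         echogenicity = c(lumen = 0.08, media = 0.25,
                                          adventitia = 0.55),
                         speckle_scale = 1.0,
                         speckle_corr = c(1, 1),
                         catheter_radius = 6,
                         ringdown_amp = 0.35,
                         ringdown_decay = 3,
                         wire_angle = 1.2,
                         wire_width = 0.35,
                         wire_attenuation = 0.25,
                         seed = 1L) {
  if (is.null(center)) center <- c((image_size - 1) / 2, (image_size - 1) / 2)
  spec <- structure(list(
    image_size = as.integer(image_size), center = center,
    lumen_offset = lumen_offset, lumen_radius = lumen_radius,
    media_radius = media_radius, lumen_harmonics = lumen_harmonics,
    media_harmonics = media_harmonics, echogenicity = echogenicity,
    speckle_scale = speckle_scale, speckle_corr = speckle_corr,
    catheter_radius = catheter_radius, ringdown_amp = ringdown_amp,
    ringdown_decay = ringdown_decay, wire_angle = wire_angle,
    wire_width = wire_width, wire_attenuation = wire_attenuation,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  th <- seq(0, 2 * pi, length.out = 721)
  rl <- interface_radius(spec$lumen_radius, spec$lumen_harmonics, th)
  rm_ <- interface_radius(spec$media_radius, spec$media_harmonics, th)
  off <- sqrt(sum(spec$lumen_offset^2))
  if (min(rm_) - (max(rl) + off) < 5)
    stop("invalid phantom spec: media-lumen gap below 5 px", call. = FALSE)
  if (max(rm_) >= spec$image_size / 2 - 5)
    stop("invalid phantom spec: media interface too close to the frame edge",
         call. = FALSE)
  if (spec$catheter_radius >= min(rl))
    stop("invalid phantom spec: catheter larger than the lumen", call. = FALSE)
  invisible(spec)
}

interface_radius <- function(r0, harm, theta) {
  pert <- rep(0, length(theta))
  if (length(harm$amp)) {
    for (i in seq_along(harm$amp))
      pert <- pert + harm$amp[i] * cos((i + 1) * theta + harm$phase[i])
  }
  r0 * (1 + pert)
}

#' Generate one IVUS phantom
#'
#' Synthesis runs on a polar grid (1 px radial bins, 720 angular bins):
#' layer echogenicity from the two ground-truth interfaces, multiplied by
#' unit-mean Rayleigh speckle (optionally correlated by a small polar
#' Gaussian kernel), plus the merged ring-down/guide-wire artifact model;
#' the polar image is scan-converted to Cartesian with bilinear
#' interpolation and clipped to [0, 1].
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom`: list with `image` (matrix in
#'   [0, 1]), `lumen_truth`, `media_truth` (`ivus_contour`s, the exact
#'   synthesized interfaces), `spec`, and `polar` (the pre-smoothing,
#'   pre-artifact polar-domain speckle image with its layer map, kept for
#'   statistical checks).
#' @examples
#' ph <- generate_phantom(phantom_spec(image_size = 128, lumen_radius = 12,
#'                                     media_radius = 26, seed = 7))
#' dim(ph$image)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    n <- spec$image_size
    n_theta <- 720L
    n_r <- as.integer(ceiling(n / 2 * sqrt(2))) + 2L
    th <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
    rr <- seq_len(n_r) - 1

    lum_cen <- spec$center + spec$lumen_offset
    r_lum <- interface_radius(spec$lumen_radius, spec$lumen_harmonics, th)
    r_med <- interface_radius(spec$media_radius, spec$media_harmonics, th)

    # layer map on the polar grid (rows = radius, cols = angle), relative to
    # the vessel center; the lumen interface is offset, handled per angle by
    # the radius at which a ray from the VESSEL center crosses the lumen
    # interface around the lumen center.
    r_lum_eff <- vapply(seq_len(n_theta), function(i) {
      ray_interface_crossing(spec$center, th[i], lum_cen,
                             spec$lumen_radius, spec$lumen_harmonics)
    }, numeric(1))
    R <- matrix(rr, n_r, n_theta)
    RL <- matrix(r_lum_eff, n_r, n_theta, byrow = TRUE)
    RM <- matrix(r_med, n_r, n_theta, byrow = TRUE)
    layer <- matrix(spec$echogenicity[["adventitia"]], n_r, n_theta)
    layer[R < RM] <- spec$echogenicity[["media"]]
    layer[R < RL] <- spec$echogenicity[["lumen"]]

    # multiplicative Rayleigh speckle, unit mean
    if (spec$speckle_scale > 0) {
      ray_sigma <- sqrt(2 / pi)  # Rayleigh(sigma) has mean sigma*sqrt(pi/2)
      S <- matrix(ray_sigma * sqrt(-2 * log(stats::runif(n_r * n_theta))),
                  n_r, n_theta)
      raw <- layer * (1 + spec$speckle_scale * (S - 1))
      polar_raw <- raw
      if (any(spec$speckle_corr > 0)) {
        Ssm <- polar_smooth(S, spec$speckle_corr[1], spec$speckle_corr[2])
        Ssm <- Ssm / mean(Ssm)
        P <- layer * (1 + spec$speckle_scale * (Ssm - 1))
      } else {
        P <- raw
      }
    } else {
      P <- layer
      polar_raw <- layer
    }
    P[P < 0] <- 0

    # merged ring-down + guide-wire artifact model
    ring <- spec$ringdown_amp *
      exp(-pmax(rr - spec$catheter_radius, 0) / spec$ringdown_decay)
    ring[rr < spec$catheter_radius] <- 0
    P <- P + matrix(ring, n_r, n_theta)
    dth <- abs(((th - spec$wire_angle + pi) %% (2 * pi)) - pi)
    wire <- dth <= spec$wire_width / 2
    if (any(wire)) {
      shadow_rows <- rr > spec$catheter_radius + 2
      P[shadow_rows, wire] <- P[shadow_rows, wire] * spec$wire_attenuation
      # bright wire echo merged into the ring-down zone
      echo_rows <- rr >= spec$catheter_radius & rr <= spec$catheter_radius + 2
      P[echo_rows, wire] <- pmax(P[echo_rows, wire], 0.9)
    }
    P[rr < spec$catheter_radius, ] <- 0.03  # transducer dead zone

    img <- scan_convert(P, spec$center, n)
    img[img < 0] <- 0
    img[img > 1] <- 1

    th_out <- seq(0, 2 * pi, length.out = 361)[-361]
    lumen_truth <- as_contour(data.frame(
      x = lum_cen[1] + interface_radius(spec$lumen_radius,
                                        spec$lumen_harmonics, th_out) * cos(th_out),
      y = lum_cen[2] + interface_radius(spec$lumen_radius,
                                        spec$lumen_harmonics, th_out) * sin(th_out)))
    media_truth <- as_contour(data.frame(
      x = spec$center[1] + interface_radius(spec$media_radius,
                                            spec$media_harmonics, th_out) * cos(th_out),
      y = spec$center[2] + interface_radius(spec$media_radius,
                                            spec$media_harmonics, th_out) * sin(th_out)))

    structure(list(image = img, lumen_truth = lumen_truth,
                   media_truth = media_truth, spec = spec,
                   polar = list(raw = polar_raw, layer = layer,
                                radii = rr, theta = th)),
              class = "phantom")
  })
}

# Radius (from `origin` along direction `theta`) at which the ray crosses the
# closed interface r(phi) around `cen`; bisection on the implicit inside test.
ray_interface_crossing <- function(origin, theta, cen, r0, harm) {
  inside <- function(t) {
    p <- origin + t * c(cos(theta), sin(theta))
    v <- p - cen
    sqrt(sum(v^2)) < interface_radius(r0, harm, atan2(v[2], v[1]))
  }
  lo <- 0; hi <- 4 * r0
  if (!inside(lo)) return(0)
  while (inside(hi)) hi <- hi * 1.5
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (inside(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Gaussian smoothing on the polar grid, wrapping in angle, mirrored in radius.
polar_smooth <- function(P, sr, st) {
  if (sr > 0) P <- apply_gauss_cols(P, sr, wrap = FALSE)
  if (st > 0) P <- t(apply_gauss_cols(t(P), st, wrap = TRUE))
  P
}

apply_gauss_cols <- function(M, sigma, wrap = FALSE) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2)); k <- k / sum(k)
  n <- nrow(M)
  idx <- (1L - half):(n + half)
  idx <- if (wrap) ((idx - 1L) %% n) + 1L else mirror_index(idx, n)
  P <- M[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(M))
  for (t in seq_along(k))
    out <- out + k[t] * P[t:(t + n - 1L), , drop = FALSE]
  out
}

# Bilinear polar-to-Cartesian scan conversion.
scan_convert <- function(P, center, n) {
  n_r <- nrow(P); n_theta <- ncol(P)
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  Y <- matrix(0:(n - 1), n, n)
  dx <- X - center[1]; dy <- Y - center[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) %% (2 * pi)
  ri <- pmin(as.vector(r), n_r - 1 - 1e-9)
  ti <- as.vector(th) / (2 * pi) * n_theta
  r0 <- floor(ri); t0 <- floor(ti) %% n_theta
  fr <- ri - r0; ft <- ti - floor(ti)
  r1 <- pmin(r0 + 1, n_r - 1); t1 <- (t0 + 1) %% n_theta
  v <- (1 - fr) * (1 - ft) * P[cbind(r0 + 1, t0 + 1)] +
       fr * (1 - ft) * P[cbind(r1 + 1, t0 + 1)] +
       (1 - fr) * ft * P[cbind(r0 + 1, t1 + 1)] +
       fr * ft * P[cbind(r1 + 1, t1 + 1)]
  matrix(v, n, n)
}

#' Generate a reproducible batch of phantoms
#'
#' Per-item seeds are derived deterministically from the batch seed, and the
#' geometry is jittered around the base specification: base radii by
#' `radius_jitter`, the lumen offset uniformly within `offset_jitter`, and
#' harmonic phases uniformly at random.
#'
#' @param n number of phantoms (the reference evaluation cohort uses 20).
#' @param base_spec a [phantom_spec()] used as the template.
#' @param seed batch seed.
#' @param radius_jitter half-width of the uniform jitter on both base radii
#'   (pixels).
#' @param offset_jitter maximum lumen-center offset component (pixels).
#' @return list of `phantom` objects.
#' @export
phantom_batch <- function(n = 20L, base_spec = phantom_spec(), seed = 1L,
                          radius_jitter = 2, offset_jitter = 3) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    item_seed <- derive_seed(seed, i)
    sp <- with_seed(item_seed, {
      sp <- base_spec
      sp$lumen_radius <- base_spec$lumen_radius +
        stats::runif(1, -radius_jitter, radius_jitter)
      sp$media_radius <- base_spec$media_radius +
        stats::runif(1, -radius_jitter, radius_jitter)
      sp$lumen_offset <- stats::runif(2, -offset_jitter, offset_jitter)
      sp$lumen_harmonics$phase <- stats::runif(
        length(sp$lumen_harmonics$phase), 0, 2 * pi)
      sp$media_harmonics$phase <- stats::runif(
        length(sp$media_harmonics$phase), 0, 2 * pi)
      sp$wire_angle <- stats::runif(1, 0, 2 * pi)
      sp$seed <- as.integer(derive_seed(item_seed, 1000L))
      sp
    })
    generate_phantom(sp)
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%d, lumen r~%.1f px, media r~%.1f px, seed %d\n",
              nrow(x$image), ncol(x$image), x$spec$lumen_radius,
              x$spec$media_radius, x$spec$seed))
  invisible(x)
}
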