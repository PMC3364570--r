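# Variational level sets without reinitialization.  The energy
#   E(phi) = mu P(phi) + lambda L(phi) + nu A(phi)
# combines an internal penalty P that keeps phi close to a signed distance
# function (eliminating reinitialization), a g-weighted contour length L and
# a g-weighted enclosed area A (balloon term).  Gradient descent gives
#   dphi/dt = mu [ Lap phi - div(grad phi/|grad phi|) ]
#           + lambda delta(phi) div( g grad phi/|grad phi| )
#           + nu g delta(phi).

#' Level-set evolution parameters
#'
#' @param mu weight of the signed-distance penalty; `mu * dt < 0.25` is
#'   required for stability of the explicit scheme.
#' @param lam weight of the g-weighted length term.
#' @param nu balloon (weighted-area) coefficient; negative expands the
#'   contour, positive shrinks it.
#' @param alpha half-width of the regularized Dirac/Heaviside (pixels).
#' @param sigma Gaussian sigma of the edge indicator (pixels).
#' @param C magnitude of the binary initial level-set values.
#' @param dt time step.
#' @param max_iter iteration cap of the balloon-driven phase.
#' @param tol convergence threshold: evolution stops once
#'   `max |phi_{t+1} - phi_t| < tol` for 5 consecutive iterations.
#' @param refine_iter iterations of the balloon-free settling phase run
#'   after the driven phase (`nu = 0`).  The balloon force makes the front
#'   equilibrate slightly past the minimum of the edge indicator valley;
#'   releasing it lets the geodesic term pull the contour back onto the
#'   edge.  0 disables the phase.
#' @return an object of class `levelset_params`.
#' @export
levelset_params <- function(mu = 0.04, lam = 7.0, nu = 1.5, alpha = 1.5,
                            sigma = 1.5, C = 4.0, dt = 5.0,
                            max_iter = 500L, tol = 1e-3, refine_iter = 100L) {
  stopifnot(mu > 0, lam > 0, alpha > 0, sigma > 0, C > 0, dt > 0,
            max_iter >= 1, tol > 0, refine_iter >= 0)
  if (mu * dt >= 0.25)
    stop(sprintf("mu * dt = %g violates the stability bound (< 0.25)", mu * dt),
         call. = FALSE)
  structure(list(mu = mu, lam = lam, nu = nu, alpha = alpha, sigma = sigma,
                 C = C, dt = dt, max_iter = as.integer(max_iter), tol = tol,
                 refine_iter = as.integer(refine_iter)),
            class = "levelset_params")
}

#' Edge indicator function
#'
#' `g = 1 / (1 + |grad(G_sigma * I)|^2)`: close to 1 in homogeneous regions,
#' small across strong edges, so it halts the contour at boundaries.
#' Gradients are central differences of the Gaussian-smoothed image.
#'
#' @param image numeric matrix (any intensity scale; note that the gradient
#'   magnitude, and hence the strength of the indicator, scales with it).
#' @param sigma Gaussian standard deviation in pixels.
#' @return matrix of values in (0, 1].
#' @export
edge_indicator <- function(image, sigma = 1.5) {
  check_image(image)
  stopifnot(sigma > 0)
  g <- grad_central(gauss_smooth(image, sigma))
  1 / (1 + g$gx^2 + g$gy^2)
}

#' Regularized Dirac and Heaviside functions
#'
#' Cosine-regularized approximations supported on `|s| <= alpha`:
#' `dirac_reg` integrates to 1 and is the derivative of `heaviside_reg`,
#' which rises monotonically from 0 to 1.
#'
#' @param s numeric vector or matrix.
#' @param alpha regularization half-width (> 0).
#' @return same shape as `s`.
#' @export
dirac_reg <- function(s, alpha) {
  stopifnot(alpha > 0)
  out <- (1 + cos(pi * s / alpha)) / (2 * alpha)
  out[abs(s) > alpha] <- 0
  out
}

#' @rdname dirac_reg
#' @export
heaviside_reg <- function(s, alpha) {
  stopifnot(alpha > 0)
  out <- (1 + s / alpha + sin(pi * s / alpha) / pi) / 2
  out[s < -alpha] <- 0
  out[s > alpha] <- 1
  out
}

#' Binary level-set initialization
#'
#' Builds the initial field `phi_0 = -C` inside the region, `+C` outside.
#' The reinitialization-free formulation accepts this binary start directly;
#' no signed-distance construction is needed.
#'
#' @param mask logical matrix, `TRUE` inside the initial region.
#' @param C positive constant.
#' @return an object of class `levelset_field`: list with `phi` (matrix) and
#'   `iteration`.
#' @export
init_phi <- function(mask, C = 4.0) {
  stopifnot(is.matrix(mask), is.logical(mask), C > 0)
  if (!any(mask) || all(mask))
    stop("initial region must be non-empty and not cover the whole frame",
         call. = FALSE)
  phi <- matrix(C, nrow(mask), ncol(mask))
  phi[mask] <- -C
  structure(list(phi = phi, iteration = 0L), class = "levelset_field")
}

#' One explicit evolution step
#'
#' Advances the field by one explicit-Euler step of the evolution PDE.
#' Discretization (part of the contract): 5-point Laplacian; all first
#' derivatives by central differences with replicated borders;
#' `|grad phi|` floored at 1e-10; Dirac regularized by [dirac_reg()].
#'
#' @param field a `levelset_field`.
#' @param g edge indicator matrix (same shape as `field$phi`).
#' @param params a [levelset_params()] object.
#' @return the updated `levelset_field`.
#' @export
evolve_step <- function(field, g, params) {
  stopifnot(inherits(field, "levelset_field"),
            all(dim(g) == dim(field$phi)))
  phi <- .evolve_step_cpp(field$phi, g, params$mu, params$lam, params$nu,
                          params$alpha, params$dt)
  if (!all(is.finite(phi))) {
    d <- phi - field$phi
    stop(sprintf(
      "level-set update diverged at iteration %d (max |dphi/dt| = %g)",
      field$iteration + 1L, max(abs(d[is.finite(d)]), 0) / params$dt),
      call. = FALSE)
  }
  field$phi <- phi
  field$iteration <- field$iteration + 1L
  field
}

# Evolve one field to convergence; returns field + diagnostics.  The whole
# iteration runs in compiled code (same per-step discretization as
# evolve_step, which remains the single-step reference surface).
evolve_to_convergence <- function(field, g, params) {
  res <- .evolve_run_cpp(field$phi, g, params$mu, params$lam, params$nu,
                         params$alpha, params$dt, params$max_iter,
                         params$tol, 5L)
  if (!res$finite)
    stop(sprintf(
      "level-set update diverged at iteration %d (max |dphi/dt| = %g)",
      field$iteration + res$iterations, res$final_delta / params$dt),
      call. = FALSE)
  field$phi <- res$phi
  field$iteration <- field$iteration + res$iterations
  list(field = field, converged = res$converged,
       iterations = field$iteration, final_delta = res$final_delta)
}

#' Extract the zero level set as a contour
#'
#' Marching-squares isocontour of `phi` at level 0 (subpixel, via
#' [grDevices::contourLines()]); the closed component enclosing the largest
#' area is returned.
#'
#' @param phi numeric matrix (a level-set field).
#' @return an `ivus_contour`, or `NULL` if no zero crossing exists.
#' @export
zero_contour <- function(phi) {
  check_image(phi, arg = "phi")
  nr <- nrow(phi); nc <- ncol(phi)
  lines <- grDevices::contourLines(x = 0:(nc - 1), y = 0:(nr - 1),
                                   z = t(phi), levels = 0)
  if (!length(lines)) return(NULL)
  best <- NULL; best_area <- -1
  for (ln in lines) {
    if (length(ln$x) < 4) next
    a <- abs(shoelace_area(ln$x, ln$y))
    if (a > best_area) { best_area <- a; best <- ln }
  }
  if (is.null(best)) return(NULL)
  as_contour(data.frame(x = best$x, y = best$y))
}

#' Two-contour level-set segmentation
#'
#' Evolves two independent level-set fields, seeded by the initial lumen and
#' media-adventitia contours, on the same edge indicator `g(I)`.  By default
#' the lumen field carries a negative balloon coefficient (it expands from a
#' circle that may underestimate the blood pool) and the media field a
#' positive one (it shrinks onto the outer interface).  After extraction the
#' lumen contour is checked to lie inside the media contour; violating
#' vertices are clamped radially to 2 px inside it, with a warning.
#'
#' @param image the (despeckled) image the contours should lock onto.  The
#'   edge indicator is computed from this image as given; callers should
#'   scale intensities so that boundary gradients are O(1) or larger
#'   (the pipeline uses an 8-bit 0..255 scale).
#' @param lumen0,media0 initial contours (`ivus_contour`), `lumen0` strictly
#'   inside `media0`.
#' @param params a [levelset_params()] object; `nu` is taken as the MEDIA
#'   balloon coefficient.
#' @param nu_lumen balloon coefficient for the lumen field (default `-params$nu`).
#' @return a list with `lumen`, `media` (final `ivus_contour`s) and
#'   `diagnostics` (per-contour iterations, convergence flags, final update
#'   sizes).
#' @export
segment <- function(image, lumen0, media0, params = levelset_params(),
                    nu_lumen = -params$nu) {
  check_image(image)
  stopifnot(inherits(lumen0, "ivus_contour"), inherits(media0, "ivus_contour"))
  if (!all(points_in_contour(lumen0$x, lumen0$y, media0)))
    stop("initial lumen contour must lie strictly inside the media contour",
         call. = FALSE)
  g <- edge_indicator(image, params$sigma)

  run_one <- function(init, nu) {
    p <- params; p$nu <- nu
    mask <- rasterize_contour(init, dim(image))
    res <- evolve_to_convergence(init_phi(mask, params$C), g, p)
    if (params$refine_iter > 0) {
      p$nu <- 0; p$max_iter <- params$refine_iter
      res2 <- evolve_to_convergence(res$field, g, p)
      res2$converged <- res$converged || res2$converged
      res <- res2
    }
    res
  }
  res_l <- run_one(lumen0, nu_lumen)
  res_m <- run_one(media0, params$nu)

  lumen <- zero_contour(res_l$field$phi)
  media <- zero_contour(res_m$field$phi)
  if (is.null(lumen)) { warning("lumen level set vanished; keeping initialization"); lumen <- lumen0 }
  if (is.null(media)) { warning("media level set vanished; keeping initialization"); media <- media0 }

  lumen <- clamp_inside(lumen, media, margin = 2)

  list(lumen = lumen, media = media,
       diagnostics = list(
         lumen = list(iterations = res_l$iterations,
                      converged = res_l$converged,
                      final_delta = res_l$final_delta),
         media = list(iterations = res_m$iterations,
                      converged = res_m$converged,
                      final_delta = res_m$final_delta)))
}

# Clamp vertices of `inner` that escape `outer` radially to `margin` px
# inside the outer contour (measured toward the outer centroid).
clamp_inside <- function(inner, outer, margin = 2) {
  out_flags <- !points_in_contour(inner$x, inner$y, outer)
  if (!any(out_flags)) return(inner)
  warning(sprintf("lumen contour crossed the media contour at %d vertices; clamped",
                  sum(out_flags)))
  cen <- contour_centroid(outer)
  x <- inner$x; y <- inner$y
  for (i in which(out_flags)) {
    d <- point_to_contour_distance(c(x[i], y[i]), outer)
    # pull the vertex toward the centroid past the outer boundary + margin
    v <- c(x[i] - cen[1], y[i] - cen[2])
    len <- sqrt(sum(v^2))
    if (len < 1e-9) next
    new_len <- max(len - d$D - margin, 0)
    x[i] <- cen[1] + v[1] / len * new_len
    y[i] <- cen[2] + v[2] / len * new_len
  }
  as_contour(data.frame(x = x, y = y))
}
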