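# Contour-to-contour error metrics: mean distance (MD, pixels) and relative
# mean distance (RMD, percent).  For each vertex p of the detected contour,
# D(p) is the exact minimum Euclidean distance to the reference POLYLINE
# (segment-wise, closing edge included), q the attaining foot point, and
# RD(p) = D(p) / d(q, O) with O the vertex centroid of the reference.
# MD = mean(D), RMD = mean(RD) * 100.

#' Minimum distance from a point to a closed contour
#'
#' @param p numeric length-2 vector `c(x, y)`.
#' @param reference an `ivus_contour` (>= 3 vertices).
#' @return list with `D` (distance) and `q` (foot point on the polyline).
#' @export
point_to_contour_distance <- function(p, reference) {
  if (!inherits(reference, "ivus_contour") || nrow(reference) < 3)
    stop("reference must be a closed contour with at least 3 vertices",
         call. = FALSE)
  res <- points_to_contour_distance(matrix(p, 1), reference)
  list(D = res$D[1], q = c(res$qx[1], res$qy[1]))
}

# Vectorized point-to-polyline distance: P is an n x 2 matrix.
points_to_contour_distance <- function(P, reference) {
  ax <- reference$x; ay <- reference$y
  n <- length(ax)
  bx <- ax[c(2:n, 1)]; by <- ay[c(2:n, 1)]
  ex <- bx - ax; ey <- by - ay
  elen2 <- ex^2 + ey^2
  px <- P[, 1]; py <- P[, 2]
  bestD2 <- rep(Inf, nrow(P))
  qx <- numeric(nrow(P)); qy <- numeric(nrow(P))
  for (s in seq_len(n)) {
    if (elen2[s] < 1e-300) {
      t <- 0
    } else {
      t <- ((px - ax[s]) * ex[s] + (py - ay[s]) * ey[s]) / elen2[s]
      t <- pmin(pmax(t, 0), 1)
    }
    fx <- ax[s] + t * ex[s]; fy <- ay[s] + t * ey[s]
    d2 <- (px - fx)^2 + (py - fy)^2
    upd <- d2 < bestD2
    bestD2[upd] <- d2[upd]; qx[upd] <- fx[upd]; qy[upd] <- fy[upd]
  }
  list(D = sqrt(bestD2), qx = qx, qy = qy)
}

#' Mean distance and relative mean distance between contours
#'
#' Computes per-vertex distances from the detected contour to the reference,
#' the mean distance MD (pixels) and the relative mean distance RMD
#' (percent), where each distance is normalized by the distance of its foot
#' point from the reference centroid.  The comparison is one-directional
#' (detected against reference); swap arguments for the other direction.
#'
#' @param detected,reference `ivus_contour` objects (the reference is the
#'   ground truth or manual tracing).
#' @return an object of class `contour_comparison`: list with `MD`, `RMD`,
#'   `n_points`, `center` (reference centroid) and `per_point` (data frame
#'   with columns `x`, `y`, `D`, `qx`, `qy`, `RD`).
#' @examples
#' ref <- circle_contour(0, 0, 50, 720)
#' det <- circle_contour(0, 0, 55, 720)
#' md_rmd(det, ref)$MD   # 5
#' @export
md_rmd <- function(detected, reference) {
  stopifnot(inherits(detected, "ivus_contour"),
            inherits(reference, "ivus_contour"))
  O <- contour_centroid(reference)
  P <- cbind(detected$x, detected$y)
  res <- points_to_contour_distance(P, reference)
  dqO <- sqrt((res$qx - O[1])^2 + (res$qy - O[2])^2)
  if (any(dqO < 1e-9))
    stop("degenerate reference: a foot point coincides with the contour center",
         call. = FALSE)
  RD <- res$D / dqO
  structure(list(MD = mean(res$D), RMD = mean(RD) * 100,
                 n_points = nrow(P), center = O,
                 per_point = data.frame(x = detected$x, y = detected$y,
                                        D = res$D, qx = res$qx, qy = res$qy,
                                        RD = RD)),
            class = "contour_comparison")
}

#' Symmetric mean contour distance
#'
#' Average of [md_rmd()] distances in both directions.  This symmetric
#' variant is an extra convenience, not part of the primary MD/RMD metric
#' definition.
#'
#' @param a,b `ivus_contour` objects.
#' @return a single number (pixels).
#' @export
mean_symmetric_distance <- function(a, b) {
  (md_rmd(a, b)$MD + md_rmd(b, a)$MD) / 2
}

#' @export
print.contour_comparison <- function(x, ...) {
  cat(sprintf("<contour_comparison> MD = %.3f px, RMD = %.2f%% (n = %d)\n",
              x$MD, x$RMD, x$n_points))
  invisible(x)
}
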