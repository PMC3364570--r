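#' Closed planar contours
#'
#' A contour is an ordered, closed polygon of subpixel points stored as a
#' data frame with columns `x` and `y` (pixel-centered, 0-based image
#' coordinates; x rightward, y downward).  The closing edge from the last
#' vertex back to the first is implied.  Vertices are kept in
#' counter-clockwise order with respect to standard mathematical axes
#' (i.e. negative shoelace area in the y-down image frame is flipped).
#'
#' @param x a data frame (or 2-column matrix) of vertex coordinates.
#' @return an object of class `ivus_contour` (a data frame with columns
#'   `x`, `y`).
#' @examples
#' sq <- as_contour(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
#' contour_area(sq)
#' @export
as_contour <- function(x) {
  if (is.matrix(x)) x <- data.frame(x = x[, 1], y = x[, 2])
  stopifnot(is.data.frame(x), all(c("x", "y") %in% names(x)))
  df <- data.frame(x = as.numeric(x$x), y = as.numeric(x$y))
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("contour vertices must be finite", call. = FALSE)
  # drop duplicated closing vertex if present
  n <- nrow(df)
  if (n >= 2 && df$x[1] == df$x[n] && df$y[1] == df$y[n])
    df <- df[-n, , drop = FALSE]
  if (nrow(df) < 3)
    stop("a contour needs at least 3 distinct vertices", call. = FALSE)
  if (shoelace_area(df$x, df$y) < 0) df <- df[rev(seq_len(nrow(df))), ]
  rownames(df) <- NULL
  class(df) <- c("ivus_contour", "data.frame")
  df
}

# Signed shoelace area (positive = counter-clockwise in math axes).
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area enclosed by a contour
#' @param contour an [as_contour()] polygon.
#' @return enclosed area in square pixels (non-negative).
#' @export
contour_area <- function(contour) {
  abs(shoelace_area(contour$x, contour$y))
}

#' Regular polygon approximating a circle
#'
#' @param xc,yc circle center (0-based pixel coordinates).
#' @param r radius in pixels.
#' @param n number of vertices.
#' @return an `ivus_contour` with `n` vertices.
#' @export
circle_contour <- function(xc, yc, r, n = 360L) {
  stopifnot(r > 0, n >= 3)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  as_contour(data.frame(x = xc + r * cos(th), y = yc + r * sin(th)))
}

#' Vertex centroid of a contour
#' @param contour an `ivus_contour`.
#' @return numeric length-2 vector `c(x, y)`.
#' @export
contour_centroid <- function(contour) {
  c(x = mean(contour$x), y = mean(contour$y))
}

#' Test points for inclusion in a closed polygon
#'
#' Even-odd (ray crossing) rule, vectorized over query points.
#'
#' @param px,py query point coordinates.
#' @param contour an `ivus_contour`.
#' @return logical vector, `TRUE` for points inside.
#' @export
points_in_contour <- function(px, py, contour) {
  vx <- contour$x; vy <- contour$y
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    xi <- vx[k]; yi <- vy[k]; xj <- vx[j[k]]; yj <- vy[j[k]]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Rasterize a contour to a binary mask
#'
#' Scanline even-odd fill on the pixel grid: pixel (row, col) is set when its
#' center (x = col - 1, y = row - 1) lies inside the polygon.
#'
#' @param contour an `ivus_contour`.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return a logical matrix of the requested dimensions.
#' @export
rasterize_contour <- function(contour, dim) {
  nr <- dim[1]; nc <- dim[2]
  mask <- matrix(FALSE, nr, nc)
  vx <- contour$x; vy <- contour$y
  n <- length(vx)
  j <- c(2:n, 1L)
  rows <- seq_len(nr)
  ymin <- max(1L, floor(min(vy)) + 1L)
  ymax <- min(nr, ceiling(max(vy)) + 1L)
  for (row in ymin:ymax) {
    y <- row - 1
    xi <- vx; yi <- vy; xj <- vx[j]; yj <- vy[j]
    sel <- (yi > y) != (yj > y)
    if (!any(sel)) next
    xs <- xi[sel] + (y - yi[sel]) * (xj[sel] - xi[sel]) / (yj[sel] - yi[sel])
    xs <- sort(xs)
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      c0 <- max(1L, ceiling(xs[k]) + 1L)
      c1 <- min(nc, floor(xs[k + 1L]) + 1L)
      if (c0 <= c1) mask[row, c0:c1] <- TRUE
    }
  }
  mask
}

#' Scale a contour about its centroid
#' @param contour an `ivus_contour`.
#' @param factor radial scale factor (> 0).
#' @return the scaled `ivus_contour`.
#' @export
scale_contour <- function(contour, factor) {
  stopifnot(factor > 0)
  cen <- contour_centroid(contour)
  as_contour(data.frame(x = cen[1] + factor * (contour$x - cen[1]),
                        y = cen[2] + factor * (contour$y - cen[2])))
}

#' Resample a contour at uniform arc-length spacing
#' @param contour an `ivus_contour`.
#' @param n number of output vertices.
#' @return an `ivus_contour` with `n` vertices.
#' @export
resample_contour <- function(contour, n = 360L) {
  x <- c(contour$x, contour$x[1]); y <- c(contour$y, contour$y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate contour (zero perimeter)", call. = FALSE)
  t0 <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  as_contour(data.frame(x = stats::approx(s, x, xout = t0)$y,
                        y = stats::approx(s, y, xout = t0)$y))
}

#' Read / write contours as CSV polygons
#'
#' Plain CSV with `x,y` header, one vertex per line; the closing edge is
#' implied.
#'
#' @param contour an `ivus_contour`.
#' @param path file path.
#' @return `read_contour_csv()` returns an `ivus_contour`;
#'   `write_contour_csv()` returns `path` invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(data.frame(x = contour$x, y = contour$y), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  as_contour(utils::read.csv(path))
}

#' @export
print.ivus_contour <- function(x, ...) {
  cen <- contour_centroid(x)
  cat(sprintf("<ivus_contour> %d vertices, area %.1f px^2, centroid (%.1f, %.1f)\n",
              nrow(x), contour_area(x), cen[1], cen[2]))
  invisible(x)
}
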