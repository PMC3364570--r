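# End-to-end orchestration: contourlet decomposition feeds two paths — the
# low-pass pyramid drives the multiresolution circle initialization, the
# band-pass directional subbands are despeckled by anisotropic diffusion and
# recombined into the filtered image on which the two level sets evolve.

#' Pipeline configuration
#'
#' Bundles the per-stage parameters with their standard defaults: a 3-level
#' pyramid with directional levels (2, 2, 3), circle search radii (15, 40)
#' with a 25 px center constraint, Perona-Malik despeckling, and the
#' level-set defaults of [levelset_params()].
#'
#' @param contourlet list with `levels` and `dfb_levels`.
#' @param hough list with `r_min`, `r_max`, `D_c`, `canny_low`, `canny_high`,
#'   `sigma_full`, `sigma_coarse`, `catheter_radius`.
#' @param diffusion an [ad_params()] object.
#' @param levelset a [levelset_params()] object.
#' @param nu_lumen balloon coefficient of the lumen field (negative =
#'   expand); the media field uses `levelset$nu`.
#' @param init_margin radial factors applied to the fitted initial circles
#'   before evolution, `c(lumen, media)`.  The media balloon only shrinks,
#'   so its start must overestimate the boundary everywhere; a 10%
#'   inflation covers the eccentricity a circle fit leaves behind, beyond
#'   what the edge valley's capture basin absorbs.  The lumen's smaller
#'   absolute eccentricity stays within that basin, so its circle is used
#'   as fitted.
#' @param intensity_scale factor applied to the (0..1-normalized) filtered
#'   image before the edge indicator, so that default level-set weights
#'   behave as on 8-bit images.
#' @param baseline `"none"` for the full method or `"traditional"` to skip
#'   despeckling and evolve on the raw image (identical initialization).
#' @return an object of class `ivus_config`.
#' @export
ivus_config <- function(contourlet = list(levels = 3L, dfb_levels = c(2L, 2L, 3L)),
                        hough = list(r_min = 15, r_max = 40, D_c = 25,
                                     canny_low = 0.1, canny_high = 0.3,
                                     sigma_full = 1.5, sigma_coarse = 1.0,
                                     catheter_radius = 12),
                        diffusion = ad_params(),
                        levelset = levelset_params(),
                        nu_lumen = -abs(levelset$nu),
                        init_margin = c(lumen = 1.0, media = 1.10),
                        intensity_scale = 255,
                        baseline = c("none", "traditional")) {
  baseline <- match.arg(baseline)
  stopifnot(contourlet$levels >= 1,
            length(contourlet$dfb_levels) == contourlet$levels,
            inherits(diffusion, "ad_params"),
            inherits(levelset, "levelset_params"),
            intensity_scale > 0, all(init_margin > 0),
            init_margin[1] <= 1, init_margin[2] >= 1)
  structure(list(contourlet = contourlet, hough = hough,
                 diffusion = diffusion, levelset = levelset,
                 nu_lumen = nu_lumen, init_margin = init_margin,
                 intensity_scale = intensity_scale,
                 baseline = baseline),
            class = "ivus_config")
}

#' Save / load a pipeline configuration as JSON
#' @param config an [ivus_config()].
#' @param path JSON file path.
#' @return `read_config()` returns an `ivus_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ivus_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- j$diffusion
  l <- j$levelset
  ivus_config(
    contourlet = list(levels = as.integer(j$contourlet$levels),
                      dfb_levels = as.integer(j$contourlet$dfb_levels)),
    hough = j$hough,
    diffusion = ad_params(n_iter = d$n_iter, dt = d$dt,
                          g_thr = d$g_thr, g_scale = d$g_scale,
                          nonstandard_conduction = isTRUE(d$nonstandard_conduction)),
    levelset = levelset_params(mu = l$mu, lam = l$lam, nu = l$nu,
                               alpha = l$alpha, sigma = l$sigma, C = l$C,
                               dt = l$dt, max_iter = l$max_iter, tol = l$tol,
                               refine_iter = l$refine_iter),
    nu_lumen = j$nu_lumen, init_margin = unlist(j$init_margin),
    intensity_scale = j$intensity_scale, baseline = j$baseline)
}

#' Read a grayscale image
#'
#' PNG and TIFF rasters are read into a numeric matrix in [0, 1]; color
#' images are averaged over channels.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @return numeric matrix (rows = image rows, top first).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop(sprintf("unsupported image format '.%s' (PNG/TIFF only)", ext),
                     call. = FALSE))
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3, dim(arr)[3]), drop = FALSE],
                                           c(1, 2), mean)
  check_image(arr)
  arr
}

#' Segment an IVUS cross-section
#'
#' Runs the full method on one image or phantom: contourlet decomposition,
#' multiresolution circular-Hough initialization on the low-pass path,
#' anisotropic-diffusion despeckling on the band-pass path, and two-contour
#' level-set evolution on the filtered image.  With
#' `baseline = "traditional"` in the config the level sets evolve on the raw
#' image with the same initialization, isolating the contribution of the
#' contourlet despeckling.
#'
#' @param input a numeric matrix in [0, 1], a `phantom`, or a file path.
#' @param config an [ivus_config()].
#' @param reference optional list with `lumen` and `media` ground-truth
#'   contours; a `phantom` input supplies its own.
#' @return an object of class `ivus_result`: list with `lumen`, `media`
#'   (final contours), `init` (initialization result), `filtered` (the image
#'   the level sets ran on, 0..1 scale), `diagnostics`, and — when a
#'   reference is available — `metrics` (data frame with per-border MD/RMD).
#' @export
segment_ivus <- function(input, config = ivus_config(), reference = NULL) {
  stopifnot(inherits(config, "ivus_config"))
  if (is.character(input)) input <- read_image(input)
  if (inherits(input, "phantom")) {
    if (is.null(reference))
      reference <- list(lumen = input$lumen_truth, media = input$media_truth)
    input <- input$image
  }
  check_image(input, min_dim = 8L * 2^config$contourlet$levels)

  coeffs <- contourlet_decompose(input, config$contourlet$levels,
                                 config$contourlet$dfb_levels)
  h <- config$hough
  init <- multiresolution_initialize(
    coeffs, init_constraints(h$r_min, h$r_max, h$D_c),
    canny_low = h$canny_low, canny_high = h$canny_high,
    sigma_full = h$sigma_full, sigma_coarse = h$sigma_coarse,
    catheter_radius = h$catheter_radius)

  filtered <- if (config$baseline == "traditional") input else
    despeckle(input, params = config$diffusion, coeffs = coeffs)

  # the balloons are one-directional: start the lumen inside its boundary
  # and the media outside, with margin for the eccentricity a circle misses
  lumen0 <- scale_contour(init$lumen, config$init_margin[1])
  media0 <- scale_contour(init$media, config$init_margin[2])
  seg <- segment(filtered * config$intensity_scale, lumen0, media0,
                 params = config$levelset, nu_lumen = config$nu_lumen)

  metrics <- NULL
  if (!is.null(reference)) {
    ml <- md_rmd(seg$lumen, reference$lumen)
    mm <- md_rmd(seg$media, reference$media)
    metrics <- data.frame(border = c("lumen", "media"),
                          MD = c(ml$MD, mm$MD), RMD = c(ml$RMD, mm$RMD))
  }
  structure(list(lumen = seg$lumen, media = seg$media, init = init,
                 filtered = filtered, diagnostics = seg$diagnostics,
                 metrics = metrics, config = config),
            class = "ivus_result")
}

#' @export
print.ivus_result <- function(x, ...) {
  cat(sprintf("<ivus_result> lumen: %d vertices (converged: %s), media: %d vertices (converged: %s)\n",
              nrow(x$lumen), x$diagnostics$lumen$converged,
              nrow(x$media), x$diagnostics$media$converged))
  if (!is.null(x$metrics)) {
    cat(sprintf("  lumen MD %.2f px / RMD %.2f%%; media MD %.2f px / RMD %.2f%%\n",
                x$metrics$MD[1], x$metrics$RMD[1],
                x$metrics$MD[2], x$metrics$RMD[2]))
  }
  invisible(x)
}

#' Write segmentation artifacts to a directory
#'
#' Writes contour CSVs (`lumen.csv`, `media.csv`), a diagnostics JSON and,
#' optionally, an overlay PNG with both contours burned into the image.
#'
#' @param result an `ivus_result`.
#' @param dir output directory (created if missing).
#' @param image optional image matrix in [0, 1] for the overlay (default:
#'   the filtered image stored in the result).
#' @param overlay write `overlay.png`?
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir, image = result$filtered, overlay = TRUE) {
  stopifnot(inherits(result, "ivus_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contour_csv(result$lumen, file.path(dir, "lumen.csv"))
  write_contour_csv(result$media, file.path(dir, "media.csv"))
  diag <- result$diagnostics
  diag$metrics <- result$metrics
  diag$init <- list(lumen_circle = result$init$lumen_circle,
                    media_circle = result$init$media_circle)
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (overlay && !is.null(image)) {
    rgb <- array(image, c(nrow(image), ncol(image), 3))
    rgb <- burn_contour(rgb, result$lumen, c(1, 0.2, 0.2))
    rgb <- burn_contour(rgb, result$media, c(0.2, 1, 0.2))
    png::writePNG(rgb, file.path(dir, "overlay.png"))
  }
  invisible(dir)
}

burn_contour <- function(rgb, contour, col) {
  dense <- resample_contour(contour, max(720L, 4L * nrow(contour)))
  r <- round(dense$y) + 1L; c <- round(dense$x) + 1L
  ok <- r >= 1 & r <= dim(rgb)[1] & c >= 1 & c <= dim(rgb)[2]
  for (ch in 1:3) rgb[cbind(r[ok], c[ok], ch)] <- col[ch]
  rgb
}

#' Cohort benchmark on simulated phantoms
#'
#' Generates a seeded phantom batch, runs both the full method and the
#' traditional baseline (same level set and initialization on the raw
#' image), and tabulates per-image and mean MD/RMD for both borders.
#'
#' @param n cohort size (default 20).
#' @param seed batch seed.
#' @param base_spec a [phantom_spec()] template.
#' @param config an [ivus_config()]; the baseline flag is set internally.
#' @param methods which methods to run.
#' @param progress print one line per image?
#' @return list with `per_image` (data frame: image, method, border, MD,
#'   RMD) and `summary` (mean MD/RMD by method and border).
#' @export
benchmark_cohort <- function(n = 20L, seed = 1L, base_spec = phantom_spec(),
                             config = ivus_config(),
                             methods = c("proposed", "traditional"),
                             progress = FALSE) {
  phs <- phantom_batch(n, base_spec, seed)
  rows <- list()
  for (m in methods) {
    cfg <- config
    cfg$baseline <- if (m == "traditional") "traditional" else "none"
    for (i in seq_along(phs)) {
      res <- suppressWarnings(segment_ivus(phs[[i]], cfg))
      rows[[length(rows) + 1L]] <- cbind(image = i, method = m, res$metrics)
      if (progress)
        message(sprintf("[%s %2d/%d] lumen MD %.2f, media MD %.2f", m, i, n,
                        res$metrics$MD[1], res$metrics$MD[2]))
    }
  }
  per_image <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(MD, RMD) ~ method + border, per_image, mean)
  list(per_image = per_image, summary = summary)
}
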