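#' Rendering configuration
#'
#' @param pixel_nm Super-resolution pixel size (nm).
#' @param blur_sigma_nm Gaussian sigma per localization (nm), matched to the
#'   lateral localization precision (default 9 nm).
#' @param z_range_nm Pseudo-color z range (+/- nm).
#' @return A list of class `render_config`.
#' @export
render_config <- function(pixel_nm = 10, blur_sigma_nm = 9,
                          z_range_nm = 350) {
  stopifnot(pixel_nm > 0, blur_sigma_nm > 0)
  structure(list(pixel_nm = pixel_nm, blur_sigma_nm = blur_sigma_nm,
                 z_range_nm = z_range_nm), class = "render_config")
}

#' Render a super-resolution image
#'
#' Each localization is drawn as an integrated 2-D Gaussian of standard
#' deviation `blur_sigma_nm` whose total intensity equals its photon count,
#' accumulated on a `pixel_nm` grid; total photons are conserved up to the
#' Gaussian mass outside the image. A companion map carries the
#' photon-weighted mean z per pixel for pseudo-color display over
#' `+/- z_range_nm`.
#'
#' @param locs Localization tibble (kept rows are used when a `keep` column
#'   is present).
#' @param config A [render_config()].
#' @param xlim,ylim Image extents (nm); default the data range padded by
#'   4 sigma.
#' @return A list of class `storm_image`: `intensity` (matrix, rows = y),
#'   `zmean` (matrix, `NA` where empty), `xlim`, `ylim`, `pixel_nm`,
#'   `z_range_nm`, `n_locs`.
#' @export
render_storm <- function(locs, config = render_config(), xlim = NULL,
                         ylim = NULL) {
  if ("keep" %in% names(locs)) locs <- locs[locs$keep, ]
  pad <- 4 * config$blur_sigma_nm
  if (nrow(locs) == 0L) {
    warn("no localizations to render; returning an empty image.")
    img <- matrix(0, 1L, 1L)
    return(structure(list(intensity = img, zmean = img * NA, xlim = c(0, 0),
                          ylim = c(0, 0), pixel_nm = config$pixel_nm,
                          z_range_nm = config$z_range_nm, n_locs = 0L),
                     class = "storm_image"))
  }
  xlim <- xlim %||% (range(locs$x_nm) + c(-pad, pad))
  ylim <- ylim %||% (range(locs$y_nm) + c(-pad, pad))
  p <- config$pixel_nm
  nx <- max(1L, ceiling(diff(xlim) / p))
  ny <- max(1L, ceiling(diff(ylim) / p))
  intensity <- matrix(0, ny, nx)
  zw <- matrix(0, ny, nx) # photon-weighted z sum
  s <- config$blur_sigma_nm
  photons <- if ("photons" %in% names(locs)) locs$photons else rep(1, nrow(locs))
  z <- if ("z_nm" %in% names(locs)) locs$z_nm else rep(NA_real_, nrow(locs))
  for (i in seq_len(nrow(locs))) {
    x <- locs$x_nm[i] - xlim[1L]
    y <- locs$y_nm[i] - ylim[1L]
    c0 <- max(1L, floor((x - 4 * s) / p) + 1L)
    c1 <- min(nx, ceiling((x + 4 * s) / p))
    r0 <- max(1L, floor((y - 4 * s) / p) + 1L)
    r1 <- min(ny, ceiling((y + 4 * s) / p))
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    fx <- pnorm((cols * p - x) / s) - pnorm(((cols - 1L) * p - x) / s)
    fy <- pnorm((rows * p - y) / s) - pnorm(((rows - 1L) * p - y) / s)
    g <- photons[i] * outer(fy, fx)
    intensity[rows, cols] <- intensity[rows, cols] + g
    if (!is.na(z[i])) zw[rows, cols] <- zw[rows, cols] + g * z[i]
  }
  zmean <- zw / intensity
  zmean[!is.finite(zmean)] <- NA_real_
  structure(list(intensity = intensity, zmean = zmean, xlim = xlim,
                 ylim = ylim, pixel_nm = p, z_range_nm = config$z_range_nm,
                 n_locs = nrow(locs)),
            class = "storm_image")
}

#' Write a rendered image to disk
#'
#' Intensity as 32-bit float TIFF; optionally the z pseudo-color view as an
#' 8-bit RGB PNG (rainbow scale over the configured z range; requires the
#' `png` package).
#'
#' @param img A `storm_image`.
#' @param tiff_path Output TIFF path (or `NULL` to skip).
#' @param png_path Output PNG path (or `NULL` to skip).
#' @return The image, invisibly.
#' @export
write_storm_image <- function(img, tiff_path = NULL, png_path = NULL) {
  if (!is.null(tiff_path)) {
    m <- img$intensity / max(img$intensity, 1e-12)
    tiff::writeTIFF(m, tiff_path, bits.per.sample = 32L)
  }
  if (!is.null(png_path)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("the `png` package is required for PNG export.")
    }
    zr <- img$z_range_nm
    zn <- pmin(pmax((img$zmean + zr) / (2 * zr), 0), 1)
    cols <- grDevices::rainbow(256L, start = 0, end = 0.75)
    rgb <- grDevices::col2rgb(cols[pmax(1L, ceiling((1 - zn) * 255))]) / 255
    alpha <- img$intensity / max(img$intensity, 1e-12)
    arr <- array(0, c(nrow(img$intensity), ncol(img$intensity), 3L))
    for (ch in 1:3) {
      m <- matrix(rgb[ch, ], nrow(img$intensity))
      m[is.na(img$zmean)] <- 0
      arr[, , ch] <- m * alpha
    }
    png::writePNG(arr, png_path)
  }
  invisible(img)
}

#' Extract reconstructable regions
#'
#' Connected agglomerations of localizations (via
#' [cluster_localizations()]) whose counts fall within
#' `[min_locs, max_locs]` — the only regions dense enough to reconstruct
#' but not so dense as to be implausible for the labeled target.
#'
#' @param locs Localization tibble (kept rows used).
#' @param min_locs,max_locs Localization-count window.
#' @param eps_nm,min_pts Clustering parameters.
#' @return A tibble with one row per qualifying region: `cluster`,
#'   `n_locs`, `xmin_nm`, `xmax_nm`, `ymin_nm`, `ymax_nm`.
#' @export
extract_regions <- function(locs, min_locs = 100L, max_locs = 3000L,
                            eps_nm = 50, min_pts = 10L) {
  if ("keep" %in% names(locs)) locs <- locs[locs$keep, ]
  if (nrow(locs) == 0L) {
    return(tibble(cluster = integer(), n_locs = integer(),
                  xmin_nm = numeric(), xmax_nm = numeric(),
                  ymin_nm = numeric(), ymax_nm = numeric()))
  }
  cl <- cluster_localizations(locs, eps_nm, min_pts)
  cl <- cl[cl$cluster > 0L, ]
  out <- dplyr::summarise(
    dplyr::group_by(cl, .data$cluster),
    n_locs = dplyr::n(),
    xmin_nm = min(.data$x_nm), xmax_nm = max(.data$x_nm),
    ymin_nm = min(.data$y_nm), ymax_nm = max(.data$y_nm),
    .groups = "drop")
  out[out$n_locs >= min_locs & out$n_locs <= max_locs, ]
}
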