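#' Spot-cleaning thresholds
#'
#' The four cleaning thresholds applied to fitted spots, in the fixed order
#' photons, PSF size, correlation, simultaneous-localization proximity:
#' spots with fewer than 300 photons, a fitted width above 4 pixels, a
#' model-data correlation below 0.95, or a same-frame neighbor closer than
#' 1.2 um are rejected (both members of a close pair are dropped). The axial
#' window `z_range_nm` (+/- 350 nm) is applied after the ellipticity-to-z
#' lookup.
#'
#' @param min_photons Minimum photons per localization.
#' @param max_psf_px Maximum fitted width, camera pixels.
#' @param min_corr Minimum Pearson correlation between fitted model and ROI.
#' @param min_neighbor_um Same-frame nearest-neighbor exclusion radius (um).
#' @param z_range_nm Half-width of the accepted axial window (nm).
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(min_photons = 300, max_psf_px = 4,
                            min_corr = 0.95, min_neighbor_um = 1.2,
                            z_range_nm = 350) {
  stopifnot(min_photons > 0, max_psf_px > 0, min_neighbor_um > 0)
  structure(list(min_photons = min_photons, max_psf_px = max_psf_px,
                 min_corr = min_corr, min_neighbor_um = min_neighbor_um,
                 z_range_nm = z_range_nm), class = "cleaning_config")
}

.blur_mat_cache <- new.env(parent = emptyenv())

# n x n one-dimensional blur operator with reflected edges; cached because
# per-frame filtering reuses the same operator thousands of times
blur_matrix <- function(n, sigma) {
  key <- paste(n, sigma, sep = "|")
  got <- .blur_mat_cache[[key]]
  if (!is.null(got)) return(got)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), 0, sigma)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + seq(-r, r)
    idx <- ifelse(idx < 1L, 1L - idx + 1L, idx) # reflect low edge
    idx <- ifelse(idx > n, 2L * n - idx, idx)   # reflect high edge
    idx <- pmin(pmax(idx, 1L), n)
    for (j in seq_along(idx)) M[i, idx[j]] <- M[i, idx[j]] + k[j]
  }
  .blur_mat_cache[[key]] <- M
  M
}

# separable Gaussian blur with reflected edges
gauss_blur <- function(img, sigma) {
  Kr <- blur_matrix(nrow(img), sigma)
  Kc <- blur_matrix(ncol(img), sigma)
  Kr %*% img %*% t(Kc)
}

#' Band-pass filter a frame
#'
#' Difference-of-Gaussians: a narrow blur at the PSF scale minus a wide
#' blur that carries the slowly varying background. The kernel sums to
#' zero, so constant background is rejected; the operator is linear.
#'
#' @param img Frame matrix.
#' @param sigma_small_px PSF-scale sigma (px).
#' @param sigma_large_px Background-scale sigma (px); default 3x the small.
#' @return Filtered matrix, zero-mean background.
#' @export
bandpass <- function(img, sigma_small_px = 1, sigma_large_px = 3 * sigma_small_px) {
  gauss_blur(img, sigma_small_px) - gauss_blur(img, sigma_large_px)
}

#' Detect candidate spots in a filtered frame
#'
#' Local maxima above `threshold_sd` robust standard deviations (MAD) of the
#' filtered image, with non-maximum suppression over the ROI half-size.
#'
#' @param filtered Band-passed frame.
#' @param threshold_sd Detection threshold in robust SDs.
#' @param roi_half ROI half-size (px); suppression radius.
#' @return A tibble `row`, `col`, `value`, brightest first.
#' @export
detect_candidates <- function(filtered, threshold_sd = 5, roi_half = 5L) {
  m <- detect_core(filtered, threshold_sd, roi_half)
  tibble(row = as.integer(m[, 1L]), col = as.integer(m[, 2L]),
         value = m[, 3L])
}

# matrix core (row, col, value), brightest first
detect_core <- function(filtered, threshold_sd = 5, roi_half = 5L) {
  s <- stats::mad(filtered)
  if (s == 0) s <- sd(filtered)
  thr <- threshold_sd * s
  ny <- nrow(filtered); nx <- ncol(filtered)
  # vectorized 8-neighbor maximum via shifted copies (edges padded -Inf)
  shifted_max <- matrix(-Inf, ny, nx)
  for (dr in -1:1) {
    rs <- max(1L, 1L + dr):min(ny, ny + dr)
    rd <- max(1L, 1L - dr):min(ny, ny - dr)
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      cs <- max(1L, 1L + dc):min(nx, nx + dc)
      cd <- max(1L, 1L - dc):min(nx, nx - dc)
      shifted_max[rd, cd] <- pmax(shifted_max[rd, cd], filtered[rs, cs])
    }
  }
  cand <- which(filtered > thr & filtered >= shifted_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(numeric(0), ncol = 3L))
  v <- filtered[cand]
  o <- order(v, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]; v <- v[o]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1L):nrow(cand)
      too_close <- abs(cand[later, 1L] - cand[i, 1L]) <= roi_half &
        abs(cand[later, 2L] - cand[i, 2L]) <= roi_half
      keep[later][too_close] <- FALSE
    }
  }
  cbind(cand[keep, 1L], cand[keep, 2L], v[keep])
}

#' Fit an elliptical Gaussian to one ROI
#'
#' Nonlinear least squares (Levenberg-Marquardt) of an axis-aligned
#' elliptical Gaussian plus constant background on a photon-converted ROI.
#' The in-plane position is read directly from the fit; `photons` is the
#' integrated amplitude `2 pi A sx sy`; `corr` is the Pearson correlation
#' between the fitted model and the data over the ROI. Non-convergence
#' returns `converged = FALSE` (downstream the spot is rejected via the
#' correlation rule).
#'
#' @param roi Square ROI matrix in camera counts.
#' @param camera A [camera_model()] (baseline and gain for photon
#'   conversion).
#' @return One-row tibble: `x_px`, `y_px` (ROI pixel-center coordinates),
#'   `wx_nm`, `wy_nm`, `photons`, `background`, `corr`, `converged`.
#' @export
fit_spot <- function(roi, camera = camera_model()) {
  v <- fit_spot_core(roi, camera)
  tibble(x_px = v[[1L]], y_px = v[[2L]], wx_nm = v[[3L]], wy_nm = v[[4L]],
         photons = v[[5L]], background = v[[6L]], corr = v[[7L]],
         converged = v[[8L]] > 0)
}

# numeric-vector core used in the per-frame loop:
# (x_px, y_px, wx_nm, wy_nm, photons, background, corr, converged)
fit_spot_core <- function(roi, camera) {
  ph <- (roi - camera$baseline) / camera$counts_per_photon
  n <- nrow(roi)
  px <- seq_len(n)
  gx <- matrix(px, n, n, byrow = TRUE)
  gy <- matrix(px, n, n)
  b0 <- median(ph)
  a0 <- max(ph) - b0
  w <- pmax(ph - b0, 0)
  tot <- sum(w)
  x0 <- if (tot > 0) sum(w * gx) / tot else (n + 1) / 2
  y0 <- if (tot > 0) sum(w * gy) / tot else (n + 1) / 2
  model <- function(p) {
    p[1] + p[2] * exp(-(gx - p[3])^2 / (2 * p[5]^2) -
                        (gy - p[4])^2 / (2 * p[6]^2))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(b0, max(a0, 1), x0, y0, 1.2, 1.2),
      fn = function(p) as.vector(model(p) - ph),
      lower = c(-Inf, 0, 0.5, 0.5, 0.3, 0.3),
      upper = c(Inf, Inf, n + 0.5, n + 0.5, n, n),
      control = minpack.lm::nls.lm.control(maxiter = 60)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0L, 9L)) {
    return(c(x0, y0, NA_real_, NA_real_, 0, b0, 0, 0))
  }
  p <- fit$par
  m <- model(p)
  corr <- suppressWarnings(stats::cor(as.vector(m), as.vector(ph)))
  if (!is.finite(corr)) corr <- 0
  c(p[3], p[4], p[5] * camera$pixel_nm, p[6] * camera$pixel_nm,
    2 * pi * p[2] * p[5] * p[6], p[1], corr, 1)
}

#' Apply the cleaning thresholds to fitted spots
#'
#' Pure filter over a localization table: flags each spot with `keep` and
#' the first failing rule in `reject_reason` (one of `photons`, `psf_size`,
#' `corr`, `proximity`, `none`), applying the rules in that fixed order.
#' The proximity rule drops both members of any same-frame pair closer than
#' `min_neighbor_um` among the spots that survived the first three rules.
#' Idempotent; never adds rows.
#'
#' @param spots Localization tibble with at least `frame`, `x_nm`, `y_nm`,
#'   `photons`, `wx_nm`, `wy_nm`, `corr`.
#' @param config A [cleaning_config()].
#' @param pixel_nm Camera pixel size (nm), for the PSF-size rule.
#' @return `spots` with `keep` and `reject_reason` columns replaced.
#' @export
clean_spots <- function(spots, config = cleaning_config(), pixel_nm = 160) {
  if (nrow(spots) == 0L) {
    spots$keep <- logical(0)
    spots$reject_reason <- character(0)
    return(spots)
  }
  reason <- rep("none", nrow(spots))
  wmax <- pmax(spots$wx_nm, spots$wy_nm)
  bad_w <- is.na(wmax) | wmax > config$max_psf_px * pixel_nm
  reason[bad_w] <- "psf_size"
  reason[spots$corr < config$min_corr & reason == "none"] <- "corr"
  reason[spots$photons < config$min_photons] <- "photons" # highest priority
  # proximity among survivors, per frame
  surv <- which(reason == "none")
  if (length(surv) > 1L) {
    d_nm <- config$min_neighbor_um * 1000
    by_frame <- split(surv, spots$frame[surv])
    for (idx in by_frame) {
      if (length(idx) < 2L) next
      dm <- as.matrix(dist(cbind(spots$x_nm[idx], spots$y_nm[idx])))
      diag(dm) <- Inf
      close <- apply(dm < d_nm, 1L, any)
      reason[idx[close]] <- "proximity"
    }
  }
  spots$keep <- reason == "none"
  spots$reject_reason <- reason
  spots
}

movie_parts <- function(movie) {
  if (inherits(movie, "sim_movie")) {
    list(frames = movie$frames, meta = movie$meta)
  } else if (is.list(movie) && !is.null(movie$frames)) {
    list(frames = movie$frames, meta = movie$meta)
  } else if (is.character(movie) && length(movie) == 1L) {
    read_movie(movie)
  } else {
    abort("`movie` must be a sim_movie, a frames+meta list, or a path prefix.")
  }
}

#' Localize an entire movie
#'
#' Per-frame pipeline: band-pass filter, candidate detection, elliptical
#' Gaussian fitting, ellipticity-to-z lookup, then the cleaning thresholds
#' and the axial window. Deterministic for fixed inputs.
#'
#' @param movie A `sim_movie`, a `frames` + `meta` list from [read_movie()],
#'   or a path prefix.
#' @param cal A [calibration_model()]; when `NULL`, rebuilt from the
#'   metadata sidecar.
#' @param cleaning A [cleaning_config()].
#' @param threshold_sd Detection threshold (robust SDs of the filtered
#'   frame).
#' @param roi_half ROI half-size in px (ROI is `2 roi_half + 1` square).
#' @param keep_rejected Keep rejected rows in the output (default TRUE;
#'   filter on `keep`).
#' @return Localization tibble: `frame`, `x_nm`, `y_nm`, `z_nm`, `photons`,
#'   `wx_nm`, `wy_nm`, `corr`, `keep`, `reject_reason`.
#' @export
localize_movie <- function(movie, cal = NULL, cleaning = cleaning_config(),
                           threshold_sd = 5, roi_half = 5L,
                           keep_rejected = TRUE) {
  mp <- movie_parts(movie)
  meta <- mp$meta
  for (key in c("pixel_nm", "frame_rate", "baseline", "counts_per_photon")) {
    if (is.null(meta[[key]])) {
      abort(sprintf("metadata sidecar is missing required key `%s`.", key))
    }
  }
  if (is.null(cal)) {
    cc <- meta$calibration
    if (is.null(cc)) abort("metadata sidecar is missing required key `calibration`.")
    cal <- calibration_model(cc$w0, cc$gamma, cc$d, cc$A, cc$B, cc$z_range)
  }
  cam <- camera_model(pixel_nm = meta$pixel_nm,
                      counts_per_photon = meta$counts_per_photon,
                      baseline = meta$baseline)
  sigma_px <- cal$w0 / cam$pixel_nm
  out <- vector("list", length(mp$frames))
  for (f in seq_along(mp$frames)) {
    img <- mp$frames[[f]]
    filt <- bandpass(img, sigma_px)
    cand <- detect_core(filt, threshold_sd, roi_half)
    if (nrow(cand) == 0L) next
    ny <- nrow(img); nx <- ncol(img)
    rows <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1L]; c <- cand[i, 2L]
      if (r <= roi_half || r > ny - roi_half ||
          c <= roi_half || c > nx - roi_half) next
      roi <- img[(r - roi_half):(r + roi_half), (c - roi_half):(c + roi_half)]
      ft <- fit_spot_core(roi, cam)
      rows[[i]] <- c(
        f,
        (c - roi_half - 1L + ft[[1L]] - 0.5) * cam$pixel_nm,
        (r - roi_half - 1L + ft[[2L]] - 0.5) * cam$pixel_nm,
        ft[[5L]], ft[[3L]], ft[[4L]], ft[[7L]])
    }
    out[[f]] <- rows
  }
  rows <- unlist(out, recursive = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  spots <- if (length(rows) > 0L) {
    m <- do.call(rbind, rows)
    tibble(frame = as.integer(m[, 1L]), x_nm = m[, 2L], y_nm = m[, 3L],
           photons = m[, 4L], wx_nm = m[, 5L], wy_nm = m[, 6L],
           corr = m[, 7L])
  } else {
    tibble(frame = integer())
  }
  if (nrow(spots) == 0L) {
    return(tibble(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                  z_nm = numeric(), photons = numeric(), wx_nm = numeric(),
                  wy_nm = numeric(), corr = numeric(), keep = logical(),
                  reject_reason = character()))
  }
  spots <- clean_spots(spots, cleaning, cam$pixel_nm)
  spots$z_nm <- z_lookup(spots$wx_nm, spots$wy_nm, cal)
  bad_z <- spots$keep & (is.na(spots$z_nm) |
                           abs(spots$z_nm) > cleaning$z_range_nm)
  spots$keep[bad_z] <- FALSE
  spots$reject_reason[bad_z] <- "z_range"
  spots <- dplyr::relocate(spots, "frame", "x_nm", "y_nm", "z_nm", "photons",
                           "wx_nm", "wy_nm", "corr", "keep", "reject_reason")
  if (!keep_rejected) spots <- spots[spots$keep, ]
  spots
}

#' Write / read a localization table
#'
#' CSV with the canonical header `frame,x_nm,y_nm,z_nm,photons,wx_nm,
#' wy_nm,corr,keep,reject_reason`; missing z is written as an empty field.
#'
#' @param locs Localization tibble.
#' @param path CSV path.
#' @return `write_localizations()` the input invisibly;
#'   `read_localizations()` the tibble.
#' @export
write_localizations <- function(locs, path) {
  readr::write_csv(locs, path, na = "")
  invisible(locs)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    frame = readr::col_integer(),
                    keep = readr::col_logical(),
                    reject_reason = readr::col_character(),
                    .default = readr::col_double()))
}
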