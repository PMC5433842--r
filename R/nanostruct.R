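#' Nanostructure candidate filter configuration
#'
#' The six empirically stringent criteria applied to every localization
#' cluster before it is accepted as an MB-labeled DNA nanostructure:
#' (1) centroid inside the nucleus; (2) farther than `bead_exclusion_nm`
#' from every fiducial bead; (3) not temporally concentrated (a cluster
#' with `temporal_conc_frac` of its localizations inside one contiguous
#' window of `temporal_window_frac` of the acquisition is transient noise);
#' (4) localization density at least `min_density_um2`; (5) between
#' `min_locs` and `max_locs` localizations; (6) convex-hull area at most
#' `max_area_um2`.
#'
#' @param min_locs,max_locs Localization-count window (100-3000).
#' @param max_area_um2 Maximum projected lateral area (um^2).
#' @param min_density_um2 Minimum localization density (locs/um^2);
#'   defaults to `min_locs / max_area_um2` (500).
#' @param temporal_window_frac Width of the temporal-concentration window,
#'   as a fraction of the acquisition.
#' @param temporal_conc_frac Fraction of localizations inside one window
#'   that marks a cluster as transient.
#' @param bead_exclusion_nm Minimum centroid distance to any bead (nm);
#'   bead diameter 200 nm plus margin.
#' @param nucleus_mask Polygon list `(x_nm, y_nm)`, or `NULL` for
#'   accept-all.
#' @return A list of class `candidate_filter_config`.
#' @export
candidate_filter_config <- function(min_locs = 100L, max_locs = 3000L,
                                    max_area_um2 = 0.2,
                                    min_density_um2 = NULL,
                                    temporal_window_frac = 0.05,
                                    temporal_conc_frac = 0.8,
                                    bead_exclusion_nm = 300,
                                    nucleus_mask = NULL) {
  stopifnot(min_locs < max_locs, max_area_um2 > 0)
  min_density_um2 <- min_density_um2 %||% (min_locs / max_area_um2)
  structure(list(min_locs = as.integer(min_locs),
                 max_locs = as.integer(max_locs),
                 max_area_um2 = max_area_um2,
                 min_density_um2 = min_density_um2,
                 temporal_window_frac = temporal_window_frac,
                 temporal_conc_frac = temporal_conc_frac,
                 bead_exclusion_nm = bead_exclusion_nm,
                 nucleus_mask = nucleus_mask),
            class = "candidate_filter_config")
}

# ray-casting point-in-polygon
point_in_polygon <- function(px, py, poly) {
  x <- poly$x_nm; y <- poly$y_nm
  n <- length(x)
  j <- n
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# convex hull area (shoelace), nm^2
hull_area_nm2 <- function(x, y) {
  if (length(x) < 3L) return(0)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
}

# largest fraction of sorted frames inside one contiguous window of length w
max_window_frac <- function(frames, w) {
  f <- sort(frames)
  n <- length(f)
  if (n == 0L) return(0)
  best <- 0L
  j <- 1L
  for (i in seq_len(n)) {
    while (j <= n && f[j] - f[i] <= w) j <- j + 1L
    best <- max(best, j - i)
  }
  best / n
}

#' Apply the six nanostructure acceptance criteria
#'
#' Evaluates every cluster of a field against
#' [candidate_filter_config()]. All six verdicts are recorded for every
#' cluster (evaluation does not stop at the first failure), and a cluster
#' is accepted exactly when all six pass; the outcome is independent of
#' the order of evaluation.
#'
#' @param clustered Localization tibble with a `cluster` column (from
#'   [cluster_localizations()]); cluster 0 (noise) is ignored.
#' @param config A [candidate_filter_config()].
#' @param beads Optional tibble of bead positions (`x_nm`, `y_nm`), e.g.
#'   `attr(trace, "bead_positions")` from [track_fiducials()].
#' @param n_frames Total frames in the acquisition; defaults to
#'   `max(clustered$frame)`.
#' @return A tibble of class `nanostructure_candidates`: one row per
#'   cluster with `cluster`, `n_locs`, `centroid_x_nm`, `centroid_y_nm`,
#'   `area_um2`, `density_um2`, `frame_conc`, the six verdicts
#'   (`in_nucleus`, `clear_of_beads`, `temporally_spread`, `dense_enough`,
#'   `n_locs_ok`, `area_ok`) and `accepted`.
#' @export
apply_criteria <- function(clustered, config = candidate_filter_config(),
                           beads = NULL, n_frames = NULL) {
  stopifnot("cluster" %in% names(clustered))
  n_frames <- n_frames %||% suppressWarnings(max(clustered$frame, 1L))
  w <- config$temporal_window_frac * n_frames
  cl_ids <- sort(unique(clustered$cluster[clustered$cluster > 0L]))
  rows <- lapply(cl_ids, function(id) {
    cc <- clustered[clustered$cluster == id, ]
    cx <- mean(cc$x_nm); cy <- mean(cc$y_nm)
    area <- hull_area_nm2(cc$x_nm, cc$y_nm) / 1e6 # um^2
    dens <- if (area > 0) nrow(cc) / area else Inf
    fc <- max_window_frac(cc$frame, w)
    bead_d <- if (!is.null(beads) && nrow(beads) > 0L) {
      sqrt(min((beads$x_nm - cx)^2 + (beads$y_nm - cy)^2))
    } else Inf
    tibble(
      cluster = id, n_locs = nrow(cc),
      centroid_x_nm = cx, centroid_y_nm = cy,
      area_um2 = area, density_um2 = dens, frame_conc = fc,
      bead_dist_nm = bead_d,
      in_nucleus = if (is.null(config$nucleus_mask)) TRUE else
        point_in_polygon(cx, cy, config$nucleus_mask),
      clear_of_beads = bead_d > config$bead_exclusion_nm,
      temporally_spread = fc < config$temporal_conc_frac,
      dense_enough = dens >= config$min_density_um2,
      n_locs_ok = nrow(cc) >= config$min_locs & nrow(cc) <= config$max_locs,
      area_ok = area <= config$max_area_um2)
  })
  out <- if (length(rows) == 0L) {
    tibble(cluster = integer(), n_locs = integer(), centroid_x_nm = numeric(),
           centroid_y_nm = numeric(), area_um2 = numeric(),
           density_um2 = numeric(), frame_conc = numeric(),
           bead_dist_nm = numeric(), in_nucleus = logical(),
           clear_of_beads = logical(), temporally_spread = logical(),
           dense_enough = logical(), n_locs_ok = logical(),
           area_ok = logical())
  } else {
    dplyr::bind_rows(rows)
  }
  out$accepted <- out$in_nucleus & out$clear_of_beads &
    out$temporally_spread & out$dense_enough & out$n_locs_ok & out$area_ok
  class(out) <- c("nanostructure_candidates", class(out))
  out
}

#' Cross-section profile of a candidate with Gaussian fit
#'
#' Projects localizations onto a line (or onto the z axis), bins them, and
#' fits one or two Gaussians by nonlinear least squares. FWHM is reported
#' as `2 sqrt(2 ln 2) sigma` per component, and the peak separation for
#' two components.
#'
#' @param locs Localization tibble (e.g. one cluster).
#' @param line 2x2 matrix of endpoints (rows = points, cols = x, y in nm);
#'   ignored when `axis = "z"`.
#' @param axis `"line"` (project onto `line`) or `"z"` (profile of z
#'   coordinates).
#' @param bin_nm Histogram bin width (nm).
#' @param n_components 1 or 2 Gaussian components.
#' @return A list of class `profile_fit`: `histogram` (tibble `position_nm`,
#'   `count`), `components` (tibble `component`, `mean_nm`, `sigma_nm`,
#'   `fwhm_nm`, `amplitude`), `separation_nm` (two components only),
#'   `converged`.
#' @export
cross_section_profile <- function(locs, line = NULL,
                                  axis = c("line", "z"), bin_nm = 10,
                                  n_components = 1L) {
  axis <- match.arg(axis)
  if ("keep" %in% names(locs)) locs <- locs[locs$keep, ]
  t <- if (axis == "z") {
    locs$z_nm[!is.na(locs$z_nm)]
  } else {
    if (is.null(line)) abort("`line` endpoints required for axis = \"line\".")
    a <- as.numeric(line[1L, ]); b <- as.numeric(line[2L, ])
    u <- (b - a) / sqrt(sum((b - a)^2))
    (locs$x_nm - a[1L]) * u[1L] + (locs$y_nm - a[2L]) * u[2L]
  }
  if (length(t) < max(5L, 3L * n_components)) {
    abort("too few localizations for a profile fit.")
  }
  breaks <- seq(floor(min(t) / bin_nm) * bin_nm,
                ceiling(max(t) / bin_nm) * bin_nm + bin_nm, by = bin_nm)
  h <- graphics::hist(t, breaks = breaks, plot = FALSE)
  hist_tb <- tibble(position_nm = h$mids, count = h$counts)
  x <- h$mids; y <- h$counts
  fit1 <- function() {
    st <- c(A = max(y), mu = x[which.max(y)], s = max(sd(t), bin_nm / 2))
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                      start = as.list(st), lower = c(0, min(x), bin_nm / 10),
                      control = stats::nls.control(maxiter = 200))
  }
  fit2 <- function() {
    qs <- quantile(t, c(0.25, 0.75))
    st <- list(A1 = max(y), m1 = qs[[1L]], s1 = max(sd(t) / 2, bin_nm / 2),
               A2 = max(y), m2 = qs[[2L]], s2 = max(sd(t) / 2, bin_nm / 2))
    minpack.lm::nlsLM(y ~ A1 * exp(-(x - m1)^2 / (2 * s1^2)) +
                        A2 * exp(-(x - m2)^2 / (2 * s2^2)),
                      start = st,
                      lower = c(0, min(x), bin_nm / 10, 0, min(x), bin_nm / 10),
                      control = stats::nls.control(maxiter = 400))
  }
  k_fwhm <- 2 * sqrt(2 * log(2))
  fit <- tryCatch(if (n_components == 1L) fit1() else fit2(),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(histogram = hist_tb, components = NULL,
                          separation_nm = NA_real_, converged = FALSE),
                     class = "profile_fit"))
  }
  p <- stats::coef(fit)
  comp <- if (n_components == 1L) {
    tibble(component = 1L, mean_nm = p[["mu"]], sigma_nm = p[["s"]],
           fwhm_nm = k_fwhm * p[["s"]], amplitude = p[["A"]])
  } else {
    tibble(component = 1:2, mean_nm = c(p[["m1"]], p[["m2"]]),
           sigma_nm = c(p[["s1"]], p[["s2"]]),
           fwhm_nm = k_fwhm * c(p[["s1"]], p[["s2"]]),
           amplitude = c(p[["A1"]], p[["A2"]]))
  }
  structure(list(histogram = hist_tb, components = comp,
                 separation_nm = if (n_components == 2L) {
                   abs(diff(comp$mean_nm))
                 } else NA_real_,
                 converged = TRUE),
            class = "profile_fit")
}
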