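#' Default photophysics of the simulated dye
#'
#' Rates of the three-state (fluorescent / dark / bleached) blinking model.
#' The defaults describe an Alexa-647-like photoswitch under imaging
#' conditions where the 405-nm reactivation is folded into `k_on`: mean
#' on-time `1/k_off = 20 ms` (about 1.7 frames at 85 Hz), mean number of
#' switching events before photobleaching `(k_off + k_bleach)/k_bleach ~ 30`,
#' and dark-state recovery fast enough that the blinking budget is spent
#' within a 36000-frame, 85 Hz acquisition. Under these rates a fluorophore
#' yields on the order of 10-100 localizations per acquisition.
#'
#' @param k_on Dark -> fluorescent rate (1/s).
#' @param k_off Fluorescent -> dark rate (1/s).
#' @param k_bleach Fluorescent -> bleached rate (1/s).
#' @param photons Mean photons detected per fully-on frame.
#' @return A named list.
#' @export
dye_kinetics <- function(k_on = 0.5, k_off = 50, k_bleach = 1.7,
                         photons = 3000) {
  stopifnot(k_on >= 0, k_off >= 0, k_bleach >= 0, photons > 0)
  list(k_on = k_on, k_off = k_off, k_bleach = k_bleach, photons = photons)
}

#' Simulate a blinking state trace
#'
#' Frame-resolution realization of the three-state Markov chain
#' fluorescent(1) / dark(0) / bleached(2). Sojourn times are geometric with
#' the per-frame exponential transition probabilities; once bleached the
#' emitter stays dark forever. Identical inputs (including `seed`) give an
#' identical trace.
#'
#' @param kinetics A [dye_kinetics()] list.
#' @param n_frames Number of frames.
#' @param frame_rate Frames per second.
#' @param seed Integer seed; when `NULL` the current RNG stream is used.
#' @param initial Initial state, `"on"` (default) or `"dark"`.
#' @return Integer vector of length `n_frames` (0 dark, 1 on, 2 bleached).
#' @export
simulate_blink_trace <- function(kinetics = dye_kinetics(), n_frames,
                                 frame_rate = 85, seed = NULL,
                                 initial = c("on", "dark")) {
  initial <- match.arg(initial)
  run <- function() {
    dt <- 1 / frame_rate
    p_leave_on <- 1 - exp(-(kinetics$k_off + kinetics$k_bleach) * dt)
    p_bleach_branch <- if (kinetics$k_off + kinetics$k_bleach > 0) {
      kinetics$k_bleach / (kinetics$k_off + kinetics$k_bleach)
    } else 0
    p_wake <- 1 - exp(-kinetics$k_on * dt)
    state <- integer(n_frames)
    t <- 0L
    cur <- if (initial == "on") 1L else 0L
    while (t < n_frames) {
      if (cur == 1L) {
        len <- if (p_leave_on > 0) rgeom(1L, p_leave_on) + 1L else n_frames
        len <- min(len, n_frames - t)
        state[(t + 1L):(t + len)] <- 1L
        t <- t + len
        if (t >= n_frames) break
        cur <- if (runif(1L) < p_bleach_branch) 2L else 0L
      } else if (cur == 0L) {
        len <- if (p_wake > 0) rgeom(1L, p_wake) + 1L else n_frames
        len <- min(len, n_frames - t)
        t <- t + len
        if (t >= n_frames) break
        cur <- 1L
      } else {
        break # bleached: remaining frames stay 0 in `state`, marked below
      }
    }
    if (cur == 2L && t < n_frames) state[(t + 1L):n_frames] <- 2L
    state
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Count switching events in a blink trace
#'
#' One switching event — one localization, in the STORM sense — is one
#' maximal run of fluorescent frames.
#'
#' @param trace Integer state trace from [simulate_blink_trace()].
#' @return Integer burst count.
#' @export
count_blink_bursts <- function(trace) {
  r <- rle(trace == 1L)
  sum(r$values)
}

#' Stage-drift trace generators
#'
#' `drift_linear()` produces a constant-velocity stage drift;
#' `drift_random_walk()` a Gaussian random walk. Both start at (0, 0) in
#' frame 1.
#'
#' @param n_frames Number of frames.
#' @param rate_nm_per_frame Length-2 numeric, (dx, dy) velocity.
#' @param step_sd_nm Per-frame step standard deviation.
#' @param seed Optional integer seed for the random walk.
#' @return A tibble `frame`, `dx_nm`, `dy_nm`.
#' @export
drift_linear <- function(n_frames, rate_nm_per_frame = c(0.02, 0.015)) {
  tibble(frame = seq_len(n_frames),
         dx_nm = (seq_len(n_frames) - 1L) * rate_nm_per_frame[1],
         dy_nm = (seq_len(n_frames) - 1L) * rate_nm_per_frame[2])
}

#' @rdname drift_linear
#' @export
drift_random_walk <- function(n_frames, step_sd_nm = 0.3, seed = NULL) {
  run <- function() {
    tibble(frame = seq_len(n_frames),
           dx_nm = cumsum(c(0, rnorm(n_frames - 1L, 0, step_sd_nm))),
           dy_nm = cumsum(c(0, rnorm(n_frames - 1L, 0, step_sd_nm))))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' EMCCD camera description
#'
#' @param pixel_nm Back-projected pixel size (nm).
#' @param counts_per_photon Overall gain, camera counts per detected photon.
#' @param read_noise_counts Gaussian read noise (counts, sd).
#' @param baseline Camera offset (counts).
#' @param background_photons Mean background photons per pixel per frame.
#' @return A named list.
#' @export
camera_model <- function(pixel_nm = 160, counts_per_photon = 5,
                         read_noise_counts = 10, baseline = 100,
                         background_photons = 5) {
  stopifnot(pixel_nm > 0, counts_per_photon > 0)
  list(pixel_nm = pixel_nm, counts_per_photon = counts_per_photon,
       read_noise_counts = read_noise_counts, baseline = baseline,
       background_photons = background_photons)
}

#' Construct a simulation scene
#'
#' Low-level constructor; most users will call [preset_scene()]. Emitters
#' are a tibble with columns `id`, `kind` (`"dye"`, `"bead"`,
#' `"autofluor"`), `x_nm`, `y_nm`, `z_nm`, `k_on`, `k_off`, `k_bleach`,
#' `photons`.
#'
#' @param emitters Emitter tibble (see above).
#' @param field_um Side length of the square field of view (um).
#' @param n_frames,frame_rate Acquisition length (frames) and rate (Hz).
#' @param drift Drift trace tibble (`frame`, `dx_nm`, `dy_nm`), one row per
#'   frame, or `NULL` for no drift.
#' @param camera A [camera_model()].
#' @param nucleus_mask Polygon list `(x_nm, y_nm)` delimiting the nucleus, or
#'   `NULL` for accept-all.
#' @return A list of class `sim_scene`.
#' @export
sim_scene <- function(emitters, field_um = 14, n_frames = 18000,
                      frame_rate = 85, drift = NULL,
                      camera = camera_model(), nucleus_mask = NULL) {
  stopifnot(n_frames >= 1, field_um > 0)
  if (is.null(drift)) drift <- drift_linear(n_frames, c(0, 0))
  if (nrow(drift) != n_frames) abort("drift trace length must equal n_frames.")
  z_max <- max(abs(emitters$z_nm), 0)
  structure(list(emitters = emitters, field_um = field_um,
                 n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 drift = drift, camera = camera,
                 nucleus_mask = nucleus_mask),
            class = "sim_scene")
}

# rejection-sample n points with pairwise min distance and edge margin,
# uniform over the field (nm); deterministic under the ambient RNG
place_points <- function(n, field_nm, min_sep_nm, margin_nm,
                         avoid = NULL, avoid_nm = 0) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(pts) < n && tries < 20000L) {
    tries <- tries + 1L
    p <- runif(2, margin_nm, field_nm - margin_nm)
    ok <- TRUE
    if (nrow(pts) > 0) {
      ok <- all(sqrt(rowSums(sweep(pts, 2, p)^2)) >= min_sep_nm)
    }
    if (ok && !is.null(avoid)) {
      ok <- all(sqrt(rowSums(sweep(avoid, 2, p)^2)) >= avoid_nm)
    }
    if (ok) pts <- rbind(pts, p)
  }
  if (nrow(pts) < n) abort("could not place points with requested spacing.")
  pts
}

#' Preset simulation scenes
#'
#' Ready-made ground-truth scenes for the imaging conditions the pipeline is
#' tested against:
#' \describe{
#'   \item{uniform_sparse}{dyes scattered uniformly at `dye_density_um2`
#'     (default 0.5/um^2), emulating sparse non-specific nuclear labeling.}
#'   \item{uniform_extreme_sparse}{as above at 0.2/um^2.}
#'   \item{nanostructure}{`n_dyes` (default 29) dyes confined to a disc of
#'     `disc_area_um2` (default 0.15 um^2, under the 0.2 um^2 candidate
#'     limit) at a random in-nucleus position, plus autofluorescence and
#'     beads: the labeled-DNA scene.}
#'   \item{blank_control}{autofluorescence and beads only (negative
#'     control).}
#'   \item{beads_only}{fiducial beads only.}
#' }
#' All scenes (except `beads_only`) carry sparse autofluorescence background
#' events and at least three fiducial beads (mutually >= 2.5 um apart, kept
#' clear of the nanostructure), an elliptical nucleus mask, and a linear
#' stage drift.
#'
#' @param kind Preset name.
#' @param params Named list of overrides: `field_um`, `n_frames`,
#'   `frame_rate`, `n_dyes`, `disc_area_um2`, `dye_density_um2`,
#'   `autofluor_density_um2`, `autofluor_photons`, `autofluor_k_on`,
#'   `n_beads`, `bead_photons`, `drift` (a trace tibble), `dye`
#'   (a [dye_kinetics()] list), `camera` (a [camera_model()]).
#' @param seed Integer seed; scene construction is deterministic given
#'   (kind, params, seed).
#' @return A [sim_scene()] with attribute `truth` holding ground-truth
#'   placement info (`structure_centroid_nm` for the nanostructure preset).
#' @export
preset_scene <- function(kind = c("uniform_sparse", "uniform_extreme_sparse",
                                  "nanostructure", "blank_control",
                                  "beads_only"),
                         params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(
    field_um = 14, n_frames = 18000L, frame_rate = 85,
    n_dyes = 29L, disc_area_um2 = 0.15,
    dye_density_um2 = if (kind == "uniform_extreme_sparse") 0.2 else 0.5,
    autofluor_density_um2 = 2, autofluor_photons = 350,
    autofluor_k_on = 0.002, autofluor_k_off = 80,
    n_beads = 3L, bead_photons = 20000,
    drift = NULL, dye = dye_kinetics(), camera = camera_model()
  ), params)
  field_nm <- p$field_um * 1000
  withr::with_seed(seed, {
    emit <- list()
    # elliptical nucleus mask covering most of the field
    th <- seq(0, 2 * pi, length.out = 73L)[-73L]
    mask <- list(x_nm = field_nm / 2 + 0.42 * field_nm * cos(th),
                 y_nm = field_nm / 2 + 0.42 * field_nm * sin(th))
    structure_centroid <- NULL
    center <- NULL
    r_nm <- sqrt(p$disc_area_um2 / pi) * 1000
    if (kind == "nanostructure") {
      # the labeled structure goes first, well inside the nucleus; beads are
      # then kept clear of it so the scene represents the analyzable case
      center <- place_points(1L, field_nm, 0, 0.25 * field_nm)
    }
    beads <- NULL
    if (p$n_beads > 0) {
      # spacing adapts to small fields; the edge margin keeps beads clear
      # of the fitting ROI border on pipeline-sized fields
      bead_sep <- min(2500, field_nm / p$n_beads)
      bead_margin <- min(1000, field_nm / 4)
      beads <- place_points(p$n_beads, field_nm, bead_sep, bead_margin,
                            avoid = center, avoid_nm = 1500 + r_nm)
    }
    if (kind == "nanostructure") {
      ang <- runif(p$n_dyes, 0, 2 * pi)
      rad <- r_nm * sqrt(runif(p$n_dyes))
      z0 <- runif(1, -150, 150)
      emit$dyes <- tibble(
        kind = "dye",
        x_nm = center[1, 1] + rad * cos(ang),
        y_nm = center[1, 2] + rad * sin(ang),
        z_nm = pmax(pmin(z0 + rnorm(p$n_dyes, 0, 40), 340), -340),
        k_on = p$dye$k_on, k_off = p$dye$k_off, k_bleach = p$dye$k_bleach,
        photons = p$dye$photons)
      structure_centroid <- c(x = mean(emit$dyes$x_nm),
                              y = mean(emit$dyes$y_nm))
    } else if (kind %in% c("uniform_sparse", "uniform_extreme_sparse")) {
      n <- rpois(1L, p$dye_density_um2 * p$field_um^2)
      emit$dyes <- tibble(
        kind = "dye", x_nm = runif(n, 0, field_nm),
        y_nm = runif(n, 0, field_nm), z_nm = runif(n, -300, 300),
        k_on = p$dye$k_on, k_off = p$dye$k_off, k_bleach = p$dye$k_bleach,
        photons = p$dye$photons)
    }
    if (kind != "beads_only") {
      n_auto <- rpois(1L, p$autofluor_density_um2 * p$field_um^2)
      if (n_auto > 0) {
        emit$auto <- tibble(
          kind = "autofluor", x_nm = runif(n_auto, 0, field_nm),
          y_nm = runif(n_auto, 0, field_nm), z_nm = runif(n_auto, -300, 300),
          k_on = p$autofluor_k_on, k_off = p$autofluor_k_off, k_bleach = 0,
          photons = p$autofluor_photons)
      }
    }
    if (!is.null(beads)) {
      emit$beads <- tibble(kind = "bead", x_nm = beads[, 1],
                           y_nm = beads[, 2], z_nm = 0,
                           k_on = 0, k_off = 0, k_bleach = 0,
                           photons = p$bead_photons)
    }
    emitters <- dplyr::bind_rows(emit)
    if (nrow(emitters) == 0L) {
      emitters <- tibble(kind = character(), x_nm = numeric(),
                         y_nm = numeric(), z_nm = numeric(), k_on = numeric(),
                         k_off = numeric(), k_bleach = numeric(),
                         photons = numeric())
    }
    emitters <- dplyr::mutate(emitters, id = dplyr::row_number(),
                              .before = 1L)
    drift <- p$drift %||% drift_linear(p$n_frames)
    scene <- sim_scene(emitters, field_um = p$field_um,
                       n_frames = p$n_frames, frame_rate = p$frame_rate,
                       drift = drift, camera = p$camera, nucleus_mask = mask)
    attr(scene, "truth") <- list(kind = kind, seed = seed,
                                 structure_centroid_nm = structure_centroid)
    scene
  })
}
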