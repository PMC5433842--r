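#' Track fiducial beads and estimate the stage-drift trace
#'
#' Fiducial beads are near-continuously emissive, unlike blinking dyes, so
#' they are identified as localizations persistent across the acquisition:
#' either the caller supplies seed positions, or seeds are auto-detected as
#' first-frame localizations that have a neighbor within `link_radius_nm`
#' in at least `persist_frac` of (sampled) frames. Each bead is tracked by
#' nearest-neighbor linking frame to frame, gaps are linearly interpolated,
#' the per-frame drift is the mean bead displacement from the first frame,
#' and the trace is smoothed by a centered moving average. By convention
#' `trace[1] = (0, 0)`.
#'
#' @param locs Localization tibble (kept rows).
#' @param bead_seeds Optional matrix/tibble of seed positions
#'   (`x_nm`, `y_nm`).
#' @param link_radius_nm Linking / persistence radius (nm).
#' @param smooth_window Moving-average window (frames).
#' @param persist_frac Fraction of frames a bead must be visible in.
#' @param n_frames Total frames; defaults to `max(locs$frame)`.
#' @return A tibble of class `drift_trace` (`frame`, `dx_nm`, `dy_nm`) with
#'   attributes `n_beads_used`, `residual_rms_nm` and `bead_positions`
#'   (drift-free mean position per bead).
#' @export
track_fiducials <- function(locs, bead_seeds = NULL, link_radius_nm = 500,
                            smooth_window = 50L, persist_frac = 0.9,
                            n_frames = NULL) {
  if ("keep" %in% names(locs)) locs <- locs[locs$keep, ]
  if (nrow(locs) == 0L) abort("no localizations; cannot track beads.")
  n_frames <- n_frames %||% max(locs$frame)
  fr <- factor(locs$frame, levels = seq_len(n_frames))
  xs_by_frame <- split(locs$x_nm, fr)
  ys_by_frame <- split(locs$y_nm, fr)
  # nearest-neighbor linking from a seed position through every frame;
  # following the link (rather than a fixed position) tolerates drifts far
  # larger than the link radius
  link_one <- function(x0, y0) {
    tx <- rep(NA_real_, n_frames)
    ty <- rep(NA_real_, n_frames)
    cx <- x0; cy <- y0
    r2 <- link_radius_nm^2
    for (f in seq_len(n_frames)) {
      px <- xs_by_frame[[f]]
      if (length(px) > 0L) {
        py <- ys_by_frame[[f]]
        d2 <- (px - cx)^2 + (py - cy)^2
        k <- which.min(d2)
        if (d2[k] <= r2) {
          cx <- px[k]; cy <- py[k]
          tx[f] <- cx
          ty[f] <- cy
        }
      }
    }
    list(x = tx, y = ty, coverage = mean(!is.na(tx)))
  }
  if (is.null(bead_seeds)) {
    f1 <- locs[locs$frame == min(locs$frame), ]
    tracks <- lapply(seq_len(nrow(f1)), function(i) {
      link_one(f1$x_nm[i], f1$y_nm[i])
    })
    tracks <- tracks[vapply(tracks, function(t) t$coverage, numeric(1)) >=
                       persist_frac]
    # drop duplicate seeds that converged onto the same bead
    if (length(tracks) > 1L) {
      first_pos <- vapply(tracks, function(t) {
        i <- which(!is.na(t$x))[1L]
        c(t$x[i], t$y[i])
      }, numeric(2))
      keep <- !duplicated(round(t(first_pos) / 10))
      tracks <- tracks[keep]
    }
  } else {
    bead_seeds <- tibble(x_nm = bead_seeds[[1]], y_nm = bead_seeds[[2]])
    tracks <- lapply(seq_len(nrow(bead_seeds)), function(i) {
      link_one(bead_seeds$x_nm[i], bead_seeds$y_nm[i])
    })
    tracks <- tracks[vapply(tracks, function(t) t$coverage, numeric(1)) >=
                       persist_frac]
  }
  if (length(tracks) == 0L) {
    abort(paste("no trackable fiducial bead found; check the field with a",
                "beads-only acquisition."))
  }
  n_beads <- length(tracks)
  trajx <- matrix(NA_real_, n_frames, n_beads)
  trajy <- matrix(NA_real_, n_frames, n_beads)
  for (b in seq_len(n_beads)) {
    seen <- which(!is.na(tracks[[b]]$x))
    if (length(seen) < 2L) next
    # linear interpolation across gaps, flat extrapolation at the ends
    trajx[, b] <- stats::approx(seen, tracks[[b]]$x[seen],
                                xout = seq_len(n_frames), rule = 2)$y
    trajy[, b] <- stats::approx(seen, tracks[[b]]$y[seen],
                                xout = seq_len(n_frames), rule = 2)$y
  }
  ok <- colSums(!is.na(trajx)) == n_frames
  if (!any(ok)) abort("no bead could be tracked across the acquisition.")
  trajx <- trajx[, ok, drop = FALSE]
  trajy <- trajy[, ok, drop = FALSE]
  raw_dx <- rowMeans(sweep(trajx, 2L, trajx[1L, ]))
  raw_dy <- rowMeans(sweep(trajy, 2L, trajy[1L, ]))
  smooth <- function(v) {
    w <- min(smooth_window, length(v))
    if (w <= 1L) return(v)
    k <- rep(1 / w, w)
    pad <- w %/% 2L
    vp <- c(rep(v[1L], pad), v, rep(v[length(v)], w - pad - 1L))
    stats::convolve(vp, k, type = "filter")
  }
  dx <- smooth(raw_dx)
  dy <- smooth(raw_dy)
  dx <- dx - dx[1L]; dy <- dy - dy[1L]
  # frame-to-frame noise of the drift estimate: deviation of the unsmoothed
  # mean-bead displacement from the smoothed trace; averaging n beads
  # shrinks this below the single-bead localization jitter
  res <- sqrt(mean(c((raw_dx - raw_dx[1L] - dx)^2,
                     (raw_dy - raw_dy[1L] - dy)^2)))
  bead_pos <- tibble(x_nm = colMeans(trajx) - mean(dx),
                     y_nm = colMeans(trajy) - mean(dy))
  out <- tibble(frame = seq_len(n_frames), dx_nm = dx, dy_nm = dy)
  class(out) <- c("drift_trace", class(out))
  attr(out, "n_beads_used") <- sum(ok)
  attr(out, "residual_rms_nm") <- res
  attr(out, "bead_positions") <- bead_pos
  out
}

#' Subtract the drift trace from a localization table
#'
#' Shifts each localization by minus the drift of its frame; z is untouched.
#' Same-frame pairwise distances are preserved exactly, and applying a trace
#' followed by its negation restores the input.
#'
#' @param locs Localization tibble.
#' @param trace Drift trace (`frame`, `dx_nm`, `dy_nm`) covering all frames
#'   present in `locs`.
#' @return `locs` with corrected `x_nm`, `y_nm`.
#' @export
correct_drift <- function(locs, trace) {
  if (nrow(locs) == 0L) return(locs)
  idx <- match(locs$frame, trace$frame)
  if (anyNA(idx)) abort("drift trace does not cover every frame in `locs`.")
  locs$x_nm <- locs$x_nm - trace$dx_nm[idx]
  locs$y_nm <- locs$y_nm - trace$dy_nm[idx]
  locs
}

#' Write a drift trace as CSV
#'
#' @param trace Drift trace tibble.
#' @param path CSV path (`frame,dx_nm,dy_nm`).
#' @return The trace, invisibly.
#' @export
write_drift_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace)[, c("frame", "dx_nm", "dy_nm")], path)
  invisible(trace)
}
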