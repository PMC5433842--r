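# synthetic ROI with an elliptical Gaussian spot, photon units -> counts
make_roi <- function(n = 11, x0, y0, sx = 1.2, sy = 1.0, amp = 300, b = 5,
                     cam = camera_model(), noise_sd = 0) {
  gx <- matrix(seq_len(n), n, n, byrow = TRUE)
  gy <- matrix(seq_len(n), n, n)
  ph <- b + amp * exp(-(gx - x0)^2 / (2 * sx^2) - (gy - y0)^2 / (2 * sy^2))
  counts <- cam$baseline + cam$counts_per_photon * ph
  if (noise_sd > 0) counts <- counts + rnorm(n * n, 0, noise_sd)
  counts
}

test_that("the band-pass filter rejects DC and preserves spot peaks", {
  expect_lt(max(abs(bandpass(matrix(57.3, 31, 31)))), 1e-8)
  roi <- make_roi(n = 21, x0 = 11.0, y0 = 11.0, amp = 500)
  f <- bandpass(roi, 1)
  peak <- which(f == max(f), arr.ind = TRUE)
  expect_identical(as.integer(peak[1, ]), c(11L, 11L))
})

test_that("band-pass white-noise gain matches the Parseval prediction", {
  withr::with_seed(71, {
    img <- matrix(rnorm(240 * 240, 0, 3), 240, 240)
    f <- bandpass(img, 1, 3)
    # effective interior kernel: difference of the two separable kernels
    kern1d <- function(s) {
      r <- max(1, ceiling(3 * s))
      k <- dnorm(seq(-r, r), 0, s)
      k / sum(k)
    }
    k1 <- kern1d(1); k2 <- kern1d(3)
    pad <- (length(k2) - length(k1)) / 2
    k1p <- c(rep(0, pad), k1, rep(0, pad))
    dog <- outer(k1p, k1p) - outer(k2, k2)
    pred <- 9 * sum(dog^2)
    inner <- f[30:210, 30:210]
    expect_equal(stats::var(as.vector(inner)), pred, tolerance = 0.05)
  })
})

test_that("candidate detection finds separated spots and ignores flat noise", {
  withr::with_seed(73, {
    noise <- matrix(rnorm(40 * 40, 100, 3), 40, 40)
    cand <- detect_candidates(bandpass(noise, 1), threshold_sd = 6)
    expect_lte(nrow(cand), 1L)
  })
  img <- make_roi(n = 31, x0 = 10, y0 = 16, amp = 400) +
    make_roi(n = 31, x0 = 20, y0 = 16, amp = 400) - camera_model()$baseline
  cand <- detect_candidates(bandpass(img, 1), threshold_sd = 5, roi_half = 4L)
  expect_identical(nrow(cand), 2L)
})

test_that("the elliptical Gaussian fit recovers sub-pixel positions and photons", {
  cam <- camera_model()
  roi <- make_roi(x0 = 6.3, y0 = 5.8, sx = 1.3, sy = 1.0, amp = 500, cam = cam)
  ft <- fit_spot(roi, cam)
  expect_true(ft$converged)
  expect_lt(abs(ft$x_px - 6.3), 0.02)
  expect_lt(abs(ft$y_px - 5.8), 0.02)
  true_photons <- 2 * pi * 500 * 1.3 * 1.0
  expect_lt(abs(ft$photons - true_photons) / true_photons, 0.05)
  expect_gt(ft$corr, 0.99)
})

test_that("fitting is translation-equivariant for whole-pixel shifts", {
  cam <- camera_model()
  big <- make_roi(n = 17, x0 = 8.25, y0 = 8.6, amp = 400, cam = cam)
  roi_a <- big[3:13, 3:13]
  roi_b <- big[5:15, 5:15] # content shifted by exactly -2 px in both axes
  fa <- fit_spot(roi_a, cam)
  fb <- fit_spot(roi_b, cam)
  expect_equal(fa$x_px - fb$x_px, 2, tolerance = 1e-3)
  expect_equal(fa$y_px - fb$y_px, 2, tolerance = 1e-3)
})

test_that("featureless ROIs fail the correlation rule", {
  withr::with_seed(79, {
    cam <- camera_model()
    roi <- matrix(rnorm(121, cam$baseline, 8), 11, 11)
    ft <- fit_spot(roi, cam)
    expect_lt(ft$corr, 0.95)
  })
})

test_that("localization precision improves as one over root photons", {
  withr::with_seed(83, {
    cam <- camera_model()
    fit_sd <- function(amp, n = 60) {
      xs <- vapply(seq_len(n), function(i) {
        ph <- make_roi(x0 = 6.2, y0 = 6.0, amp = amp, b = 2, cam = cam)
        lam <- (ph - cam$baseline) / cam$counts_per_photon
        noisy <- cam$baseline + cam$counts_per_photon * rpois(121, lam)
        fit_spot(matrix(noisy, 11, 11), cam)$x_px
      }, numeric(1))
      sd(xs)
    }
    s_low <- fit_sd(60)
    s_high <- fit_sd(600)
    ratio <- s_low / s_high # expect ~ sqrt(10) ~ 3.16
    expect_gt(ratio, 2.0)
    expect_lt(ratio, 5.0)
  })
})

test_that("z lookup round-trips the calibration and flags outliers", {
  cal <- calibration_model()
  for (z0 in c(-300, -150, 0, 150, 300)) {
    w <- psf_widths(z0, cal)
    expect_lt(abs(z_lookup(w$wx, w$wy, cal) - z0), 1)
  }
  w0 <- psf_widths(0, cal)
  expect_equal(z_lookup(w0$wx, w0$wx, cal), 0, tolerance = 1)
  # widths far off the curve are undefined
  expect_true(is.na(z_lookup(500, 500, cal)))
  expect_true(is.na(z_lookup(NA_real_, 160, cal)))
})

test_that("cleaning applies the four thresholds in order, to both pair members", {
  spots <- tibble::tibble(
    frame = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
    x_nm = c(1000, 1500, 3000, 5000, 1000, 1600, 4000),
    y_nm = 1000,
    photons = c(250, 900, 900, 900, 900, 900, 900),
    wx_nm = c(200, 200, 700, 200, 200, 200, 200),
    wy_nm = 200,
    corr = c(0.99, 0.99, 0.99, 0.90, 0.99, 0.99, 0.99))
  out <- clean_spots(spots, cleaning_config(), pixel_nm = 160)
  expect_identical(out$reject_reason,
                   c("photons", "none", "psf_size", "corr",
                     "proximity", "proximity", "none"))
  expect_identical(out$keep, out$reject_reason == "none")
  # pure filter and idempotent
  again <- clean_spots(out, cleaning_config(), pixel_nm = 160)
  expect_identical(again$keep, out$keep)
  empty <- clean_spots(spots[0, ], cleaning_config())
  expect_identical(nrow(empty), 0L)
})

test_that("localize_movie recovers a single emitter and handles empty stacks", {
  cam <- camera_model()
  em <- tibble::tibble(id = 1L, kind = "bead", x_nm = 2000, y_nm = 2100,
                       z_nm = 100, k_on = 0, k_off = 0, k_bleach = 0,
                       photons = 4000)
  sc <- sim_scene(em, field_um = 4, n_frames = 25, camera = cam)
  cal <- calibration_model()
  mv <- render_movie(sc, cal, seed = 31)
  locs <- localize_movie(mv, cal)
  kept <- locs[locs$keep, ]
  expect_identical(nrow(kept), 25L)
  expect_lt(max(abs(kept$x_nm - 2000)), 3 * 15)
  expect_lt(max(abs(kept$y_nm - 2100)), 3 * 15)
  expect_lt(abs(median(kept$z_nm) - 100), 40)
  # empty stack
  empty <- localize_movie(list(frames = list(), meta = mv$meta), cal)
  expect_identical(nrow(empty), 0L)
  # missing metadata key errors by name
  bad_meta <- mv$meta
  bad_meta$pixel_nm <- NULL
  expect_error(localize_movie(list(frames = mv$frames, meta = bad_meta), cal),
               "pixel_nm")
})

test_that("localization tables round-trip through CSV", {
  locs <- tibble::tibble(frame = 1:3, x_nm = c(1, 2, 3) * 100.5,
                         y_nm = c(4, 5, 6) * 100.5,
                         z_nm = c(10.25, NA, -20.5), photons = c(500, 700, 900),
                         wx_nm = 170, wy_nm = 180, corr = 0.99,
                         keep = c(TRUE, FALSE, TRUE),
                         reject_reason = c("none", "z_range", "none"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations(locs, path)
  # missing z written as an empty field
  expect_true(grepl(",,", readLines(path)[3]))
  back <- read_localizations(path)
  expect_equal(as.data.frame(back), as.data.frame(locs))
})
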