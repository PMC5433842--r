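# synthetic localization table: beads with injected drift and jitter
bead_locs <- function(bead_xy, n_frames, drift_dx, drift_dy, jitter = 0,
                      seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(bead_xy)), function(b) {
      tibble::tibble(
        frame = seq_len(n_frames),
        x_nm = bead_xy[b, 1] + drift_dx + rnorm(n_frames, 0, jitter),
        y_nm = bead_xy[b, 2] + drift_dy + rnorm(n_frames, 0, jitter),
        photons = 5000, wx_nm = 170, wy_nm = 170, corr = 0.99, keep = TRUE)
    })
    dplyr::bind_rows(rows)
  })
}

test_that("a single static bead yields a zero drift trace", {
  locs <- bead_locs(matrix(c(2000, 2000), 1), 200, 0, 0)
  tr <- track_fiducials(locs, n_frames = 200)
  expect_equal(max(abs(tr$dx_nm)), 0)
  expect_equal(max(abs(tr$dy_nm)), 0)
  expect_identical(attr(tr, "n_beads_used"), 1L)
})

test_that("linear drift is recovered within 2 percent from three jittered beads", {
  beads <- matrix(c(1000, 1000, 8000, 2000, 4000, 9000), 3, byrow = TRUE)
  n <- 1000L
  drift <- (seq_len(n) - 1) * 1.0 # 1 nm / frame
  locs <- bead_locs(beads, n, drift, 0.5 * drift, jitter = 3, seed = 5)
  tr <- track_fiducials(locs, n_frames = n)
  interior <- 100:900
  slope <- stats::coef(stats::lm(tr$dx_nm[interior] ~ interior))[[2]]
  expect_lt(abs(slope - 1.0) / 1.0, 0.02)
  slope_y <- stats::coef(stats::lm(tr$dy_nm[interior] ~ interior))[[2]]
  expect_lt(abs(slope_y - 0.5) / 0.5, 0.02)
})

test_that("averaging several beads beats single-bead jitter", {
  beads <- matrix(c(1000, 1000, 8000, 2000), 2, byrow = TRUE)
  locs <- bead_locs(beads, 600, 0, 0, jitter = 5, seed = 7)
  tr <- track_fiducials(locs, n_frames = 600)
  expect_lt(attr(tr, "residual_rms_nm"), 5)
})

test_that("drift correction is exact, invertible and distance-preserving", {
  withr::with_seed(9, {
    locs <- tibble::tibble(frame = rep(1:50, each = 4),
                           x_nm = runif(200, 0, 5000),
                           y_nm = runif(200, 0, 5000),
                           z_nm = runif(200, -300, 300))
    zero <- tibble::tibble(frame = 1:50, dx_nm = 0, dy_nm = 0)
    expect_identical(correct_drift(locs, zero), locs)
    tr <- tibble::tibble(frame = 1:50, dx_nm = cumsum(runif(50, -2, 3)),
                         dy_nm = cumsum(runif(50, -1, 2)))
    corr <- correct_drift(locs, tr)
    neg <- tr
    neg$dx_nm <- -neg$dx_nm
    neg$dy_nm <- -neg$dy_nm
    expect_equal(correct_drift(corr, neg), locs)
    expect_identical(corr$z_nm, locs$z_nm)
    # same-frame pairwise distances preserved exactly
    f1 <- locs$frame == 1
    expect_equal(as.vector(dist(cbind(corr$x_nm[f1], corr$y_nm[f1]))),
                 as.vector(dist(cbind(locs$x_nm[f1], locs$y_nm[f1]))))
    # frames outside the trace error
    expect_error(correct_drift(dplyr::mutate(locs, frame = frame + 100), tr),
                 "cover")
  })
})

test_that("clustered localizations tighten after drift correction", {
  withr::with_seed(13, {
    n <- 400L
    drift <- tibble::tibble(frame = 1:n, dx_nm = (1:n) * 0.25, dy_nm = 0)
    # one fluorophore cluster plus one bead, both dragged by the drift
    cluster <- tibble::tibble(frame = sort(sample(1:n, 120, TRUE)))
    cluster$x_nm <- 3000 + rnorm(120, 0, 9) + drift$dx_nm[cluster$frame]
    cluster$y_nm <- 3000 + rnorm(120, 0, 9)
    bead <- tibble::tibble(frame = 1:n,
                           x_nm = 6000 + drift$dx_nm, y_nm = 6000,
                           photons = 5000, wx_nm = 170, wy_nm = 170,
                           corr = 0.99, keep = TRUE)
    tr <- track_fiducials(bead, n_frames = n)
    fixed <- correct_drift(cluster, tr)
    expect_lt(sd(fixed$x_nm), sd(cluster$x_nm))
    expect_lt(sd(fixed$x_nm), 12) # close to the injected 9 nm spread
  })
})
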