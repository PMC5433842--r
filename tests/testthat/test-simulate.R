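test_that("psf widths follow the closed-form defocus model", {
  cal <- calibration_model(w0 = 150, gamma = 200, d = 400)
  w0 <- psf_widths(0, cal)
  expect_equal(w0$wx, w0$wy) # symmetric at the midpoint when A = B = 0
  expect_equal(psf_widths(cal$gamma, cal)$wx, cal$w0) # minimum of wx
  expect_equal(psf_widths(-cal$gamma, cal)$wy, cal$w0)
  zs <- seq(-400, 400, by = 50)
  got <- psf_widths(zs, cal)
  # direct formula evaluation as the oracle
  expect_equal(got$wx, 150 * sqrt(1 + ((zs - 200) / 400)^2))
  expect_equal(got$wy, 150 * sqrt(1 + ((zs + 200) / 400)^2))
  # mirror symmetry and monotone ellipticity
  rev_wy <- psf_widths(-zs, cal)$wy
  expect_equal(got$wx, rev_wy)
  expect_true(all(diff(got$wx / got$wy) < 0) || all(diff(got$wx / got$wy) > 0))
})

test_that("blink traces honor the Markov structure and the seed contract", {
  kin <- dye_kinetics()
  t1 <- simulate_blink_trace(kin, 2000, 85, seed = 5)
  t2 <- simulate_blink_trace(kin, 2000, 85, seed = 5)
  expect_identical(t1, t2)
  # dark start with no activation stays dark
  t3 <- simulate_blink_trace(dye_kinetics(k_on = 0), 500, 85, seed = 1,
                             initial = "dark")
  expect_true(all(t3 == 0L))
  # bleaching is absorbing
  t4 <- simulate_blink_trace(dye_kinetics(k_bleach = 20), 5000, 85, seed = 2)
  first_bleached <- match(2L, t4)
  if (!is.na(first_bleached)) {
    expect_true(all(t4[first_bleached:length(t4)] == 2L))
  }
})

test_that("switching-event counts match the analytic geometric expectation", {
  # events per dye before bleaching ~ geometric with success
  # p = k_bleach / (k_off + k_bleach); long acquisitions realize the mean
  kin <- dye_kinetics(k_on = 2, k_off = 50, k_bleach = 2.5)
  n <- 400L
  bursts <- vapply(seq_len(n), function(i) {
    count_blink_bursts(simulate_blink_trace(kin, 30000, 85, seed = 100 + i))
  }, integer(1))
  expected_mean <- (kin$k_off + kin$k_bleach) / kin$k_bleach
  se <- expected_mean / sqrt(n) # geometric sd ~ mean for small p
  expect_lt(abs(mean(bursts) - expected_mean), 3 * se)
})

test_that("an empty scene renders to baseline plus background", {
  cam <- camera_model(background_photons = 2)
  sc <- sim_scene(tibble::tibble(id = integer(), kind = character(),
                                 x_nm = numeric(), y_nm = numeric(),
                                 z_nm = numeric(), k_on = numeric(),
                                 k_off = numeric(), k_bleach = numeric(),
                                 photons = numeric()),
                  field_um = 3, n_frames = 5, camera = cam)
  mv <- render_movie(sc, calibration_model(), seed = 3)
  expect_identical(nrow(mv$truth), 0L)
  m <- mean(unlist(mv$frames))
  expect_equal(m, cam$baseline + cam$counts_per_photon * 2, tolerance = 0.02)
})

test_that("a bright static emitter lands where the ground truth says", {
  cam <- camera_model(counts_per_photon = 0.2, read_noise_counts = 0,
                      baseline = 0, background_photons = 0)
  em <- tibble::tibble(id = 1L, kind = "bead", x_nm = 1480, y_nm = 1520,
                       z_nm = 0, k_on = 0, k_off = 0, k_bleach = 0,
                       photons = 5e4)
  sc <- sim_scene(em, field_um = 3, n_frames = 3, camera = cam)
  mv <- render_movie(sc, calibration_model(), seed = 7)
  img <- mv$frames[[1]]
  tot <- sum(img)
  gx <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  gy <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cx <- (sum(img * gx) / tot - 0.5) * cam$pixel_nm
  cy <- (sum(img * gy) / tot - 0.5) * cam$pixel_nm
  expect_lt(abs(cx - 1480), 0.01 * cam$pixel_nm + 2)
  expect_lt(abs(cy - 1520), 0.01 * cam$pixel_nm + 2)
  # photon conservation: integrated signal equals the photon budget
  expect_equal(tot / cam$counts_per_photon, 5e4, tolerance = 0.02)
})

test_that("drift shifts the rendered image by construction", {
  cam <- camera_model(read_noise_counts = 0, background_photons = 0)
  em <- tibble::tibble(id = 1L, kind = "bead", x_nm = 1500, y_nm = 1500,
                       z_nm = 0, k_on = 0, k_off = 0, k_bleach = 0,
                       photons = 2e4)
  drift <- drift_linear(40, c(2.5, 0)) # 100 nm total drift in x
  sc <- sim_scene(em, field_um = 3, n_frames = 40, drift = drift,
                  camera = cam)
  mv <- render_movie(sc, calibration_model(), seed = 9)
  centroid_x <- function(img) {
    img <- pmax(img - cam$baseline, 0)
    gx <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
    (sum(img * gx) / sum(img) - 0.5) * cam$pixel_nm
  }
  shift <- centroid_x(mv$frames[[40]]) - centroid_x(mv$frames[[1]])
  expect_equal(shift, drift$dx_nm[40], tolerance = 0.1)
})

test_that("movies are byte-identical for identical scene, calibration, seed", {
  sc <- preset_scene("beads_only", params = list(field_um = 4, n_frames = 6),
                     seed = 13)
  m1 <- render_movie(sc, calibration_model(), seed = 21)
  m2 <- render_movie(sc, calibration_model(), seed = 21)
  expect_identical(m1$frames, m2$frames)
  expect_identical(m1$truth, m2$truth)
})

test_that("presets build the advertised scene compositions", {
  blank <- preset_scene("blank_control",
                        params = list(field_um = 5, n_frames = 10), seed = 1)
  expect_identical(sum(blank$emitters$kind == "dye"), 0L)
  expect_gte(sum(blank$emitters$kind == "bead"), 3L)

  ns <- preset_scene("nanostructure",
                     params = list(field_um = 6, n_frames = 10,
                                   disc_area_um2 = 0.15), seed = 2)
  dyes <- ns$emitters[ns$emitters$kind == "dye", ]
  expect_identical(nrow(dyes), 29L)
  ctr <- attr(ns, "truth")$structure_centroid_nm
  r_max <- sqrt(0.15 / pi) * 1000
  d <- sqrt((dyes$x_nm - mean(dyes$x_nm))^2 + (dyes$y_nm - mean(dyes$y_nm))^2)
  expect_true(all(d <= 2 * r_max)) # all dyes inside the disc diameter
  expect_true(all(abs(dyes$z_nm) <= 350))

  # uniform preset: dye count Poisson around density * area
  u <- preset_scene("uniform_sparse",
                    params = list(field_um = 14, n_frames = 10,
                                  dye_density_um2 = 0.5), seed = 3)
  n_dye <- sum(u$emitters$kind == "dye")
  expect_gt(n_dye, 98 - 4 * sqrt(98))
  expect_lt(n_dye, 98 + 4 * sqrt(98))

  bo <- preset_scene("beads_only", params = list(field_um = 5, n_frames = 5),
                     seed = 4)
  expect_true(all(bo$emitters$kind == "bead"))
})

test_that("bead rows in the ground truth cover every frame", {
  sc <- preset_scene("beads_only", params = list(field_um = 4, n_frames = 8),
                     seed = 5)
  mv <- render_movie(sc, calibration_model(), seed = 5)
  per_bead <- table(mv$truth$emitter_id)
  expect_true(all(per_bead == 8L))
})

test_that("movies round-trip through TIFF + JSON sidecar", {
  sc <- preset_scene("beads_only", params = list(field_um = 3, n_frames = 4),
                     seed = 6)
  mv <- render_movie(sc, calibration_model(), seed = 6)
  prefix <- file.path(withr::local_tempdir(), "mv")
  write_movie(mv, prefix)
  back <- read_movie(prefix)
  expect_identical(length(back$frames), 4L)
  expect_equal(back$frames[[2]], unname(mv$frames[[2]]), tolerance = 1e-9)
  expect_equal(back$meta$pixel_nm, mv$meta$pixel_nm)
  expect_identical(nrow(back$truth), nrow(mv$truth))
  expect_error(read_movie(file.path(tempdir(), "absent")), "missing")
})
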