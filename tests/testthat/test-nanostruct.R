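# build a clustered localization table with controllable geometry
make_cluster <- function(id, n, cx, cy, r_nm = 150, frames = NULL,
                         n_frames = 1000L, seed = id) {
  withr::with_seed(seed, {
    ang <- runif(n, 0, 2 * pi)
    rad <- r_nm * sqrt(runif(n))
    tibble::tibble(
      cluster = id,
      frame = frames %||% sort(sample.int(n_frames, n, replace = TRUE)),
      x_nm = cx + rad * cos(ang), y_nm = cy + rad * sin(ang),
      z_nm = rnorm(n, 0, 30))
  })
}

test_that("each of the six criteria rejects its own failure mode", {
  cfg <- candidate_filter_config()
  n_frames <- 1000L
  good <- make_cluster(1L, 300, 3000, 3000)
  # (5) too many localizations
  big <- make_cluster(2L, 3500, 8000, 8000, r_nm = 220)
  # (6) too large an area: points spread over ~0.5 um^2
  wide <- make_cluster(3L, 500, 13000, 3000, r_nm = 420)
  # (3) temporally concentrated: everything within a 3% window
  burst <- make_cluster(4L, 300, 3000, 13000,
                        frames = sort(sample(481:510, 300, TRUE)))
  # (4) too sparse: few points over a moderate area
  sparse <- make_cluster(5L, 110, 13000, 13000, r_nm = 380)
  all_cl <- dplyr::bind_rows(good, big, wide, burst, sparse)
  cand <- apply_criteria(all_cl, cfg, n_frames = n_frames)
  cand <- cand[order(cand$cluster), ]
  expect_true(cand$accepted[1])
  expect_false(cand$n_locs_ok[2])
  expect_false(cand$area_ok[3])
  expect_false(cand$temporally_spread[4])
  expect_false(cand$dense_enough[5])
  expect_identical(cand$accepted, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # verdicts are recorded for every cluster even after a failure
  expect_false(anyNA(cand$in_nucleus))
  expect_false(anyNA(cand$area_ok))
})

test_that("bead overlap and nucleus membership are enforced", {
  cfg_mask <- candidate_filter_config(
    nucleus_mask = list(x_nm = c(0, 1e4, 1e4, 0), y_nm = c(0, 0, 1e4, 1e4)))
  inside <- make_cluster(1L, 300, 3000, 3000)
  outside <- make_cluster(2L, 300, 15000, 3000)
  cand <- apply_criteria(dplyr::bind_rows(inside, outside), cfg_mask,
                         n_frames = 1000L)
  expect_identical(cand$in_nucleus, c(TRUE, FALSE))
  expect_identical(cand$accepted, c(TRUE, FALSE))
  beads <- tibble::tibble(x_nm = 3100, y_nm = 3000)
  cand_b <- apply_criteria(inside, candidate_filter_config(), beads = beads,
                           n_frames = 1000L)
  expect_false(cand_b$clear_of_beads)
  expect_false(cand_b$accepted)
})

test_that("accepted candidates always satisfy the numeric bounds", {
  cfg <- candidate_filter_config()
  withr::with_seed(61, {
    cl <- dplyr::bind_rows(lapply(1:6, function(i) {
      make_cluster(i, sample(50:600, 1), runif(1, 2000, 2e4),
                   runif(1, 2000, 2e4), r_nm = runif(1, 80, 400))
    }))
  })
  cand <- apply_criteria(cl, cfg, n_frames = 1000L)
  acc <- cand[cand$accepted, ]
  expect_true(all(acc$n_locs >= cfg$min_locs & acc$n_locs <= cfg$max_locs))
  expect_true(all(acc$area_um2 <= cfg$max_area_um2))
  expect_true(all(acc$density_um2 >= cfg$min_density_um2))
  expect_true(all(acc$frame_conc < cfg$temporal_conc_frac))
  # acceptance equals the conjunction of the six verdicts (order-free)
  expect_identical(cand$accepted,
                   cand$in_nucleus & cand$clear_of_beads &
                     cand$temporally_spread & cand$dense_enough &
                     cand$n_locs_ok & cand$area_ok)
})

test_that("cross-section profiles recover widths and separations", {
  withr::with_seed(67, {
    pts <- tibble::tibble(x_nm = rnorm(600, 1000, 15), y_nm = rnorm(600, 0, 15),
                          z_nm = rnorm(600, 0, 20))
    fit <- cross_section_profile(pts, line = rbind(c(0, 0), c(2000, 0)),
                                 bin_nm = 5)
    expect_true(fit$converged)
    expect_equal(tidy(fit)$fwhm_nm, 2 * sqrt(2 * log(2)) * 15,
                 tolerance = 0.12)
    # two z populations 95 nm apart
    pts2 <- tibble::tibble(x_nm = rnorm(400, 0, 10), y_nm = rnorm(400, 0, 10),
                           z_nm = c(rnorm(200, -10, 20), rnorm(200, 85, 20)))
    fit2 <- cross_section_profile(pts2, axis = "z", bin_nm = 8,
                                  n_components = 2L)
    expect_true(fit2$converged)
    expect_equal(fit2$separation_nm, 95, tolerance = 0.12)
    expect_identical(nrow(glance(fit2)), 1L)
  })
  expect_error(cross_section_profile(tibble::tibble(x_nm = 1, y_nm = 1),
                                     line = rbind(c(0, 0), c(1, 0))),
               "too few")
})
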