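# add one integrated elliptical Gaussian spot (photon units) to `img`
add_spot <- function(img, x_nm, y_nm, wx, wy, photons, pixel_nm) {
  nx <- ncol(img); ny <- nrow(img)
  c0 <- max(1L, floor((x_nm - 4 * wx) / pixel_nm) + 1L)
  c1 <- min(nx, ceiling((x_nm + 4 * wx) / pixel_nm))
  r0 <- max(1L, floor((y_nm - 4 * wy) / pixel_nm) + 1L)
  r1 <- min(ny, ceiling((y_nm + 4 * wy) / pixel_nm))
  if (c0 > c1 || r0 > r1) return(img)
  cols <- c0:c1; rows <- r0:r1
  fx <- pnorm((cols * pixel_nm - x_nm) / wx) -
    pnorm(((cols - 1L) * pixel_nm - x_nm) / wx)
  fy <- pnorm((rows * pixel_nm - y_nm) / wy) -
    pnorm(((rows - 1L) * pixel_nm - y_nm) / wy)
  img[rows, cols] <- img[rows, cols] + photons * outer(fy, fx)
  img
}

#' Render a simulated single-molecule movie
#'
#' Forward model of the astigmatic acquisition: each fluorescent-state
#' emitter contributes an integrated elliptical Gaussian whose widths come
#' from [psf_widths()] at its z position, shifted by the per-frame stage
#' drift; sparse autofluorescence emitters fire with their own kinetics;
#' beads are continuously on. Pixel photons are Poisson-distributed around
#' the expected photon map (shot noise), then scaled by the camera gain,
#' offset by the baseline and perturbed by Gaussian read noise. The full EM
#' register excess-noise cascade is not modeled. Identical (scene, cal,
#' seed) give byte-identical movies.
#'
#' @param scene A [sim_scene()].
#' @param cal A [calibration_model()].
#' @param seed Integer seed.
#' @return A list of class `sim_movie`: `frames` (list of count matrices,
#'   rows = y), `truth` (tibble `frame`, `emitter_id`, `kind`, `x_nm`,
#'   `y_nm`, `z_nm`, `photons`; positions are true positions without drift,
#'   photons the expected per-frame photons), `meta` (pixel size, rates,
#'   calibration, seed), and `scene`.
#' @export
render_movie <- function(scene, cal = calibration_model(), seed = 1L) {
  stopifnot(inherits(scene, "sim_scene"))
  cam <- scene$camera
  field_nm <- scene$field_um * 1000
  nx <- ny <- as.integer(round(field_nm / cam$pixel_nm))
  em <- scene$emitters
  withr::with_seed(seed, {
    inside <- em$x_nm >= 0 & em$x_nm <= field_nm &
      em$y_nm >= 0 & em$y_nm <= field_nm
    if (any(!inside)) {
      warn(sprintf("%d emitter(s) outside the field were skipped.",
                   sum(!inside)))
      em <- em[inside, ]
    }
    n_em <- nrow(em)
    on_frames <- vector("list", n_em)
    if (n_em > 0) {
      w <- psf_widths(em$z_nm, cal)
      for (i in seq_len(n_em)) {
        on_frames[[i]] <- if (em$kind[i] == "bead") {
          seq_len(scene$n_frames)
        } else {
          kin <- dye_kinetics(em$k_on[i], em$k_off[i], em$k_bleach[i],
                              em$photons[i])
          which(simulate_blink_trace(kin, scene$n_frames,
                                     scene$frame_rate) == 1L)
        }
      }
    }
    # invert: per frame, which emitters are on
    frame_emitters <- vector("list", scene$n_frames)
    for (i in seq_len(n_em)) {
      for (f in on_frames[[i]]) {
        frame_emitters[[f]] <- c(frame_emitters[[f]], i)
      }
    }
    frames <- vector("list", scene$n_frames)
    truth <- vector("list", scene$n_frames)
    for (f in seq_len(scene$n_frames)) {
      lam <- matrix(cam$background_photons, nrow = ny, ncol = nx)
      ids <- frame_emitters[[f]]
      for (i in ids) {
        lam <- add_spot(lam,
                        em$x_nm[i] + scene$drift$dx_nm[f],
                        em$y_nm[i] + scene$drift$dy_nm[f],
                        w$wx[i], w$wy[i], em$photons[i], cam$pixel_nm)
      }
      photons_px <- matrix(rpois(nx * ny, lam), nrow = ny)
      counts <- cam$baseline + cam$counts_per_photon * photons_px +
        rnorm(nx * ny, 0, cam$read_noise_counts)
      frames[[f]] <- matrix(pmin(pmax(round(counts), 0), 65535L), nrow = ny)
      if (length(ids) > 0) {
        truth[[f]] <- tibble(frame = f, emitter_id = em$id[ids],
                             kind = em$kind[ids], x_nm = em$x_nm[ids],
                             y_nm = em$y_nm[ids], z_nm = em$z_nm[ids],
                             photons = em$photons[ids])
      }
    }
    truth <- dplyr::bind_rows(truth)
    if (nrow(truth) == 0L) {
      truth <- tibble(frame = integer(), emitter_id = integer(),
                      kind = character(), x_nm = numeric(), y_nm = numeric(),
                      z_nm = numeric(), photons = numeric())
    }
    meta <- list(pixel_nm = cam$pixel_nm, frame_rate = scene$frame_rate,
                 n_frames = scene$n_frames, field_um = scene$field_um,
                 baseline = cam$baseline,
                 counts_per_photon = cam$counts_per_photon,
                 calibration = unclass(cal)[c("w0", "gamma", "d", "A", "B",
                                              "z_range")],
                 seed = seed)
    structure(list(frames = frames, truth = truth, meta = meta,
                   scene = scene), class = "sim_movie")
  })
}

#' Write / read a movie as TIFF + JSON sidecar + ground-truth CSV
#'
#' `write_movie()` writes `<prefix>.tif` (multi-page 16-bit grayscale),
#' `<prefix>.json` (metadata sidecar) and, when ground truth is present,
#' `<prefix>_truth.csv`. `read_movie()` loads them back into the same
#' structure (`truth` is `NULL` when absent).
#'
#' @param movie A `sim_movie` (or a compatible `frames` + `meta` list).
#' @param prefix Output path prefix.
#' @return `write_movie()` the prefix, invisibly; `read_movie()` a list with
#'   `frames`, `meta`, `truth`.
#' @export
write_movie <- function(movie, prefix) {
  imgs <- lapply(movie$frames, function(m) m / 65535)
  tiff::writeTIFF(imgs, paste0(prefix, ".tif"), bits.per.sample = 16L)
  jsonlite::write_json(movie$meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(movie$truth)) {
    readr::write_csv(movie$truth, paste0(prefix, "_truth.csv"))
  }
  invisible(prefix)
}

#' @rdname write_movie
#' @export
read_movie <- function(prefix) {
  tif <- paste0(prefix, ".tif")
  js <- paste0(prefix, ".json")
  if (!file.exists(tif)) abort(paste0("missing movie file: ", tif))
  if (!file.exists(js)) abort(paste0("missing metadata sidecar: ", js))
  imgs <- tiff::readTIFF(tif, all = TRUE)
  frames <- lapply(imgs, function(m) round(m * 65535))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  truth_path <- paste0(prefix, "_truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  }
  list(frames = frames, meta = meta, truth = truth)
}
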