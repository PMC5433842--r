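#' Astigmatic PSF calibration model
#'
#' Defocus model for the widths of the astigmatic point-spread function:
#' `wx(z) = w0 * sqrt(1 + u^2 + A u^3 + B u^4)` with `u = (z - gamma)/d`,
#' and `wy` the mirror image (`u = (z + gamma)/d`). `gamma` is the
#' astigmatic offset introduced by the cylindrical lens, `d` the depth of
#' focus. With `A = B = 0` the model is symmetric: `wx(z) = wy(-z)` and
#' `wx(0) = wy(0)`.
#'
#' @param w0 Focal-plane width (nm).
#' @param gamma Astigmatic focal offset (nm).
#' @param d Depth of focus (nm).
#' @param A,B Unitless higher-order terms.
#' @param z_range Working axial range (nm), used as the rendering color range
#'   and the localization z window.
#' @return A list of class `calibration_model`.
#' @export
calibration_model <- function(w0 = 150, gamma = 200, d = 400, A = 0, B = 0,
                              z_range = 350) {
  stopifnot(w0 > 0, d > 0, z_range > 0)
  structure(list(w0 = w0, gamma = gamma, d = d, A = A, B = B,
                 z_range = z_range), class = "calibration_model")
}

#' PSF widths at an axial position
#'
#' @param z Axial position(s), nm.
#' @param cal A [calibration_model()].
#' @return A tibble with columns `z`, `wx`, `wy` (nm).
#' @examples
#' psf_widths(c(-300, 0, 300), calibration_model())
#' @export
psf_widths <- function(z, cal = calibration_model()) {
  w_of <- function(u) cal$w0 * sqrt(pmax(1 + u^2 + cal$A * u^3 + cal$B * u^4,
                                         .Machine$double.eps))
  ux <- (z - cal$gamma) / cal$d
  uy <- (z + cal$gamma) / cal$d
  tibble(z = z, wx = w_of(ux), wy = w_of(uy))
}

#' Axial position from fitted widths
#'
#' Inverts the calibration curve: `z` minimizes
#' `(sqrt(wx) - sqrt(wx_cal(z)))^2 + (sqrt(wy) - sqrt(wy_cal(z)))^2`
#' on a 1-nm grid over an extended axial range, followed by a local
#' quadratic refinement. When the best residual distance exceeds
#' `tol_sqrt_nm` the ellipticity is inconsistent with the calibration and
#' `NA` is returned.
#'
#' @param wx,wy Fitted widths (nm); vectorized, equal length.
#' @param cal A [calibration_model()].
#' @param tol_sqrt_nm Maximum tolerated residual distance in sqrt-nm units.
#' @param grid_nm Grid step (nm).
#' @return Numeric vector of z (nm), `NA` where undefined.
#' @export
z_lookup <- function(wx, wy, cal = calibration_model(), tol_sqrt_nm = 2.5,
                     grid_nm = 1) {
  stopifnot(length(wx) == length(wy))
  zg <- seq(-2 * cal$d, 2 * cal$d, by = grid_nm)
  wcal <- psf_widths(zg, cal)
  sx <- sqrt(wcal$wx); sy <- sqrt(wcal$wy)
  vapply(seq_along(wx), function(i) {
    if (is.na(wx[i]) || is.na(wy[i]) || wx[i] <= 0 || wy[i] <= 0) {
      return(NA_real_)
    }
    d2 <- (sqrt(wx[i]) - sx)^2 + (sqrt(wy[i]) - sy)^2
    k <- which.min(d2)
    if (sqrt(d2[k]) > tol_sqrt_nm) return(NA_real_)
    # parabolic refinement on the grid minimum
    if (k > 1L && k < length(zg)) {
      y0 <- d2[k - 1L]; y1 <- d2[k]; y2 <- d2[k + 1L]
      denom <- y0 - 2 * y1 + y2
      off <- if (denom > 0) 0.5 * (y0 - y2) / denom else 0
      zg[k] + max(min(off, 1), -1) * grid_nm
    } else {
      zg[k]
    }
  }, numeric(1))
}
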