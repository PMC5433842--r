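#' Tidy a cross-section profile fit
#'
#' @param x A `profile_fit` from [cross_section_profile()].
#' @param ... Unused.
#' @return One row per Gaussian component: `component`, `mean_nm`,
#'   `sigma_nm`, `fwhm_nm`, `amplitude`.
#' @method tidy profile_fit
#' @export
tidy.profile_fit <- function(x, ...) {
  if (is.null(x$components)) {
    return(tibble(component = integer(), mean_nm = numeric(),
                  sigma_nm = numeric(), fwhm_nm = numeric(),
                  amplitude = numeric()))
  }
  x$components
}

#' @rdname tidy.profile_fit
#' @method glance profile_fit
#' @export
glance.profile_fit <- function(x, ...) {
  tibble(n_components = if (is.null(x$components)) 0L else nrow(x$components),
         separation_nm = x$separation_nm, converged = x$converged,
         n_bins = nrow(x$histogram))
}

#' Tidy a pooled precision summary
#'
#' @param x A `precision_summary` from [pooled_precision()].
#' @param ... Unused.
#' @return One row per axis: `axis`, `sigma_nm`, `sigma_sample_nm`,
#'   `fwhm_nm`.
#' @method tidy precision_summary
#' @export
tidy.precision_summary <- function(x, ...) x$axes

#' @rdname tidy.precision_summary
#' @method glance precision_summary
#' @export
glance.precision_summary <- function(x, ...) {
  tibble(n_locs = x$n_locs, n_clusters = x$n_clusters)
}

#' @export
print.precision_summary <- function(x, ...) {
  cat(sprintf("<precision_summary> %d localizations from %d clusters\n",
              x$n_locs, x$n_clusters))
  print(x$axes)
  invisible(x)
}

#' @export
print.profile_fit <- function(x, ...) {
  cat("<profile_fit>\n")
  if (!x$converged) {
    cat("  fit did not converge\n")
  } else {
    print(x$components)
    if (!is.na(x$separation_nm)) {
      cat(sprintf("  peak separation: %.1f nm\n", x$separation_nm))
    }
  }
  invisible(x)
}
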