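#' Event densities and condition false discovery ratio
#'
#' The condition FDR compares a labeling condition against its unlabeled
#' control: the ratio of kept-event density in the control field to that in
#' the labeled field (not the multiple-testing FDR). A labeled density of
#' zero leaves the ratio undefined (`NA`), never infinite.
#'
#' @param events_labeled,events_control Event counts (or localization
#'   tibbles, in which case kept rows are counted).
#' @param area_um2 Field area (um^2); a length-2 vector gives separate
#'   labeled / control areas.
#' @return One-row tibble: `events_per_um2_labeled`,
#'   `events_per_um2_control`, `fdr`.
#' @examples
#' event_density_and_fdr(120, 12, 100)
#' @export
event_density_and_fdr <- function(events_labeled, events_control, area_um2) {
  count_of <- function(x) {
    if (is.data.frame(x)) {
      if ("keep" %in% names(x)) sum(x$keep) else nrow(x)
    } else {
      as.numeric(x)
    }
  }
  stopifnot(all(area_um2 > 0))
  area <- rep(area_um2, length.out = 2L)
  dl <- count_of(events_labeled) / area[1L]
  dc <- count_of(events_control) / area[2L]
  tibble(events_per_um2_labeled = dl, events_per_um2_control = dc,
         fdr = if (dl > 0) dc / dl else NA_real_)
}

#' Normalized event time course
#'
#' Event counts per time bin, normalized to the first bin (so the series
#' starts at 1 when defined).
#'
#' @param locs Localization tibble (kept rows counted) with a `frame`
#'   column.
#' @param bin_s Bin width (seconds).
#' @param frame_rate Frames per second.
#' @return Tibble `t_s` (bin start), `events`, `normalized`.
#' @export
time_course <- function(locs, bin_s = 5, frame_rate = 85) {
  if ("keep" %in% names(locs)) locs <- locs[locs$keep, ]
  if (nrow(locs) == 0L) abort("no events; cannot compute a time course.")
  t_s <- (locs$frame - 1L) / frame_rate
  bins <- floor(t_s / bin_s)
  full <- 0:max(bins)
  counts <- vapply(full, function(b) sum(bins == b), integer(1))
  if (counts[1L] == 0L) {
    abort("first time bin contains no events; cannot normalize.")
  }
  tibble(t_s = full * bin_s, events = counts,
         normalized = counts / counts[1L])
}

#' Pooled localization precision from blinking clusters
#'
#' Re-centers every cluster of repeated localizations of one fluorophore on
#' its centroid, pools the deviations, and fits a Gaussian per axis. The
#' per-axis standard deviation is the localization precision; FWHM is the
#' identity `2 sqrt(2 ln 2) sigma`. Gaussian fits use least squares on
#' Freedman-Diaconis-binned histograms, with the plain sample SD reported
#' alongside as a cross-check. Singleton clusters are excluded with a
#' warning. Translating any whole cluster leaves the result unchanged.
#'
#' @param locs Localization tibble with a `cluster` column (cluster 0
#'   ignored) and `x_nm`, `y_nm` and optionally `z_nm`.
#' @return A list of class `precision_summary`: `n_locs`, `n_clusters`, and
#'   a tibble `axes` with `axis`, `sigma_nm` (Gaussian fit), `sigma_sample_nm`
#'   (sample SD), `fwhm_nm`.
#' @export
pooled_precision <- function(locs) {
  stopifnot("cluster" %in% names(locs))
  locs <- locs[locs$cluster > 0L, ]
  sizes <- table(locs$cluster)
  singletons <- names(sizes)[sizes < 2L]
  if (length(singletons) > 0L) {
    warn(sprintf("%d singleton cluster(s) excluded.", length(singletons)))
    locs <- locs[!locs$cluster %in% as.integer(singletons), ]
  }
  if (nrow(locs) == 0L) abort("no clusters with >= 2 localizations.")
  has_z <- "z_nm" %in% names(locs) && any(!is.na(locs$z_nm))
  axes_cols <- c(x = "x_nm", y = "y_nm", if (has_z) c(z = "z_nm"))
  centered <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(locs, .data$cluster),
    dplyr::across(dplyr::all_of(unname(axes_cols)), ~ .x - mean(.x))))
  fit_axis <- function(dev) {
    dev <- dev[!is.na(dev)]
    s_sample <- sd(dev)
    if (s_sample == 0) return(0)
    bw <- 2 * stats::IQR(dev) / length(dev)^(1 / 3) # Freedman-Diaconis
    if (bw <= 0) bw <- max(s_sample / 4, 1e-6)
    breaks <- seq(min(dev) - bw, max(dev) + bw, by = bw)
    h <- graphics::hist(dev, breaks = breaks, plot = FALSE)
    x <- h$mids; y <- h$counts
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                        start = list(A = max(y), mu = 0, s = s_sample),
                        control = stats::nls.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) s_sample else abs(stats::coef(fit)[["s"]])
  }
  k <- 2 * sqrt(2 * log(2))
  axes <- dplyr::bind_rows(lapply(names(axes_cols), function(ax) {
    dev <- centered[[axes_cols[[ax]]]]
    s_fit <- fit_axis(dev)
    tibble(axis = ax, sigma_nm = s_fit,
           sigma_sample_nm = sd(dev[!is.na(dev)]), fwhm_nm = k * s_fit)
  }))
  structure(list(n_locs = nrow(locs),
                 n_clusters = length(unique(locs$cluster)),
                 axes = axes),
            class = "precision_summary")
}

#' Hypergeometric detection specificity
#'
#' One-sided tail probability that at least `k_pos_detected` of the
#' `K = k_pos + k_neg` total detections fall in the positive cell group
#' when the `K` detections are assigned to the `N = n_pos + n_neg` cells
#' uniformly without replacement. With zero detections among negatives the
#' tail reduces to the single term `C(n_pos, K) / C(N, K)`. Computed with
#' log-gamma binomials to stay finite at realistic cell counts.
#'
#' @param n_pos_cells,k_pos_detected Positive-group cell count and number
#'   of cells with a detected structure.
#' @param n_neg_cells,k_neg_detected The same for the negative control
#'   group.
#' @return The p-value.
#' @examples
#' hypergeom_detection_p(78, 21, 83, 0) # ~5.0e-8
#' @export
hypergeom_detection_p <- function(n_pos_cells, k_pos_detected,
                                  n_neg_cells, k_neg_detected) {
  if (any(c(n_pos_cells, k_pos_detected, n_neg_cells, k_neg_detected) < 0) ||
      k_pos_detected > n_pos_cells || k_neg_detected > n_neg_cells) {
    abort("invalid counts: need 0 <= k <= n in both groups.")
  }
  N <- n_pos_cells + n_neg_cells
  K <- k_pos_detected + k_neg_detected
  i <- k_pos_detected:min(K, n_pos_cells)
  terms <- lchoose(n_pos_cells, i) + lchoose(n_neg_cells, K - i) -
    lchoose(N, K)
  # log-sum-exp over the upper tail
  m <- max(terms)
  exp(m + log(sum(exp(terms - m))))
}
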