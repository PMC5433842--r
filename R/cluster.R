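# grid-hashed DBSCAN on 2-D points; returns integer labels (0 = noise).
# Written here because no density-based clustering package ships with the
# standard library; O(n) neighbor lookup via eps-sized grid cells.
dbscan_points <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  cx <- floor(x / eps); cy <- floor(y / eps)
  key <- paste(cx, cy, sep = ",")
  cell <- split(seq_len(n), key)
  neighbors <- function(i) {
    ks <- as.vector(outer(cx[i] + (-1:1), cy[i] + (-1:1), paste, sep = ","))
    cand <- unlist(cell[ks], use.names = FALSE)
    cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= eps^2]
  }
  labels <- rep(-1L, n) # -1 unvisited, 0 noise, >0 cluster id
  queued <- rep(FALSE, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L) next
    nb <- neighbors(i)
    if (length(nb) < min_pts) {
      labels[i] <- 0L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[labels[nb] <= 0L & !queued[nb]]
    queued[queue] <- TRUE
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]
      head <- head + 1L
      if (labels[j] > 0L) next
      labels[j] <- cl # border or core point of this cluster
      nbj <- neighbors(j)
      if (length(nbj) >= min_pts) { # core: expand
        add <- nbj[labels[nbj] <= 0L & !queued[nbj]]
        if (length(add) > 0L) {
          queued[add] <- TRUE
          queue <- c(queue, add)
        }
      }
    }
  }
  labels
}

#' Density-based clustering of localizations
#'
#' DBSCAN on the lateral (x, y) coordinates: a core point has at least
#' `min_pts` localizations (itself included) within `eps_nm`; clusters are
#' the connected components of core points plus their border points; all
#' other localizations are noise (`cluster = 0`).
#'
#' @param locs Localization tibble (kept rows; `x_nm`, `y_nm`).
#' @param eps_nm Neighborhood radius (nm).
#' @param min_pts Core-point threshold.
#' @return `locs` with an integer `cluster` column (0 = unassigned).
#' @export
cluster_localizations <- function(locs, eps_nm = 50, min_pts = 10L) {
  locs$cluster <- dbscan_points(locs$x_nm, locs$y_nm, eps_nm, min_pts)
  locs
}
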