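#' Enumerate intramolecular stems of a beacon sequence
#'
#' Exhaustive enumeration of every maximal intramolecular stem (a run of
#' consecutive Watson-Crick pairs between two segments of the same strand,
#' closing a loop of at least `min_loop` nt). Each stem is scored by the
#' nearest-neighbor stacking free energy of the paired duplex at 37 degC
#' (no loop penalty, no partition function), reported as a positive stability
#' score `-dG` in kcal/mol. Used to verify that the intended 7-bp arm-arm
#' stem of a molecular beacon is the dominant fold and that no competing stem
#' approaches it in stability.
#'
#' @param full_seq DNA string (<= 200 nt).
#' @param config A [design_config()]; supplies `fold_min_stem` (minimum
#'   reported stem length) and `fold_margin_kcal`.
#' @param arm_len When > 0, the stem pairing the first and last `arm_len`
#'   bases is the intended hairpin stem; the verdict then reports whether it
#'   is the unique most stable stem (no other stem as long, none within
#'   `fold_margin_kcal` of its score).
#' @param min_loop Minimum unpaired loop length between the stem halves (nt).
#' @return A list of class `fold_check` with elements `stems` (tibble with
#'   columns `start5`, `end5`, `start3`, `end3` (1-based inclusive), `length`,
#'   `score_kcal`), `arm_stem_score`, `max_competing_score`,
#'   `max_competing_len` and `arm_stem_ok`.
#' @examples
#' fc <- fold_check("CGCACGCAAATTTAAATTTAAATTTAAATTTAAATTTAAATTTAAATTTGCGTGCG")
#' fc$arm_stem_ok
#' @export
fold_check <- function(full_seq, config = design_config(), arm_len = 0L,
                       min_loop = 3L) {
  check_dna(full_seq)
  n <- nchar(full_seq)
  if (n > 200L) abort("`full_seq` longer than 200 nt.")
  b <- strsplit(full_seq, "", fixed = TRUE)[[1L]]
  comp <- chartr("ACGT", "TGCA", b)
  # pair matrix: P[i, j] TRUE when base i pairs base j (i < j)
  P <- outer(b, comp, "==")
  min_stem <- config$fold_min_stem
  stems <- list()
  # anti-diagonal runs: stem extends (i, j) -> (i + 1, j - 1)
  for (d in seq_len(2L * n - 1L)) { # d = i + j constant along anti-diagonals
    i <- max(1L, d + 1L - n):min(n, d)
    j <- d + 1L - i
    ok <- i < j & P[cbind(i, j)]
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_stem)) {
      i0 <- i[starts[k]]; j0 <- j[starts[k]]
      len <- r$lengths[k]
      # innermost pair: (i0 + len - 1, j0 - len + 1); loop between them
      loop <- (j0 - len + 1L) - (i0 + len - 1L) - 1L
      # trim the stem from the inside until the loop constraint holds
      while (len >= min_stem && loop < min_loop) {
        len <- len - 1L
        loop <- loop + 2L
      }
      if (len < min_stem) next
      stems[[length(stems) + 1L]] <-
        c(start5 = i0, end5 = i0 + len - 1L,
          start3 = j0 - len + 1L, end3 = j0, length = len)
    }
  }
  if (length(stems) == 0L) {
    stems <- tibble(start5 = integer(), end5 = integer(), start3 = integer(),
                    end3 = integer(), length = integer(),
                    score_kcal = numeric())
  } else {
    m <- do.call(rbind, stems)
    score <- vapply(seq_len(nrow(m)), function(r) {
      s <- substr(full_seq, m[r, "start5"], m[r, "end5"])
      -nn_dG(s, 37, config, init = FALSE)
    }, numeric(1))
    o <- order(score, decreasing = TRUE)
    stems <- tibble(start5 = as.integer(m[o, "start5"]),
                    end5 = as.integer(m[o, "end5"]),
                    start3 = as.integer(m[o, "start3"]),
                    end3 = as.integer(m[o, "end3"]),
                    length = as.integer(m[o, "length"]),
                    score_kcal = score[o])
  }
  arm_score <- NA_real_
  max_comp <- 0
  max_comp_len <- 0L
  arm_ok <- NA
  if (arm_len > 0L) {
    is_arm <- stems$start5 == 1L & stems$end5 == arm_len &
      stems$start3 == n - arm_len + 1L & stems$end3 == n
    # the arm stem may appear extended if the hybrid ends chance-pair with it;
    # accept any stem containing the full arm pairing
    contains_arm <- stems$start5 <= 1L + 0L & stems$end5 >= arm_len &
      stems$end3 >= n & stems$start3 <= n - arm_len + 1L
    arm_row <- which(is_arm | contains_arm)
    others <- setdiff(seq_len(nrow(stems)), arm_row)
    if (length(arm_row) > 0L) {
      arm_score <- max(stems$score_kcal[arm_row])
      arm_stem_len <- max(stems$length[arm_row])
      if (length(others) > 0L) {
        max_comp <- max(stems$score_kcal[others])
        max_comp_len <- max(stems$length[others])
      }
      arm_ok <- arm_stem_len <= arm_len && # not extended beyond intended
        max_comp_len <= arm_len &&
        max_comp < arm_score - 1e-9 &&
        max_comp <= arm_score - config$fold_margin_kcal + 1e-9
    } else {
      arm_ok <- FALSE
    }
  } else if (nrow(stems) > 0L) {
    max_comp <- max(stems$score_kcal)
    max_comp_len <- max(stems$length)
  }
  structure(list(stems = stems, arm_stem_score = arm_score,
                 max_competing_score = max_comp,
                 max_competing_len = max_comp_len,
                 arm_stem_ok = arm_ok), class = "fold_check")
}
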