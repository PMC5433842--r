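#' Describe a design target
#'
#' @param name Target name (used in probe ids).
#' @param seq Target sequence (ACGT, at least one hybridizing-region long).
#' @param seqname Name of the reference sequence the target lies on (for the
#'   uniqueness screen's self-exclusion); defaults to `name`.
#' @param ref_start 0-based start of the target on that reference.
#' @param strand_policy Which strands probes may hybridize to: `"both"`
#'   (default), `"plus"` or `"minus"`.
#' @return A list of class `target_sequence`.
#' @export
target_sequence <- function(name, seq, seqname = name, ref_start = 0L,
                            strand_policy = c("both", "plus", "minus")) {
  check_dna(seq)
  strand_policy <- match.arg(strand_policy)
  structure(list(name = name, seq = seq, seqname = seqname,
                 ref_start = as.integer(ref_start),
                 strand_policy = strand_policy),
            class = "target_sequence")
}

probe_row <- function(id, start, end, strand, hybrid, arms, thermo, offt) {
  tibble(probe_id = id, target_start = start, target_end = end,
         strand = strand, hybrid_seq = hybrid, arm5 = arms$arm5,
         arm3 = arms$arm3, full_seq = paste0(arms$arm5, hybrid, arms$arm3),
         tm_hybrid = thermo, tm_arm = arms$tm_arm,
         gc_arm = gc_fraction(arms$arm5), max_offtarget_identity = offt)
}

#' Tile a target with molecular-beacon probes
#'
#' Greedy left-to-right scan of the target. At each position the strand(s)
#' allowed by the target's `strand_policy` are tried (+ first); the first
#' candidate whose hybridizing region passes [hybrid_candidate_ok()] and
#' [uniqueness_screen()] and for which [design_arms()] succeeds is accepted,
#' and the scan advances past the accepted site plus `min_gap`. The finished
#' set is passed through [cross_hyb_filter()]. The result is deterministic
#' for fixed (target, background, config).
#'
#' @param target A [target_sequence()].
#' @param index A [background_index()], or `NULL` to skip the off-target
#'   screen (e.g. for targets with no surrounding genome fixture).
#' @param config A [design_config()].
#' @return A tibble of probes, one row per accepted beacon, with columns
#'   `probe_id`, `target_start`, `target_end` (0-based half-open on the
#'   target), `strand`, `hybrid_seq` (as synthesized), `arm5`, `arm3`,
#'   `full_seq`, `tm_hybrid`, `tm_arm`, `gc_arm`, `max_offtarget_identity`.
#'   Zero qualifying sites yield an empty tibble with a warning.
#' @export
tile_target <- function(target, index = NULL, config = design_config()) {
  stopifnot(inherits(target, "target_sequence"))
  len <- nchar(target$seq)
  hl <- config$hybrid_len
  probes <- list()
  strands <- switch(target$strand_policy, both = c("+", "-"),
                    plus = "+", minus = "-")
  interval <- list(seqname = target$seqname, start = target$ref_start,
                   end = target$ref_start + len)
  pos <- 0L
  while (pos + hl <= len) {
    accepted <- FALSE
    window <- substr(target$seq, pos + 1L, pos + hl)
    for (st in strands) {
      # a probe labeled "+" reads as the + strand window (it hybridizes the
      # - strand); a "-" probe is synthesized as the reverse complement of
      # the + strand window
      hybrid <- if (st == "+") window else revcomp(window)
      hc <- hybrid_candidate_ok(hybrid, config)
      if (!hc$ok) next
      offt <- 0L
      if (!is.null(index)) {
        us <- uniqueness_screen(hybrid, index, interval, config = config)
        offt <- us$max_match
        if (!us$pass) next
      }
      arms <- design_arms(hybrid, config)
      if (!arms$ok) next
      id <- sprintf("%s_MB%03d", target$name, length(probes) + 1L)
      probes[[length(probes) + 1L]] <-
        probe_row(id, pos, pos + hl, st, hybrid, arms, hc$tm, offt)
      accepted <- TRUE
      break
    }
    pos <- pos + if (accepted) hl + config$min_gap else 1L
  }
  if (length(probes) == 0L) {
    warn("no qualifying probe sites found; returning an empty probe set.")
    return(probe_row("x", 0L, 0L, "+", "A", list(arm5 = "A", arm3 = "T",
                                                 tm_arm = 0), 0, 0L)[0, ])
  }
  cross_hyb_filter(dplyr::bind_rows(probes), config = config)
}

# longest exact complementary stretch between two probe sequences: the
# longest common substring of a and revcomp(b), thresholded at m
has_cross_comp <- function(a, b, m) {
  if (m < 1L) return(TRUE)
  rb <- rc_chr(b)
  n <- nchar(a)
  if (m > n || m > nchar(rb)) return(FALSE)
  pats <- unique(substring(a, seq_len(n - m + 1L), m:n))
  any(vapply(pats, grepl, logical(1), x = rb, fixed = TRUE))
}

#' Remove mutually complementary probes
#'
#' Greedy pass in target-coordinate order: a probe is dropped when it
#' duplicates the full sequence of an earlier retained probe, or shares an
#' exact complementary stretch of `max_comp` nt or more with one (such pairs
#' could hybridize to each other instead of the target).
#'
#' @param probes Probe tibble as produced by [tile_target()].
#' @param max_comp Complementarity threshold (nt); defaults from `config`.
#' @param config A [design_config()].
#' @return The retained subset of `probes`.
#' @export
cross_hyb_filter <- function(probes, max_comp = NULL,
                             config = design_config()) {
  max_comp <- max_comp %||% config$max_cross_comp
  if (nrow(probes) <= 1L) return(probes)
  probes <- dplyr::arrange(probes, .data$target_start)
  keep <- rep(TRUE, nrow(probes))
  for (j in 2:nrow(probes)) {
    for (i in which(keep[seq_len(j - 1L)])) {
      if (probes$full_seq[j] == probes$full_seq[i] ||
          has_cross_comp(probes$full_seq[i], probes$full_seq[j], max_comp)) {
        keep[j] <- FALSE
        break
      }
    }
  }
  probes[keep, ]
}

#' Probe-set design metrics
#'
#' Probe density and the closest possible dye-quencher approach between
#' neighboring probes. With the design-rule minimum inter-site gap of 10 nt
#' and 7-nt arms, the nearest Alexa-647/BHQ3 pair from two neighboring
#' beacons is separated by 10 + 7 + 7 = 24 nt, about 7.9 nm at 0.33 nm/nt.
#'
#' @param probes A probe tibble, or a plain probe count.
#' @param target_len_bp Target length in bp (taken from `target` if given).
#' @param target Optional [target_sequence()].
#' @param config A [design_config()] (supplies `arm_len` and `min_gap` when
#'   `probes` is a bare count or has fewer than two rows).
#' @return A one-row tibble: `n_probes`, `probes_per_kb`,
#'   `min_dye_quencher_gap_nt`, `gap_nm`.
#' @examples
#' design_metrics(29, 2500)
#' @export
design_metrics <- function(probes, target_len_bp = NULL, target = NULL,
                           config = design_config()) {
  if (!is.null(target)) target_len_bp <- nchar(target$seq)
  stopifnot(!is.null(target_len_bp), target_len_bp > 0)
  if (is.numeric(probes)) {
    n <- as.integer(probes)
    min_site_gap <- config$min_gap
  } else {
    n <- nrow(probes)
    min_site_gap <- if (n >= 2L) {
      p <- dplyr::arrange(probes, .data$target_start)
      min(p$target_start[-1L] - p$target_end[-n])
    } else {
      config$min_gap
    }
  }
  gap_nt <- min_site_gap + 2L * config$arm_len
  tibble(n_probes = n, probes_per_kb = n / (target_len_bp / 1000),
         min_dye_quencher_gap_nt = gap_nt, gap_nm = gap_nt * 0.33)
}

#' Validate a probe set against the beacon invariants
#'
#' Re-checks every emitted probe: 56-nt full sequence equal to
#' `arm5 + hybrid + arm3`, `arm3 == revcomp(arm5)`, 5' base C, arm GC
#' fraction >= 0.85, and no homopolymer run of `max_run` or more.
#'
#' @param probes Probe tibble.
#' @param config A [design_config()].
#' @return A tibble with one logical column per invariant plus `ok`.
#' @export
validate_probes <- function(probes, config = design_config()) {
  full_len <- config$hybrid_len + 2L * config$arm_len
  n <- nrow(probes)
  chk <- function(f) vapply(seq_len(n), f, logical(1))
  out <- tibble(
    probe_id = probes$probe_id,
    len_ok = nchar(probes$full_seq) == full_len &
      probes$full_seq == paste0(probes$arm5, probes$hybrid_seq, probes$arm3),
    arms_complementary = chk(function(i) {
      probes$arm3[i] == revcomp(probes$arm5[i])
    }),
    five_prime_c = substr(probes$arm5, 1L, 1L) == "C",
    gc_arm_ok = chk(function(i) gc_fraction(probes$arm5[i]) >= 0.85),
    run_ok = chk(function(i) longest_run(probes$full_seq[i]) < config$max_run),
    coords_ok = probes$target_end - probes$target_start == config$hybrid_len
  )
  out$ok <- out$len_ok & out$arms_complementary & out$five_prime_c &
    out$gc_arm_ok & out$run_ok & out$coords_ok
  out
}

#' Write a probe table to TSV / BED6
#'
#' `write_probe_tsv()` writes the probe tibble as tab-separated text with the
#' canonical column order. `write_probe_bed()` writes probe sites as BED6
#' (0-based half-open; score = `round(tm_hybrid * 10)`).
#'
#' @param probes Probe tibble.
#' @param path Output file.
#' @param seqname Chromosome/sequence name for the BED records.
#' @return The input, invisibly.
#' @export
write_probe_tsv <- function(probes, path) {
  readr::write_tsv(probes, path)
  invisible(probes)
}

#' @rdname write_probe_tsv
#' @export
write_probe_bed <- function(probes, path, seqname = "target") {
  bed <- tibble(chrom = seqname, start = probes$target_start,
                end = probes$target_end, name = probes$probe_id,
                score = as.integer(round(probes$tm_hybrid * 10)),
                strand = probes$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(probes)
}
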