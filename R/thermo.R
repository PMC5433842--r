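# Unified nearest-neighbor duplex parameters (1 M NaCl reference):
# dH in kcal/mol, dS in cal/(mol K), one entry per 5'->3' dinucleotide step of
# the top strand paired with its perfect complement.
.nn_dH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.nn_dS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# terminal initiation, per duplex end
.init_gc <- c(dH = 0.1, dS = -2.8)
.init_at <- c(dH = 2.3, dS = 4.1)

.R_gas <- 1.9872 # cal/(mol K)

#' Probe-design configuration
#'
#' Bundles every tunable threshold of the beacon design pipeline. Defaults
#' encode the published design rules: a 42-nt hybridizing region flanked by
#' complementary 7-nt arms (56 nt total), hybridizing-region melting
#' temperature at least 70 degC, arm-arm melting temperature inside
#' \[50, 60\] degC, no homopolymer run of six or more bases, at most 22 nt
#' (human mode) or 25 nt (mouse mode) of exact off-target identity, and a
#' minimum inter-probe gap of 10 nt.
#'
#' @param hybrid_len Length of the hybridizing region (nt).
#' @param arm_len Length of each hairpin arm (nt).
#' @param tm_hybrid_min Minimum hybridizing-region melting temperature (degC).
#' @param tm_arm_range Two-element numeric, allowed arm-arm duplex Tm (degC).
#' @param max_identity Longest tolerated exact off-target match (nt); 22 for
#'   the human-genome mode, 25 for the mouse-genome mode.
#' @param max_run Homopolymer runs of this length or longer are rejected.
#' @param min_gap Minimum gap between neighboring probe sites on a strand (nt).
#' @param max_cross_comp Inter-probe exact complementarity of this many nt or
#'   more triggers removal in [cross_hyb_filter()].
#' @param na_mM Monovalent cation concentration for the salt correction (mM).
#' @param formamide_pct Formamide percentage of the hybridization buffer.
#' @param probe_nM Probe strand concentration used in the duplex Tm (nM).
#' @param arm_ref_uM Reference strand concentration for the arm-arm duplex
#'   Tm (uM). The published arm-Tm window of 50-60 degC corresponds to a
#'   melting analysis at tens of micromolar oligo; 50 uM makes that window
#'   attainable by GC-rich 7-mers while still rejecting most of the pool.
#' @param fold_min_stem Shortest intramolecular stem reported by
#'   [fold_check()] (bp).
#' @param fold_margin_kcal A non-arm stem within this many kcal/mol of the arm
#'   stem's stability fails the fold check.
#' @param hybrid_stem_max_kcal A bare hybridizing region is rejected when its
#'   strongest intramolecular stem is at least this stable (kcal/mol stacking
#'   stability, roughly a 6-bp GC stem); such folds compete with hairpin
#'   opening on the target.
#' @param mode Convenience switch: `"human"` sets `max_identity = 22`,
#'   `"mouse"` sets 25. Explicit `max_identity` wins.
#' @return A list of class `design_config`.
#' @examples
#' design_config(mode = "mouse")$max_identity
#' @export
design_config <- function(hybrid_len = 42L, arm_len = 7L,
                          tm_hybrid_min = 70, tm_arm_range = c(50, 60),
                          max_identity = NULL, max_run = 6L, min_gap = 10L,
                          max_cross_comp = 10L,
                          na_mM = 1000, formamide_pct = 0, probe_nM = 250,
                          arm_ref_uM = 50,
                          fold_min_stem = 4L, fold_margin_kcal = 3,
                          hybrid_stem_max_kcal = 9,
                          mode = c("human", "mouse")) {
  mode <- match.arg(mode)
  if (is.null(max_identity)) max_identity <- if (mode == "human") 22L else 25L
  stopifnot(hybrid_len > 0, arm_len > 0, tm_arm_range[1] < tm_arm_range[2],
            max_run > 0, min_gap >= 0, na_mM > 0, probe_nM > 0, arm_ref_uM > 0)
  structure(list(
    hybrid_len = as.integer(hybrid_len), arm_len = as.integer(arm_len),
    tm_hybrid_min = tm_hybrid_min, tm_arm_range = tm_arm_range,
    max_identity = as.integer(max_identity), max_run = as.integer(max_run),
    min_gap = as.integer(min_gap), max_cross_comp = as.integer(max_cross_comp),
    na_mM = na_mM, formamide_pct = formamide_pct, probe_nM = probe_nM,
    arm_ref_uM = arm_ref_uM, fold_min_stem = as.integer(fold_min_stem),
    fold_margin_kcal = fold_margin_kcal,
    hybrid_stem_max_kcal = hybrid_stem_max_kcal, mode = mode
  ), class = "design_config")
}

# raw NN sums for the perfect duplex of `seq` with its complement;
# init = TRUE adds the two terminal initiation terms
nn_sums <- function(seq, init = TRUE) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(b)
  steps <- paste0(b[-n], b[-1L])
  dH <- sum(.nn_dH[steps])
  dS <- sum(.nn_dS[steps])
  if (init) {
    for (e in c(b[1L], b[n])) {
      term <- if (e %in% c("G", "C")) .init_gc else .init_at
      dH <- dH + term[["dH"]]
      dS <- dS + term[["dS"]]
    }
  }
  c(dH = dH, dS = dS)
}

#' Nearest-neighbor duplex thermodynamics
#'
#' Enthalpy, entropy and corrected melting temperature of the perfect duplex
#' of `seq` with its complement, from unified nearest-neighbor parameters.
#' The melting temperature is computed at strand concentration `ct_M`
#' (defaults to `config$probe_nM`), then salt-corrected by
#' `16.6 * log10([Na+])` and lowered by 0.65 degC per percent formamide.
#'
#' @param seq DNA string (ACGT, length >= 2).
#' @param config A [design_config()].
#' @param ct_M Optional total strand concentration (mol/L) overriding
#'   `config$probe_nM`.
#' @return A one-row tibble with columns `dH` (kcal/mol), `dS` (cal/(mol K))
#'   and `tm` (degC, corrected).
#' @examples
#' nn_thermo("ACGTACGTACGT", design_config())
#' @export
nn_thermo <- function(seq, config = design_config(), ct_M = NULL) {
  check_dna(seq)
  if (nchar(seq) < 2L) {
    abort("`seq` must have length >= 2.", class = "mbstorm_invalid_sequence")
  }
  ct <- ct_M %||% (config$probe_nM * 1e-9)
  s <- nn_sums(seq)
  tm_K <- s[["dH"]] * 1000 / (s[["dS"]] + .R_gas * log(ct / 4))
  tm <- tm_K - 273.15 +
    16.6 * log10(config$na_mM / 1000) -
    0.65 * config$formamide_pct
  tibble(dH = s[["dH"]], dS = s[["dS"]], tm = tm)
}

# arm-arm duplex Tm at the reference concentration (degC)
arm_tm <- function(arm5, config = design_config()) {
  nn_thermo(arm5, config, ct_M = config$arm_ref_uM * 1e-6)$tm
}

# NN free energy (kcal/mol) of the perfect duplex at temperature temp_C, with
# an entropic salt correction of 0.368 * (n-1) * ln[Na+] cal/(mol K).
nn_dG <- function(seq, temp_C, config = design_config(), init = TRUE) {
  s <- nn_sums(seq, init = init)
  dS <- s[["dS"]] + 0.368 * (nchar(seq) - 1) * log(config$na_mM / 1000)
  s[["dH"]] - (temp_C + 273.15) * dS / 1000
}
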