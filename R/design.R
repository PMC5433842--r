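#' Screen a candidate hybridizing region
#'
#' Applies the published candidate rules to a 42-nt hybridizing region:
#' (i) duplex melting temperature at least `tm_hybrid_min` (70 degC),
#' (ii) no homopolymer run of `max_run` (six) or more identical nucleotides,
#' and (iii) no strong intramolecular secondary structure (strongest stem
#' stability below `hybrid_stem_max_kcal`). The off-target uniqueness rule is
#' screened separately by [uniqueness_screen()].
#'
#' @param seq42 Candidate hybridizing region, length `config$hybrid_len`.
#' @param config A [design_config()].
#' @return A list with `ok` (logical), `reasons` (character vector naming
#'   every failed rule: `"tm"`, `"homopolymer"`, `"fold"`), `tm` (degC) and
#'   `max_stem_kcal`.
#' @examples
#' hybrid_candidate_ok(strrep("ACGGTC", 7))$ok
#' @export
hybrid_candidate_ok <- function(seq42, config = design_config()) {
  check_dna(seq42, "seq42")
  if (nchar(seq42) != config$hybrid_len) {
    abort(sprintf("`seq42` must have length %d.", config$hybrid_len))
  }
  reasons <- character()
  tm <- nn_thermo(seq42, config)$tm
  if (tm < config$tm_hybrid_min) reasons <- c(reasons, "tm")
  if (longest_run(seq42) >= config$max_run) reasons <- c(reasons, "homopolymer")
  fc <- fold_check(seq42, config)
  max_stem <- fc$max_competing_score
  if (max_stem >= config$hybrid_stem_max_kcal) reasons <- c(reasons, "fold")
  list(ok = length(reasons) == 0L, reasons = reasons, tm = tm,
       max_stem_kcal = max_stem)
}

# deterministic candidate arm pool: 7-mers starting with C (never G next to
# the dye) with >= 85% GC, in lexicographic order
arm_candidates <- function(arm_len = 7L, gc_min = 0.85) {
  stopifnot(arm_len >= 2L)
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), arm_len - 1L),
                      stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder columns so that the
  # candidates come out in plain lexicographic order of the full string
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  cands <- paste0("C", apply(as.matrix(grid), 1L, paste, collapse = ""))
  need_gc <- ceiling(gc_min * arm_len - 1e-9)
  gc_n <- vapply(strsplit(cands, "", fixed = TRUE),
                 function(b) sum(b %in% c("G", "C")), integer(1))
  cands[gc_n >= need_gc]
}

.arm_pool_cache <- new.env(parent = emptyenv())

# candidate arms with their duplex Tm, cached per thermodynamic condition
arm_pool_with_tm <- function(config) {
  key <- paste(config$arm_len, config$arm_ref_uM, config$na_mM,
               config$formamide_pct, sep = "|")
  if (!is.null(.arm_pool_cache[[key]])) return(.arm_pool_cache[[key]])
  pool <- arm_candidates(config$arm_len)
  tm <- vapply(pool, arm_tm, numeric(1), config = config)
  out <- tibble(arm5 = pool, tm = unname(tm))
  .arm_pool_cache[[key]] <- out
  out
}

#' Design the hairpin arms for a hybridizing region
#'
#' Searches the deterministic pool of GC-rich 7-mers beginning with C (a C,
#' never a G, sits at the 5' end next to the fluorophore) for the first arm
#' whose arm-arm duplex Tm falls inside `tm_arm_range` and whose full 56-nt
#' beacon passes [fold_check()]: the intended 7-bp arm stem must be the
#' unique most stable fold, with no competing stem as long or within
#' `fold_margin_kcal` of its stability, and the full sequence must stay free
#' of homopolymer runs of `max_run` or more.
#'
#' @param hybrid_seq Hybridizing region (length `config$hybrid_len`).
#' @param config A [design_config()].
#' @param rng_seed Unused; the search is a deterministic lexicographic scan
#'   and the argument exists only to make the determinism contract explicit.
#' @return A list with `ok`; when `ok`, also `arm5`, `arm3`
#'   (`revcomp(arm5)`), `tm_arm` and `fold` (the [fold_check()] result); when
#'   not, `diagnostics`, a tibble counting candidates rejected per rule.
#' @export
design_arms <- function(hybrid_seq, config = design_config(), rng_seed = NULL) {
  check_dna(hybrid_seq, "hybrid_seq")
  pool_tb <- arm_pool_with_tm(config)
  pool <- pool_tb$arm5
  rejects <- c(tm_arm = 0L, homopolymer = 0L, fold = 0L)
  # stems internal to the hybrid region appear unchanged in every full
  # beacon: pre-screen them once so hopeless candidates fail cheaply
  fc_h <- fold_check(hybrid_seq, config)
  hyb_max_score <- fc_h$max_competing_score
  hyb_max_len <- fc_h$max_competing_len
  if (hyb_max_len > config$arm_len) {
    return(list(ok = FALSE,
                diagnostics = tibble(rule = "fold", rejected = length(pool),
                                     pool_size = length(pool))))
  }
  for (k in seq_along(pool)) {
    arm5 <- pool[k]
    tm <- pool_tb$tm[k]
    if (tm < config$tm_arm_range[1] || tm > config$tm_arm_range[2]) {
      rejects[["tm_arm"]] <- rejects[["tm_arm"]] + 1L
      next
    }
    arm3 <- rc_chr(arm5)
    full <- paste0(arm5, hybrid_seq, arm3)
    if (longest_run(full) >= config$max_run) {
      rejects[["homopolymer"]] <- rejects[["homopolymer"]] + 1L
      next
    }
    arm_score <- -nn_dG(arm5, 37, config, init = FALSE)
    if (hyb_max_score >= arm_score - config$fold_margin_kcal) {
      rejects[["fold"]] <- rejects[["fold"]] + 1L
      next
    }
    fc <- fold_check(full, config, arm_len = config$arm_len)
    if (!isTRUE(fc$arm_stem_ok)) {
      rejects[["fold"]] <- rejects[["fold"]] + 1L
      next
    }
    return(list(ok = TRUE, arm5 = arm5, arm3 = arm3, tm_arm = tm, fold = fc))
  }
  list(ok = FALSE,
       diagnostics = tibble(rule = names(rejects), rejected = unname(rejects),
                            pool_size = length(pool)))
}
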