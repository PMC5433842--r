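# independent greedy reference: evaluate every window with the same
# acceptance predicates, then replay the documented scan order
oracle_tile_sites <- function(target, idx, cfg) {
  len <- nchar(target$seq)
  hl <- cfg$hybrid_len
  strands <- switch(target$strand_policy, both = c("+", "-"), plus = "+",
                    minus = "-")
  interval <- list(seqname = target$seqname, start = target$ref_start,
                   end = target$ref_start + len)
  passes <- function(pos, st) {
    win <- substr(target$seq, pos + 1L, pos + hl)
    hyb <- if (st == "+") win else revcomp(win)
    if (!hybrid_candidate_ok(hyb, cfg)$ok) return(FALSE)
    if (!is.null(idx) &&
        !uniqueness_screen(hyb, idx, interval, config = cfg)$pass) {
      return(FALSE)
    }
    design_arms(hyb, cfg)$ok
  }
  sites <- list()
  pos <- 0L
  while (pos + hl <= len) {
    hit <- NULL
    for (st in strands) if (passes(pos, st)) { hit <- st; break }
    if (!is.null(hit)) {
      sites[[length(sites) + 1L]] <- list(start = pos, strand = hit)
      pos <- pos + hl + cfg$min_gap
    } else {
      pos <- pos + 1L
    }
  }
  sites
}

toy_design_world <- function(target_len, seed = 53) {
  withr::with_seed(seed, {
    genome <- random_dna_str(1500 + target_len)
    start <- 800L
    list(target = target_sequence("toy",
                                  substr(genome, start + 1L,
                                         start + target_len),
                                  seqname = "chr1", ref_start = start),
         idx = background_index(c(chr1 = genome)))
  })
}

test_that("targets shorter than one hybridizing region yield an empty set", {
  tg <- target_sequence("short", strrep("ACGT", 10)) # 40 nt < 42
  expect_warning(pr <- tile_target(tg), "no qualifying")
  expect_identical(nrow(pr), 0L)
})

test_that("greedy tiling matches the exhaustive-enumeration reference", {
  w <- toy_design_world(160L)
  cfg <- design_config()
  pr <- tile_target(w$target, w$idx, cfg)
  ref <- oracle_tile_sites(w$target, w$idx, cfg)
  expect_identical(nrow(pr), length(ref))
  expect_identical(pr$target_start,
                   vapply(ref, function(s) s$start, integer(1)))
  expect_identical(pr$strand,
                   vapply(ref, function(s) s$strand, character(1)))
})

test_that("tiling is deterministic and emits only valid probes", {
  w <- toy_design_world(320L, seed = 59)
  pr1 <- tile_target(w$target, w$idx)
  pr2 <- tile_target(w$target, w$idx)
  expect_identical(pr1, pr2)
  expect_gte(nrow(pr1), 2L)
  expect_true(all(validate_probes(pr1)$ok))
  # mutually non-overlapping with the minimum gap
  starts <- pr1$target_start
  expect_true(all(diff(starts) >= 42L + 10L))
})

test_that("probe density never exceeds the packing bound", {
  w <- toy_design_world(400L, seed = 61)
  cfg <- design_config()
  pr <- tile_target(w$target, w$idx, cfg)
  dens <- design_metrics(pr, target = w$target, config = cfg)$probes_per_kb
  expect_lte(dens, 1000 / (cfg$hybrid_len + cfg$min_gap))
})

test_that("cross-hybridizing probe pairs are pruned greedily", {
  w <- toy_design_world(320L, seed = 59)
  pr <- tile_target(w$target, w$idx)
  # duplicated probe: later copy dropped
  dup <- pr[c(1, 1), ]
  dup$target_start <- c(0L, 100L)
  expect_identical(nrow(cross_hyb_filter(dup)), 1L)
  # a pair sharing a planted 12-nt complement: exactly one dropped
  a <- pr[1, ]
  b <- pr[2, ]
  frag <- substr(a$full_seq, 20, 31) # 12 nt of probe a
  b$full_seq <- paste0(substr(b$full_seq, 1, 20), revcomp(frag),
                       substr(b$full_seq, 33, 56))
  pair <- dplyr::bind_rows(a, b)
  kept <- cross_hyb_filter(pair)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$probe_id, a$probe_id) # later probe dropped
  # disjoint probes (no >= 10 nt complementarity, by the oracle) survive
  rc_b <- revcomp(pr$full_seq[2])
  max_comp <- max(vapply(1:(56 - 9), function(s0) {
    pat <- substr(pr$full_seq[1], s0, s0 + 9)
    if (grepl(pat, rc_b, fixed = TRUE)) 10L else 0L
  }, integer(1)))
  if (max_comp < 10L) {
    expect_identical(nrow(cross_hyb_filter(pr[1:2, ])), 2L)
  }
})

test_that("design metrics reproduce the published arithmetic", {
  m29 <- design_metrics(29, 2500)
  expect_equal(m29$probes_per_kb, 11.6)
  expect_identical(m29$min_dye_quencher_gap_nt, 24L)
  expect_equal(m29$gap_nm, 7.92)
  expect_equal(design_metrics(34, 2500)$probes_per_kb, 13.6)
  expect_equal(design_metrics(0, 2500)$probes_per_kb, 0)
})

test_that("probe tables round-trip through TSV and BED", {
  w <- toy_design_world(160L)
  pr <- tile_target(w$target, w$idx)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_probe_tsv(pr, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_identical(names(back), names(pr))
  expect_equal(back$tm_hybrid, pr$tm_hybrid)
  write_probe_bed(pr, bed)
  bed_tb <- readr::read_tsv(bed, col_names = FALSE, show_col_types = FALSE)
  expect_identical(ncol(bed_tb), 6L)
  expect_equal(bed_tb$X5, round(pr$tm_hybrid * 10))
})
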