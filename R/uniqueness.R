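#' Build a background sequence index for the uniqueness screen
#'
#' Loads the background genome (the sequences a probe must not match outside
#' its own target locus) into a simple exact-substring index. Matching is
#' performed on both strands of the background by also screening the reverse
#' complement of the query.
#'
#' @param x A FASTA file path, a named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return An object of class `background_index`.
#' @export
background_index <- function(x) {
  seqs <- if (inherits(x, "DNAStringSet")) {
    x
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    Biostrings::readDNAStringSet(x)
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    Biostrings::DNAStringSet(x)
  } else {
    abort("`x` must be a FASTA path, named character vector, or DNAStringSet.")
  }
  if (length(seqs) == 0L) abort("empty background index.")
  structure(list(seqs = seqs), class = "background_index")
}

# subject strings with the excluded target interval masked out by N
masked_subjects <- function(index, target_interval = NULL) {
  subj <- as.character(index$seqs)
  if (!is.null(target_interval)) {
    nm <- target_interval$seqname
    if (nm %in% names(subj)) {
      s <- subj[[nm]]
      from <- target_interval$start + 1L # 0-based half-open -> 1-based
      to <- target_interval$end
      substr(s, from, to) <- paste(rep("N", to - from + 1L), collapse = "")
      subj[[nm]] <- s
    }
  }
  subj
}

#' Longest off-target exact match of a probe sequence
#'
#' Finds the maximum length of an exact match between `seq` (or its reverse
#' complement) and the background sequences, excluding the probe's own target
#' interval. This operationalizes the published off-target rule "maximum
#' identical sequence restrained to 22 nt" (human mode; 25 nt for mouse) as
#' an exact longest-common-substring screen over both strands.
#'
#' @param seq Query DNA string (typically the 42-nt hybridizing region).
#' @param index A [background_index()].
#' @param target_interval Optional list `(seqname, start, end)` (0-based
#'   half-open) naming the locus the probe is designed against; matches
#'   overlapping this interval are not counted.
#' @param max_identity Longest tolerated match (nt); defaults from `config`.
#' @param config A [design_config()].
#' @return A one-row tibble with `max_match` (nt) and `pass` (logical,
#'   `max_match <= max_identity`).
#' @export
uniqueness_screen <- function(seq, index, target_interval = NULL,
                              max_identity = NULL,
                              config = design_config()) {
  check_dna(seq)
  if (!inherits(index, "background_index")) abort("`index` must be a background_index.")
  max_identity <- max_identity %||% config$max_identity
  subj <- masked_subjects(index, target_interval)
  n <- nchar(seq)
  queries <- c(seq, rc_chr(seq))
  has_match_len <- function(L) {
    pats <- unique(unlist(lapply(queries, function(q) {
      substring(q, seq_len(n - L + 1L), L:n)
    })))
    any(vapply(pats, function(p) any(grepl(p, subj, fixed = TRUE)),
               logical(1)))
  }
  # occurrence at length L implies occurrence at L - 1: binary search
  lo <- 0L; hi <- n
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (has_match_len(mid)) lo <- mid else hi <- mid - 1L
  }
  tibble(max_match = lo, pass = lo <= max_identity)
}
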