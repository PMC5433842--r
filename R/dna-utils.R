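#' DNA string helpers
#'
#' Small utilities shared by the probe-design functions. Sequences are plain
#' upper-case character strings over the strict ACGT alphabet; IUPAC ambiguity
#' codes are rejected because every downstream thermodynamic rule needs a
#' definite base.
#'
#' @param seq A single DNA string.
#' @return `revcomp()` returns the reverse complement; `gc_fraction()` the
#'   G+C fraction; `longest_run()` the length of the longest homopolymer run.
#' @examples
#' revcomp("ACCGT")
#' gc_fraction("GGCC")
#' longest_run("AATTTTG")
#' @name dna-utils
NULL

check_dna <- function(seq, what = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("`%s` must be a single DNA string.", what),
          class = "mbstorm_invalid_sequence")
  }
  if (nchar(seq) == 0L || grepl("[^ACGT]", seq)) {
    abort(sprintf("`%s` must be non-empty and contain only A, C, G, T.", what),
          class = "mbstorm_invalid_sequence")
  }
  invisible(seq)
}

# hot-path reverse complement without validation
rc_chr <- function(seq) {
  intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", seq))))
}

#' @rdname dna-utils
#' @export
revcomp <- function(seq) {
  check_dna(seq)
  rc_chr(seq)
}

#' @rdname dna-utils
#' @export
gc_fraction <- function(seq) {
  check_dna(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mean(b %in% c("G", "C"))
}

#' @rdname dna-utils
#' @export
longest_run <- function(seq) {
  check_dna(seq)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1L]])
  max(r$lengths)
}

# internal: complement without reversing
complement_chr <- function(seq) chartr("ACGT", "TGCA", seq)

# internal: random DNA of length n from the global RNG
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
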