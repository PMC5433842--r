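# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementation.

# --- nearest-neighbor table (independent transcription) ---------------------
.oracle_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
                CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
                CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
                CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.oracle_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
                CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
                CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
                CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

oracle_nn_sums <- function(seq, init = TRUE) {
  n <- nchar(seq)
  steps <- substring(seq, 1:(n - 1), 2:n)
  H <- sum(.oracle_dH[steps])
  S <- sum(.oracle_dS[steps])
  if (init) {
    ends <- substring(seq, c(1, n), c(1, n))
    for (e in ends) {
      if (e %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
      else { H <- H + 2.3; S <- S + 4.1 }
    }
  }
  c(dH = H, dS = S)
}

oracle_tm <- function(seq, ct = 250e-9, na_M = 1, fa = 0) {
  s <- oracle_nn_sums(seq)
  s[["dH"]] * 1000 / (s[["dS"]] + 1.9872 * log(ct / 4)) - 273.15 +
    16.6 * log10(na_M) - 0.65 * fa
}

# --- exhaustive maximal-stem enumeration ------------------------------------
oracle_stems <- function(seq, min_stem = 4L, min_loop = 3L) {
  b <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(b)
  pairs <- function(i, j) b[j] == comp[[b[i]]]
  out <- list()
  for (i in 1:(n - 1)) {
    for (j in n:(i + 1)) {
      if (!pairs(i, j)) next
      # outward-maximal start of a run?
      if (i > 1 && j < n && pairs(i - 1, j + 1)) next
      len <- 1L
      while (i + len <= n && j - len >= 1 && i + len < j - len &&
             pairs(i + len, j - len)) {
        len <- len + 1L
      }
      L <- len
      while (L >= 1L && (j - L + 1L) - (i + L - 1L) - 1L < min_loop) {
        L <- L - 1L
      }
      if (L >= min_stem) {
        out[[length(out) + 1L]] <- c(i, i + L - 1L, j - L + 1L, j)
      }
    }
  }
  if (length(out) == 0L) {
    return(matrix(integer(0), ncol = 4))
  }
  m <- unique(do.call(rbind, out))
  m[order(m[, 1], m[, 4]), , drop = FALSE]
}

# --- brute-force longest off-target exact match -----------------------------
oracle_longest_match <- function(query, subjects) {
  rc <- function(s) intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s))))
  qs <- c(query, rc(query))
  best <- 0L
  for (q in qs) {
    n <- nchar(q)
    for (L in n:1) {
      if (L <= best) break
      found <- FALSE
      for (s0 in 1:(n - L + 1)) {
        pat <- substr(q, s0, s0 + L - 1)
        if (any(grepl(pat, subjects, fixed = TRUE))) { found <- TRUE; break }
      }
      if (found) { best <- max(best, L); break }
    }
  }
  best
}

# --- brute-force hypergeometric tail by enumeration -------------------------
oracle_hypergeom_enum <- function(n_pos, k_pos, n_neg, k_neg) {
  N <- n_pos + n_neg
  K <- k_pos + k_neg
  if (K == 0) return(1)
  hits <- utils::combn(N, K, function(cells) sum(cells <= n_pos) >= k_pos)
  mean(hits)
}

# --- reference DBSCAN with a full distance matrix ---------------------------
oracle_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  visited <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    stack <- i
    while (length(stack) > 0) {
      j <- stack[[1]]
      stack <- stack[-1]
      if (visited[j] && labels[j] > 0L) next
      visited[j] <- TRUE
      labels[j] <- cl
      if (core[j]) {
        stack <- c(stack, setdiff(nb[[j]], which(visited & labels > 0L)))
      }
    }
  }
  labels
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
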