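# Independent brute-force oracles. These deliberately re-derive results with
# naive algorithms (codon lookup, quadratic segment scan, full DP matrices,
# exhaustive enumeration) so the implementation is checked against a second,
# unrelated code path.

# hand-built standard codon table (independent of Biostrings)
ORACLE_CODONS <- local({
  b <- c("T", "C", "A", "G")
  aa <- paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  )
  codons <- unlist(lapply(b, function(b1) {
    unlist(lapply(b, function(b2) paste0(b1, b2, b)))
  }))
  setNames(strsplit(aa, "")[[1]], codons)
})

oracle_translate <- function(seq, frame_offset = 0) {
  s <- substr(seq, frame_offset + 1, nchar(seq))
  n <- (nchar(s) %/% 3) * 3
  if (n == 0) return("")
  cod <- substring(s, seq(1, n, 3), seq(3, n, 3))
  paste(vapply(cod, function(cc) {
    if (grepl("N", cc)) "X" else unname(ORACLE_CODONS[cc])
  }, character(1)), collapse = "")
}

# quadratic best-segment scan for modified-Mott trimming; ties resolved to
# the smallest start, then the smallest end
oracle_mott <- function(q, limit) {
  n <- length(q)
  if (n == 0) return(c(0L, -1L))
  s <- limit - 10^(-q / 10)
  cs <- cumsum(c(0, s))
  best <- 0; bs <- 0L; be <- -1L
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- cs[j + 1] - cs[i]
      if (v > best + 1e-12) { best <- v; bs <- i; be <- j }
    }
  }
  c(bs, be)
}

# full-matrix affine-gap fit alignment (pattern global, free end gaps on the
# reference); returns the optimal score
oracle_align_score <- function(pattern, ref, match = 1, mismatch = -2,
                               gap_open = -3, gap_extend = -1) {
  p <- strsplit(pattern, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(p); m <- length(r)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # pattern base against a gap (insertion)
  Y <- matrix(NEG, n + 1, m + 1)  # reference base against a gap (deletion)
  M[1, ] <- 0                     # free leading reference
  for (i in 1:n) {
    X[i + 1, ] <- pmax(M[i, ] + gap_open, X[i, ] + gap_extend)
    for (j in seq_len(m)) {
      s <- if (p[i] == r[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open, Y[i + 1, j] + gap_extend)
    }
  }
  max(pmax(M[n + 1, ], X[n + 1, ]))  # free trailing reference
}

# exhaustive barcode feasibility: enumerate all 4^k candidates, filter
# homopolymer runs, lexicographic greedy packing at the distance floor
oracle_barcode_greedy_max <- function(k, min_dist) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)
  cand <- sort(apply(as.matrix(grid), 1, paste, collapse = ""))
  cand <- cand[!grepl("AA|CC|GG|TT", cand)]
  sel <- character(0)
  for (x in cand) {
    ok <- TRUE
    for (s in sel) {
      d <- sum(strsplit(x, "")[[1]] != strsplit(s, "")[[1]])
      if (d < min_dist) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, x)
  }
  sel
}

oracle_pairwise_dist_ok <- function(set, min_dist) {
  n <- length(set)
  if (n < 2) return(TRUE)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sum(strsplit(set[i], "")[[1]] != strsplit(set[j], "")[[1]])
      if (d < min_dist) return(FALSE)
    }
  }
  TRUE
}

# longest substring of a whose reverse complement occurs in b, by checking
# every substring (quadratic-cubic, tiny inputs only)
oracle_complementary_run <- function(a, b) {
  rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  na <- nchar(a)
  best <- 0
  for (i in seq_len(na)) {
    for (j in i:na) {
      if (j - i + 1 <= best) next
      if (grepl(rc(substr(a, i, j)), b, fixed = TRUE)) best <- j - i + 1
    }
  }
  best
}

oracle_mean_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)))
}
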