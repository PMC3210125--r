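# Barcode and fusion-primer design under the amplicon-sequencing rules:
# 5' layout adaptor + barcode + gene-specific primer, barcodes without
# adjacent repeated bases and pairwise Hamming distance >= 2.

#' Generate a barcode set
#'
#' Constructs `n` distinct `k`-mer barcodes containing no homopolymer run (no
#' two identical adjacent bases) with all pairwise Hamming distances at least
#' `min_dist`. The full candidate space is enumerated, a deterministic
#' lexicographic greedy pass builds the maximal achievable code, and `seed`
#' selects which `n` members are returned (any subset of a valid code is
#' valid). Fails with a capacity error reporting the achievable maximum when
#' `n` is infeasible.
#'
#' @param k barcode length in bases.
#' @param n number of barcodes requested.
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return tibble with column `barcode`, in stable (lexicographic) order.
#' @export
#' @examples
#' generate_barcode_set(5, 39, min_dist = 2, seed = 1)
generate_barcode_set <- function(k, n, min_dist = 2, seed = 1) {
  stopifnot(k >= 1, n >= 1, min_dist >= 1)
  pool <- barcode_code(k, min_dist)
  if (n > length(pool)) {
    abort(paste0("capacity error: only ", length(pool), " barcodes of length ",
                 k, " achievable at min_dist ", min_dist,
                 " without adjacent repeats (", n, " requested)"))
  }
  sel <- withr_seed(seed, sample(length(pool), n))
  tibble(barcode = pool[sort(sel)])
}

# run code under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# maximal greedy code over all homopolymer-free k-mers, lexicographic order
barcode_code <- function(k, min_dist) {
  cand <- all_kmers(k)
  cand <- cand[!has_adjacent_repeat(cand)]
  if (min_dist <= 1) return(cand)
  m <- do.call(rbind, strsplit(cand, ""))
  keep <- integer(0)
  for (i in seq_along(cand)) {
    if (length(keep) == 0) { keep <- i; next }
    d <- rowSums(m[keep, , drop = FALSE] != matrix(m[i, ], length(keep), k, byrow = TRUE))
    if (all(d >= min_dist)) keep <- c(keep, i)
  }
  cand[keep]
}

all_kmers <- function(k) {
  # lexicographic order: later positions vary fastest
  g <- do.call(tidyr::expand_grid,
               setNames(rep(list(DNA_BASES), k), paste0("p", seq_len(k))))
  apply(as.matrix(g), 1, paste, collapse = "")
}

# independent re-validation used by callers and tests
barcode_set_valid <- function(barcodes, min_dist = 2) {
  if (any(has_adjacent_repeat(barcodes))) return(FALSE)
  if (anyDuplicated(barcodes)) return(FALSE)
  nb <- length(barcodes)
  if (nb < 2) return(TRUE)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      if (hamming(barcodes[i], barcodes[j]) < min_dist) return(FALSE)
    }
  }
  TRUE
}

#' Assemble a fusion primer
#'
#' A fusion primer is adaptor + barcode + gene-specific primer, 5' to 3'. The
#' adaptor must be a 19-mer (A adaptor for forward, B adaptor for reverse
#' primers) and the barcode must pass the barcode rules (no adjacent repeated
#' bases).
#'
#' @param adaptor 19-mer adaptor sequence.
#' @param barcode barcode sequence without adjacent repeats.
#' @param gene_primer gene-specific primer (IUPAC degeneracy allowed).
#' @param direction `"forward"` or `"reverse"`.
#' @return one-row tibble with the components and the full `sequence`.
#' @export
assemble_fusion_primer <- function(adaptor, barcode, gene_primer,
                                   direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (nchar(adaptor) != 19) abort("adaptor must be a 19-mer")
  if (has_adjacent_repeat(barcode))
    abort(paste0("invalid barcode '", barcode, "': contains adjacent repeated bases"))
  if (grepl("[^ACGT]", barcode)) abort("barcode must be plain A/C/G/T")
  tibble(adaptor = adaptor, barcode = barcode, gene_primer = gene_primer,
         direction = direction,
         sequence = paste0(adaptor, barcode, gene_primer))
}

#' Validate a fusion-primer pair
#'
#' Report-only checks for one amplicon's primer pair: the 440 bp product
#' length cap, nearest-neighbor melting-temperature estimates (advisory), and
#' the longest self- and cross-complementary runs as a string-based dimer
#' screen. Runs at or above `run_threshold` are flagged.
#'
#' @param fwd,rev one-row tibbles from [assemble_fusion_primer()].
#' @param amplicon_len expected product length in bp.
#' @param run_threshold complementary-run length that raises a flag.
#' @return one-row tibble report with length/Tm/dimer fields and flags.
#' @export
check_primer_pair <- function(fwd, rev, amplicon_len, run_threshold = 8) {
  self_f <- longest_complementary_run(fwd$sequence, fwd$sequence)
  self_r <- longest_complementary_run(rev$sequence, rev$sequence)
  cross <- longest_complementary_run(fwd$sequence, rev$sequence)
  tibble(
    amplicon_len = amplicon_len,
    length_ok = amplicon_len <= 440,
    tm_fwd = primer_tm(fwd$gene_primer),
    tm_rev = primer_tm(rev$gene_primer),
    self_run_fwd = self_f, self_run_rev = self_r, cross_run = cross,
    dimer_flag = max(self_f, self_r, cross) >= run_threshold
  )
}

# longest substring of `a` whose reverse complement occurs in `b`
# (classic longest-common-substring DP between a and revcomp(b))
longest_complementary_run <- function(a, b) {
  x <- seq_chars(a)
  y <- seq_chars(revcomp(b))
  n <- length(x); m <- length(y)
  best <- 0L
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    for (j in seq_len(m)) {
      if (x[i] == y[j]) {
        cur[j] <- if (j == 1) 1L else prev[j - 1] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# nearest-neighbor Tm (unified dinucleotide parameters, 50 mM Na+, 200 nM
# primer); degenerate positions are resolved to their first matching base.
# Advisory only — never used as a hard gate.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)

primer_tm <- function(primer, conc = 2e-7, na = 0.05) {
  s <- vapply(seq_chars(primer), function(b) IUPAC_SETS[[b]][1], character(1))
  if (length(s) < 2) return(NA_real_)
  dh <- 0.2; ds <- -5.7  # initiation
  for (i in seq_len(length(s) - 1)) {
    d <- paste0(s[i], s[i + 1])
    if (!d %in% names(NN_DH)) d <- revcomp(d)
    dh <- dh + NN_DH[[d]]
    ds <- ds + NN_DS[[d]]
  }
  ds <- ds + 0.368 * (length(s) - 1) * log(na)  # salt correction
  tm <- dh * 1000 / (ds + 1.987 * log(conc / 4)) - 273.15
  round(tm, 1)
}
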