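# Shared low-level helpers: sequence arithmetic, IUPAC matching, phred maths.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide code -> set of plain bases it matches
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a nucleotide string
#'
#' Accepts plain and IUPAC-degenerate bases; vectorised.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# split a string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

# TRUE if the string contains two identical adjacent bases
has_adjacent_repeat <- function(x) {
  grepl("AA|CC|GG|TT", x, fixed = FALSE)
}

# number of mismatches of `obs` (plain ACGT) against `pat` (IUPAC allowed);
# an N in obs always matches
iupac_mismatches <- function(obs, pat) {
  co <- seq_chars(obs)
  cp <- seq_chars(pat)
  stopifnot(length(co) == length(cp))
  ok <- vapply(seq_along(co), function(i) {
    if (co[[i]] == "N") return(TRUE)
    co[[i]] %in% IUPAC_SETS[[cp[[i]]]]
  }, logical(1))
  sum(!ok)
}

# phred <-> error probability
phred_to_perr <- function(q) 10^(-q / 10)
perr_to_phred <- function(p) -10 * log10(pmax(p, 1e-10))

# one phred vector -> one ascii (phred+33) string
phred_to_ascii <- function(q) {
  if (length(q) == 0) return("")
  intToUtf8(pmin(pmax(round(q), 0), 60) + 33L)
}

ascii_to_phred <- function(s) utf8ToInt(s) - 33L

# mean quality in a +/- radius window around every base (read coordinates);
# partial windows at the edges use the available bases
window_mean_qual <- function(q, radius) {
  n <- length(q)
  if (n == 0) return(numeric(0))
  cs <- cumsum(c(0, q))
  lo <- pmax(seq_len(n) - radius, 1L)
  hi <- pmin(seq_len(n) + radius, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# round half up to `digits` decimals (matches the survey's table formatting;
# base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
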