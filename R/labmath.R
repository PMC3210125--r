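# Bench quantitation utilities: equimolar-pool molecule counting and peptide
# physicochemical properties.

AVOGADRO <- 6.02214076e23

#' Molecules per microlitre of an amplicon solution
#'
#' molecules/ul = C x 1e-9 x N_A / (bp_w x bp) — the standard dsDNA
#' conversion used to equalize amplicon pools before emulsion PCR. With a
#' `target` (e.g. 7e9 molecules/ul) the dilution factor to reach it is also
#' returned. Linear in `C` and inversely proportional to `bp`.
#'
#' @param conc amplicon concentration C in ng/ul (vectorised).
#' @param bp amplicon length in base pairs.
#' @param bp_w average mass per base pair in g/mol (default 660, the common
#'   dsDNA convention).
#' @param target optional desired molecules/ul.
#' @return tibble: `conc`, `bp`, `molecules_per_ul`, and `dilution_factor`
#'   when `target` is given.
#' @export
#' @examples
#' molecules_per_ul(3.07, 400)  # ~7e9 molecules/ul
molecules_per_ul <- function(conc, bp, bp_w = 660, target = NULL) {
  stopifnot(all(conc >= 0), all(bp >= 1), bp_w > 0)
  m <- conc * 1e-9 * AVOGADRO / (bp_w * bp)
  out <- tibble(conc = conc, bp = bp, molecules_per_ul = m)
  if (!is.null(target)) out$dilution_factor <- m / target
  out
}

# average residue masses (Da) and water
RESIDUE_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                  C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                  H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                  M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

# ionizable-group pKa tables
PKA_TABLES <- list(
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  bjellqvist = c(Nterm = 7.5, Cterm = 3.55, C = 9.0, D = 4.05, E = 4.45,
                 H = 5.98, K = 10.0, R = 12.0, Y = 10.0)
)

HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W")

#' Peptide physicochemical properties
#'
#' Molecular weight from average residue masses plus one water (reduced
#' chains, no disulfide mass correction), isoelectric point by bisection on
#' the Henderson-Hasselbalch net-charge function, and the hydrophobicity
#' ratio as the percentage of residues in the hydrophobic set
#' {A,C,F,I,L,M,V,W}.
#'
#' @param peptides character vector of standard 20-letter peptide sequences.
#' @param pka pKa table: `"emboss"` (default) or `"bjellqvist"`.
#' @param hydrophobic residues counted as hydrophobic.
#' @return tibble: `peptide`, `length`, `mw_da`, `mw_kda`,
#'   `isoelectric_point`, `hydrophobicity_pct`.
#' @export
#' @examples
#' peptide_properties("G")  # 75.07 Da
peptide_properties <- function(peptides, pka = c("emboss", "bjellqvist"),
                               hydrophobic = HYDROPHOBIC_SET) {
  pka <- PKA_TABLES[[match.arg(pka)]]
  bad <- lapply(peptides, function(p) {
    ch <- seq_chars(p)
    unique(ch[!ch %in% names(RESIDUE_MASS)])
  })
  if (any(lengths(bad) > 0)) {
    abort(paste0("non-standard residue letter(s): ",
                 paste(unique(unlist(bad)), collapse = ", ")))
  }
  rows <- lapply(peptides, function(p) {
    ch <- seq_chars(p)
    mw <- sum(RESIDUE_MASS[ch]) + WATER_MASS
    tibble(peptide = p, length = length(ch), mw_da = mw, mw_kda = mw / 1000,
           isoelectric_point = isoelectric_point(ch, pka),
           hydrophobicity_pct = 100 * mean(ch %in% hydrophobic))
  })
  bind_rows(rows)
}

# net charge at a pH: termini + D/E/C/Y (acidic) and H/K/R (basic)
peptide_net_charge <- function(chars, ph, pka = PKA_TABLES$emboss) {
  pos_groups <- c(Nterm = 1, table(factor(chars, levels = c("H", "K", "R"))))
  neg_groups <- c(Cterm = 1, table(factor(chars, levels = c("C", "D", "E", "Y"))))
  pos <- sum(pos_groups * 1 / (1 + 10^(ph - pka[names(pos_groups)])))
  neg <- sum(neg_groups * 1 / (1 + 10^(pka[names(neg_groups)] - ph)))
  pos - neg
}

isoelectric_point <- function(chars, pka) {
  f <- function(ph) peptide_net_charge(chars, ph, pka)
  uniroot(f, c(0, 14), tol = 1e-8)$root
}
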