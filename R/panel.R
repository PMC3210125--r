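# Reference amplicon panel: data model, I/O and coordinate bookkeeping.
#
# Coordinates are 1-based inclusive on the sense strand of the amplified
# transcript. Each amplicon row records where it sits in its AMP transcript
# (`tx_start`) and where codon 1 of the precursor starts in that transcript
# (`cds_tx_start`), so overlapping amplicons of one AMP share a codon frame.

AMP_IDS <- c("MytA", "MytB", "MytC", "MytlB", "MytlC", "MytlD",
             "MytM", "MGD1", "MGDt")

#' Default 454-style sequencing adaptors (19-mers)
#' @name adaptors
#' @keywords internal
ADAPTOR_A <- "CCATCTCATCCCTGCGTGT"
ADAPTOR_B <- "CCTATCCCCTGTGTGCCTT"

#' Load a reference amplicon panel
#'
#' Reads a panel from a FASTA file of amplicon sequences plus two TSV sidecars:
#' an amplicon metadata table and a barcode assignment table. All structural
#' invariants are validated (length cap of 440 bp, codon-multiple covered cds,
#' cysteine arrays of 8 — 12 for MytM — inside the mature peptide, regions
#' partitioning the precursor, one barcode per sample/amplicon/direction,
#' barcodes unique within each direction).
#'
#' @param fasta path to the amplicon FASTA file (record names = amplicon_id).
#' @param amplicons path to the amplicon metadata TSV. Required columns:
#'   `amplicon_id`, `amp_id`, `tx_start`, `cds_start`, `cds_end`,
#'   `cds_frame_offset`, `cds_tx_start`, `signal_start`, `signal_end`,
#'   `mature_start`, `mature_end`, `cterm_start`, `cterm_end` (NA when the AMP
#'   has no C-terminal extension), `cys_positions` (comma-separated aa
#'   indices), `fwd_primer`, `rev_primer`.
#' @param barcodes path to the barcode TSV with columns `sample_id`,
#'   `amplicon_id`, `direction` (`forward`/`reverse`), `barcode`.
#' @param adaptor_a,adaptor_b 19-mer sequencing adaptors fused 5' of forward
#'   and reverse primers respectively.
#' @return an object of class `amp_panel`: a list with tibbles `amplicons` and
#'   `barcodes` plus the two adaptors.
#' @export
load_panel <- function(fasta, amplicons, barcodes,
                       adaptor_a = ADAPTOR_A, adaptor_b = ADAPTOR_B) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- readr::read_tsv(amplicons, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            cys_positions = readr::col_character(),
                            fwd_primer = readr::col_character(),
                            rev_primer = readr::col_character()
                          ))
  bc <- readr::read_tsv(barcodes, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  amp <- meta %>%
    mutate(across(dplyr::any_of(c("tx_start", "cds_start", "cds_end",
                                  "cds_frame_offset", "cds_tx_start",
                                  "signal_start", "signal_end", "mature_start",
                                  "mature_end", "cterm_start", "cterm_end")),
                  as.integer)) %>%
    mutate(
      sequence = {
        missing <- setdiff(.data$amplicon_id, names(seqs))
        if (length(missing) > 0) {
          abort(paste0("missing sequence for metadata row(s): ",
                       paste(missing, collapse = ", ")))
        }
        unname(as.character(seqs[.data$amplicon_id]))
      },
      length = nchar(.data$sequence),
      cys_positions = lapply(strsplit(as.character(.data$cys_positions), ","),
                             as.integer)
    )
  new_panel(amp, bc, adaptor_a, adaptor_b)
}

new_panel <- function(amplicons, barcodes, adaptor_a, adaptor_b) {
  panel <- structure(
    list(amplicons = as_tibble(amplicons), barcodes = as_tibble(barcodes),
         adaptor_a = adaptor_a, adaptor_b = adaptor_b),
    class = "amp_panel"
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  amp <- panel$amplicons
  bc <- panel$barcodes
  for (i in seq_len(nrow(amp))) {
    a <- amp[i, ]
    id <- a$amplicon_id
    fail <- function(msg) abort(paste0("amplicon ", id, ": ", msg))
    if (!a$amp_id %in% AMP_IDS) fail(paste0("unknown amp_id ", a$amp_id))
    if (grepl("[^ACGT]", a$sequence)) fail("reference sequence must be plain A/C/G/T")
    if (a$length > 440) fail(paste0("length ", a$length, " exceeds the 440 bp amplicon cap"))
    if (!(a$cds_start >= 1 && a$cds_start <= a$cds_end && a$cds_end <= a$length))
      fail("cds coordinates out of range")
    if (!a$cds_frame_offset %in% 0:2) fail("cds_frame_offset must be 0-2")
    covered <- a$cds_end - a$cds_start + 1 - a$cds_frame_offset
    if (covered %% 3 != 0)
      fail("covered cds is not a whole number of codons after frame adjustment")
    if ((a$tx_start + a$cds_start - 1 + a$cds_frame_offset - a$cds_tx_start) %% 3 != 0)
      fail("cds_start/cds_frame_offset inconsistent with cds_tx_start frame")
    cys <- a$cys_positions[[1]]
    n_expected <- if (a$amp_id == "MytM") 12L else 8L
    if (length(cys) != n_expected)
      fail(paste0("expected ", n_expected, " cysteine positions, got ", length(cys)))
    if (any(cys < a$mature_start | cys > a$mature_end))
      fail("cysteine positions must fall inside the mature-peptide span")
    if (a$signal_start != 1) fail("signal peptide must start at aa 1")
    if (a$mature_start != a$signal_end + 1)
      fail("mature peptide must follow the signal peptide without gap or overlap")
    if (is.na(a$cterm_start) != is.na(a$cterm_end))
      fail("cterm_start/cterm_end must both be set or both NA")
    if (!is.na(a$cterm_start) && a$cterm_start != a$mature_end + 1)
      fail("C-terminal extension must follow the mature peptide without gap or overlap")
    for (p in c(a$fwd_primer, a$rev_primer)) {
      if (grepl(paste0("[^", paste(names(IUPAC_SETS), collapse = ""), "]"), p))
        fail("primer contains a non-IUPAC letter")
    }
  }
  if (anyDuplicated(amp$amplicon_id)) abort("duplicate amplicon_id in panel")
  if (nchar(panel$adaptor_a) != 19 || nchar(panel$adaptor_b) != 19)
    abort("adaptors must be 19-mers")

  key <- paste(bc$sample_id, bc$amplicon_id, bc$direction)
  if (anyDuplicated(key))
    abort(paste0("duplicate barcode assignment for: ", key[duplicated(key)][1]))
  full <- tidyr::expand_grid(sample_id = unique(bc$sample_id),
                             amplicon_id = amp$amplicon_id,
                             direction = c("forward", "reverse"))
  miss <- anti_join(full, bc, by = c("sample_id", "amplicon_id", "direction"))
  if (nrow(miss) > 0)
    abort(paste0("missing barcode for: ",
                 paste(miss$sample_id[1], miss$amplicon_id[1], miss$direction[1])))
  dup <- bc %>%
    distinct(.data$direction, .data$barcode, .data$sample_id, .data$amplicon_id) %>%
    count(.data$direction, .data$barcode, .data$sample_id) %>%
    group_by(.data$direction, .data$barcode) %>%
    summarise(n_samples = n(), .groups = "drop") %>%
    filter(.data$n_samples > 1)
  # a barcode may tag all amplicons of one sample, but two samples sharing a
  # barcode in the same direction would be unresolvable
  if (nrow(dup) > 0)
    abort(paste0("barcode ", dup$barcode[1], " (", dup$direction[1],
                 ") assigned to more than one sample"))
  invisible(panel)
}

#' @export
print.amp_panel <- function(x, ...) {
  cat("<amp_panel> ", nrow(x$amplicons), " amplicons, ",
      length(unique(x$amplicons$amp_id)), " AMPs, ",
      length(unique(x$barcodes$sample_id)), " samples\n", sep = "")
  print(select(x$amplicons, -"sequence"), ...)
  invisible(x)
}

#' Write a panel back to FASTA + TSV sidecars
#'
#' Inverse of [load_panel()]: reproduces sequences and metadata so that a
#' reload round-trips byte-identically at the field level.
#'
#' @param panel an `amp_panel`.
#' @param dir output directory (created if needed).
#' @param basename file stem; writes `<basename>.fasta`,
#'   `<basename>_amplicons.tsv`, `<basename>_barcodes.tsv`.
#' @return invisibly, the three paths written.
#' @export
write_panel <- function(panel, dir, basename = "panel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(basename, ".fasta"))
  seqs <- Biostrings::DNAStringSet(setNames(panel$amplicons$sequence,
                                            panel$amplicons$amplicon_id))
  Biostrings::writeXStringSet(seqs, fa, width = 70)
  meta <- panel$amplicons %>%
    mutate(cys_positions = vapply(.data$cys_positions, paste, character(1),
                                  collapse = ",")) %>%
    select(-"sequence", -"length")
  mt <- file.path(dir, paste0(basename, "_amplicons.tsv"))
  readr::write_tsv(meta, mt)
  bt <- file.path(dir, paste0(basename, "_barcodes.tsv"))
  readr::write_tsv(panel$barcodes, bt)
  invisible(c(fasta = fa, amplicons = mt, barcodes = bt))
}

#' Bundled synthetic demonstration panel
#'
#' A synthetic stand-in for a real reference panel: 13 amplicons covering 9
#' mussel AMP precursor transcripts (two partially overlapping amplicons for
#' MytA, MytC, MytlB and MytlC), six samples, 5-mer barcodes with no adjacent
#' repeats and pairwise Hamming distance >= 2. Sequences were generated once
#' with a fixed seed; region layouts, cysteine arrays and covered-codon counts
#' follow the features of the nine AMP isotypes (precursor lengths 61-152 aa,
#' 8 cysteines — 12 for mytimycin).
#'
#' @return an `amp_panel`.
#' @export
demo_panel <- function() {
  d <- system.file("extdata", package = "ampdiversity")
  load_panel(file.path(d, "demo_panel.fasta"),
             file.path(d, "demo_panel_amplicons.tsv"),
             file.path(d, "demo_panel_barcodes.tsv"))
}

amp_row <- function(panel, amplicon_id) {
  i <- match(amplicon_id, panel$amplicons$amplicon_id)
  if (is.na(i)) abort(paste0("unknown amplicon_id: ", amplicon_id))
  panel$amplicons[i, ]
}

# transcript position of an amplicon-local position
tx_pos <- function(arow, pos) arow$tx_start + pos - 1L

# precursor codon index (aa position) of a transcript position; positions
# before codon 1 give values < 1
tx_codon <- function(arow, txp) ((txp - arow$cds_tx_start) %/% 3L) + 1L

# amplicon-local bounds of the frame-adjusted covered cds
cds_span <- function(arow) {
  c(start = arow$cds_start + arow$cds_frame_offset, end = arow$cds_end)
}

# number of whole codons covered by one amplicon
covered_codons <- function(arow) {
  sp <- cds_span(arow)
  as.integer((sp[["end"]] - sp[["start"]] + 1) / 3)
}

# union of covered precursor codon indices for all amplicons of one AMP
covered_codons_by_amp <- function(panel) {
  parts <- split(panel$amplicons, panel$amplicons$amp_id)
  tibble(
    amp_id = names(parts),
    covered_codons = vapply(parts, function(df) {
      idx <- unlist(lapply(seq_len(nrow(df)), function(i) {
        a <- df[i, ]
        sp <- cds_span(a)
        tx_codon(a, tx_pos(a, sp[["start"]])):tx_codon(a, tx_pos(a, sp[["end"]] - 2L))
      }))
      length(unique(idx))
    }, integer(1), USE.NAMES = FALSE)
  )
}

#' Virtual translation of a coding nucleotide sequence
#'
#' Standard genetic code. The first `frame_offset` bases are skipped, a
#' trailing partial codon is dropped, codons containing N translate to `X`,
#' and stop codons render `*` with translation continuing (read clusters are
#' reported as-is).
#'
#' @param seq nucleotide string (A/C/G/T/N after frame trimming).
#' @param frame_offset 0, 1 or 2 bases to skip before the first codon.
#' @return the peptide string (empty for empty input).
#' @export
#' @examples
#' translate_cds("ATGGCT")     # "MA"
#' translate_cds("TTGTTGT", 1) # "CC"
translate_cds <- function(seq, frame_offset = 0) {
  stopifnot(length(seq) == 1, frame_offset %in% 0:2)
  s <- substr(seq, frame_offset + 1, nchar(seq))
  n <- (nchar(s) %/% 3) * 3
  if (n == 0) return("")
  s <- substr(s, 1, n)
  if (grepl("[^ACGTN]", s)) abort("translate_cds: sequence must be A/C/G/T/N")
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Classify transcript positions into precursor regions
#'
#' Maps an amplicon-local nucleotide position to its precursor codon and then
#' to a region label: `flank` (outside the covered cds), `signal`, `mature`
#' or `c_terminal`. The labels partition every position of the amplicon.
#'
#' @param panel an `amp_panel`.
#' @param amplicon_id amplicon to annotate.
#' @param pos integer vector of 1-based amplicon-local positions.
#' @return character vector of region labels, one per position.
#' @export
locate_region <- function(panel, amplicon_id, pos) {
  a <- amp_row(panel, amplicon_id)
  if (any(pos < 1 | pos > a$length))
    abort(paste0("position out of range 1..", a$length))
  sp <- cds_span(a)
  codon <- tx_codon(a, tx_pos(a, pos))
  out <- rep("flank", length(pos))
  in_cds <- pos >= sp[["start"]] & pos <= sp[["end"]]
  lab <- function(cd) {
    dplyr::case_when(
      cd >= a$signal_start & cd <= a$signal_end ~ "signal",
      cd >= a$mature_start & cd <= a$mature_end ~ "mature",
      !is.na(a$cterm_start) & cd >= a$cterm_start & cd <= a$cterm_end ~ "c_terminal",
      TRUE ~ "flank"
    )
  }
  out[in_cds] <- lab(codon[in_cds])
  out
}
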