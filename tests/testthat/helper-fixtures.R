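# Fixtures built in code: a tiny designed panel with known codons, plus
# small constructors for reads and pileup rows.

# 30-codon precursor: signal aa 1-8 (codon 2 = GCT/Ala, codon 9 = TGT/Cys
# starts the mature cysteine array at odd offsets), mature aa 9-24, C-term
# 25-30; 15 nt 5' UTR, stop + 12 nt 3' UTR; one amplicon spanning the whole
# 120 nt transcript
TINY_CDS <- paste0(
  "ATGGCTCTTAAATCTACTGTTGAT",                          # signal aa 1-8
  "TGTCGTTGCCGATGTAGATGTCGTTGCCGTTGTCGATGTCGTTGCAGA",  # mature aa 9-24
  "AAACTTACTGAATGGGGA"                                 # C-term aa 25-30
)
TINY_TX <- paste0("GATTACAGATTACAG", TINY_CDS, "TAA", "CCGGTTAACCGG")

tiny_panel_env <- new.env()

tiny_panel <- function() {
  if (!is.null(tiny_panel_env$panel)) return(tiny_panel_env$panel)
  d <- withr::local_tempdir(.local_envir = teardown_env())
  len <- nchar(TINY_TX)
  writeLines(c(">TINY_1", TINY_TX), file.path(d, "p.fasta"))
  meta <- tibble::tibble(
    amplicon_id = "TINY_1", amp_id = "MGD1", tx_start = 1L,
    cds_start = 16L, cds_end = 105L, cds_frame_offset = 0L,
    cds_tx_start = 16L,
    signal_start = 1L, signal_end = 8L, mature_start = 9L, mature_end = 24L,
    cterm_start = 25L, cterm_end = 30L,
    cys_positions = "9,11,13,15,17,19,21,23",
    fwd_primer = substr(TINY_TX, 1, 20),
    rev_primer = ampdiversity::revcomp(substr(TINY_TX, len - 19, len))
  )
  readr::write_tsv(meta, file.path(d, "p_amp.tsv"))
  bc <- tidyr::expand_grid(sample_id = c("S1", "S2"), amplicon_id = "TINY_1",
                           direction = c("forward", "reverse"))
  bc$barcode <- rep(c("ACACA", "AGAGA"), each = 2)
  readr::write_tsv(bc, file.path(d, "p_bc.tsv"))
  tiny_panel_env$panel <- load_panel(file.path(d, "p.fasta"),
                                     file.path(d, "p_amp.tsv"),
                                     file.path(d, "p_bc.tsv"))
  tiny_panel_env$panel
}

# hand-made pileup rows matching the build_pileup() schema; counts are taken
# as already quality-passing (raw = qc)
make_pileup <- function(amplicon_id, pos, ref, A = 0, C = 0, G = 0, T = 0,
                        sample_id = "S1", del = 0) {
  tibble::tibble(
    amplicon_id = amplicon_id, sample_id = sample_id, pos = as.integer(pos),
    ref = ref, depth = A + C + G + T, qc_depth = A + C + G + T,
    A = A, C = C, G = G, T = T,
    raw_A = A, raw_C = C, raw_G = G, raw_T = T, del = del
  )
}

make_reads <- function(bases, quals = NULL, ids = NULL) {
  n <- length(bases)
  if (is.null(quals)) {
    quals <- vapply(nchar(bases), function(k) strrep("I", k), character(1))
  }
  tibble::tibble(read_id = ids %||% paste0("r", seq_len(n)),
                 bases = bases, quals = quals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

phred_str <- function(q) intToUtf8(q + 33L)

# amplicon-local [start, end] of the complete codons covered by forward
# reads once the fusion-primer prefix is clipped
clipped_codon_window <- function(panel, amplicon_id) {
  a <- amp_subset(panel, amplicon_id)
  s0 <- max(nchar(a$fwd_primer) + 1L, a$cds_start + a$cds_frame_offset)
  phase <- (s0 - (a$cds_start + a$cds_frame_offset)) %% 3
  w1 <- s0 + (3 - phase) %% 3
  c(w1, a$cds_end)
}

amp_subset <- function(panel, amplicon_id) {
  panel$amplicons[match(amplicon_id, panel$amplicons$amplicon_id), ]
}
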