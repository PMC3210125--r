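# Semi-global mapping of assigned reads onto their reference amplicon
# (Biostrings pairwiseAlignment, free end-gaps on the reference, whole read
# aligned) and coverage summaries.

default_scoring <- function() {
  list(match = 1, mismatch = -2, gap_open = -3, gap_extend = -1)
}

#' Align assigned reads to their reference amplicons
#'
#' Semi-global alignment: the (trimmed, clipped) read aligns end-to-end
#' against a substring of the reference, so end-gaps on the reference are
#' free. Reverse-direction reads are aligned as their reverse complement, so
#' every alignment is reported on the sense strand. Reads whose identity
#' (matches / alignment columns) falls below `min_identity` are flagged
#' non-specific; downstream pileups ignore them.
#'
#' @param reads assigned read tibble (`read_id`, `bases`, `quals`,
#'   `sample_id`, `amplicon_id`, `direction`) as produced by [demultiplex()].
#' @param panel an `amp_panel`.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (defaults +1/-2/-3/-1; the first gap base costs `gap_open`).
#' @param min_identity identity floor below which a read is flagged
#'   non-specific (default 0.8).
#' @return tibble: `read_id`, `sample_id`, `amplicon_id`, `direction`,
#'   `strand`, `ref_start`, `ref_end`, `cigar` (M/X/I/D runs), `identity`,
#'   `score`, `aligned_bases`, `nonspecific`, plus sense-oriented `bases` and
#'   `quals` for pileup construction.
#' @export
align_reads <- function(reads, panel, scoring = default_scoring(),
                        min_identity = 0.8) {
  if (nrow(reads) == 0) return(empty_alignment_tbl())
  reads <- filter(reads, nchar(.data$bases) > 0)
  if (nrow(reads) == 0) return(empty_alignment_tbl())
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE
  )
  go <- -(scoring$gap_open) + scoring$gap_extend  # Biostrings opening cost
  ge <- -(scoring$gap_extend)
  out <- reads %>%
    mutate(strand = if_else(.data$direction == "reverse", "-", "+"),
           bases = if_else(.data$direction == "reverse",
                           revcomp(.data$bases), .data$bases),
           quals = if_else(.data$direction == "reverse",
                           vapply(.data$quals,
                                  function(s) paste(rev(seq_chars(s)), collapse = ""),
                                  character(1), USE.NAMES = FALSE),
                           .data$quals)) %>%
    group_by(.data$amplicon_id) %>%
    dplyr::group_modify(function(df, key) {
      ref <- amp_row(panel, key$amplicon_id)$sequence
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(df$bases), Biostrings::DNAString(ref),
        type = "global-local", substitutionMatrix = mat,
        gapOpening = go, gapExtension = ge
      )
      ap <- as.character(Biostrings::pattern(pa))
      as_ <- as.character(Biostrings::subject(pa))
      cig <- mapply(alignment_cigar, ap, as_, USE.NAMES = FALSE)
      ncols <- nchar(ap)
      nmatch <- Biostrings::nmatch(pa)
      df %>% mutate(
        ref_start = Biostrings::start(Biostrings::subject(pa)),
        ref_end = Biostrings::end(Biostrings::subject(pa)),
        cigar = cig,
        identity = nmatch / ncols,
        score = Biostrings::score(pa),
        aligned_bases = vapply(cig, function(cg) {
          d <- decode_cigar(cg)
          sum(d$len[d$op %in% c("M", "X")])
        }, numeric(1), USE.NAMES = FALSE)
      )
    }) %>%
    ungroup() %>%
    mutate(nonspecific = .data$identity < min_identity)
  select(out, "read_id", "sample_id", "amplicon_id", "direction", "strand",
         "ref_start", "ref_end", "cigar", "identity", "score",
         "aligned_bases", "nonspecific", "bases", "quals")
}

empty_alignment_tbl <- function() {
  tibble(read_id = character(), sample_id = character(),
         amplicon_id = character(), direction = character(),
         strand = character(), ref_start = integer(), ref_end = integer(),
         cigar = character(), identity = numeric(), score = numeric(),
         aligned_bases = numeric(), nonspecific = logical(),
         bases = character(), quals = character())
}

# gapped pattern/subject strings -> run-length op string (M match, X
# mismatch, I insertion in the read, D deletion from the read)
alignment_cigar <- function(pat, subj) {
  cp <- seq_chars(pat)
  cs <- seq_chars(subj)
  op <- ifelse(cp == "-", "D", ifelse(cs == "-", "I",
               ifelse(cp == cs, "M", "X")))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

decode_cigar <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MXID]", cigar))[[1]]
  list(len = len, op = op)
}

#' Average base coverage per amplicon
#'
#' Total aligned read bases divided by the reference length, the standard
#' average-base-coverage figure for amplicon mappings. Non-specific reads are
#' excluded.
#'
#' @param alignments tibble from [align_reads()].
#' @param panel an `amp_panel`.
#' @return tibble: `amplicon_id`, `sample_id` (if present), `n_reads`,
#'   `aligned_bases`, `mean_coverage` (0 for amplicons with no reads).
#' @export
coverage_stats <- function(alignments, panel) {
  grp <- intersect(c("amplicon_id", "sample_id"), names(alignments))
  al <- filter(alignments, !.data$nonspecific)
  lens <- select(panel$amplicons, "amplicon_id", "length")
  if (nrow(al) == 0) {
    return(mutate(lens, sample_id = NA_character_, n_reads = 0L,
                  aligned_bases = 0, mean_coverage = 0) %>%
             select(-"length"))
  }
  al %>%
    group_by(across(dplyr::all_of(grp))) %>%
    summarise(n_reads = n(), aligned_bases = sum(.data$aligned_bases),
              .groups = "drop") %>%
    left_join(lens, by = "amplicon_id") %>%
    mutate(mean_coverage = .data$aligned_bases / .data$length) %>%
    select(-"length")
}
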