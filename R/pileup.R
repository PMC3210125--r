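# Quality-aware pileup construction: per reference column, allele counts
# restricted to observations passing the base-quality and
# neighborhood-quality gates, alongside unrestricted raw counts.

#' Build quality-aware pileups
#'
#' An observation contributes to the quality-passing allele counts only if
#' its base quality is at least `qual_min` AND the mean quality of the
#' surrounding bases (a +/- `neighborhood_radius` window in read coordinates)
#' is at least `neighborhood_min`. Insertions are excluded from columns;
#' deletions are counted separately per column. Non-specific alignments are
#' ignored.
#'
#' @param alignments tibble from [align_reads()].
#' @param panel an `amp_panel`.
#' @param qual_min minimum phred quality of the observed base (default 20).
#' @param neighborhood_min minimum mean phred quality of the window
#'   (default 15).
#' @param neighborhood_radius window half-width in bases (default 5, i.e. an
#'   11-base window).
#' @return tibble with one row per covered column: `amplicon_id`,
#'   `sample_id` (if present), `pos`, `ref`, `depth` (raw), `qc_depth`,
#'   quality-passing counts `A`,`C`,`G`,`T`, raw counts `raw_A`..`raw_T`,
#'   and `del` (deleted-read count).
#' @export
build_pileup <- function(alignments, panel, qual_min = 20,
                         neighborhood_min = 15, neighborhood_radius = 5) {
  stopifnot(qual_min >= 0, neighborhood_min >= 0, neighborhood_radius >= 0)
  al <- filter(alignments, !.data$nonspecific)
  if (nrow(al) == 0) return(empty_pileup_tbl())
  grp <- intersect(c("amplicon_id", "sample_id"), names(al))
  obs <- lapply(seq_len(nrow(al)), function(i) {
    o <- expand_alignment(al$ref_start[i], al$cigar[i], al$bases[i],
                          al$quals[i], neighborhood_radius)
    if (nrow(o) == 0) return(o)
    o$amplicon_id <- al$amplicon_id[i]
    if ("sample_id" %in% grp) o$sample_id <- al$sample_id[i]
    o
  })
  obs <- bind_rows(obs)
  if (nrow(obs) == 0) return(empty_pileup_tbl())
  obs <- mutate(obs, qc = !.data$is_del & .data$qual >= qual_min &
                  .data$win >= neighborhood_min)
  pile <- obs %>%
    group_by(across(dplyr::all_of(c(grp, "pos")))) %>%
    summarise(
      depth = sum(!.data$is_del),
      qc_depth = sum(.data$qc),
      A = sum(.data$qc & .data$base == "A"),
      C = sum(.data$qc & .data$base == "C"),
      G = sum(.data$qc & .data$base == "G"),
      T = sum(.data$qc & .data$base == "T"),
      raw_A = sum(!.data$is_del & .data$base == "A"),
      raw_C = sum(!.data$is_del & .data$base == "C"),
      raw_G = sum(!.data$is_del & .data$base == "G"),
      raw_T = sum(!.data$is_del & .data$base == "T"),
      del = sum(.data$is_del),
      .groups = "drop"
    )
  refs <- setNames(panel$amplicons$sequence, panel$amplicons$amplicon_id)
  pile %>%
    mutate(ref = substring(refs[.data$amplicon_id], .data$pos, .data$pos)) %>%
    select(dplyr::all_of(grp), "pos", "ref", "depth", "qc_depth",
           "A", "C", "G", "T", dplyr::starts_with("raw_"), "del") %>%
    arrange(across(dplyr::all_of(c(grp, "pos"))))
}

empty_pileup_tbl <- function() {
  tibble(amplicon_id = character(), sample_id = character(), pos = integer(),
         ref = character(), depth = integer(), qc_depth = integer(),
         A = integer(), C = integer(), G = integer(), T = integer(),
         raw_A = integer(), raw_C = integer(), raw_G = integer(),
         raw_T = integer(), del = integer())
}

# one alignment -> per-column observations (ref pos, read base, base quality,
# window mean quality) plus deletion rows
expand_alignment <- function(ref_start, cigar, bases, quals, radius) {
  d <- decode_cigar(cigar)
  q <- ascii_to_phred(quals)
  win <- window_mean_qual(q, radius)
  ch <- seq_chars(bases)
  ref_off <- 0L
  read_off <- 0L
  parts <- vector("list", length(d$op))
  for (k in seq_along(d$op)) {
    L <- d$len[k]
    op <- d$op[k]
    if (op %in% c("M", "X")) {
      idx <- read_off + seq_len(L)
      parts[[k]] <- tibble(pos = ref_start + ref_off + seq_len(L) - 1L,
                           base = ch[idx], qual = q[idx], win = win[idx],
                           is_del = FALSE)
      ref_off <- ref_off + L
      read_off <- read_off + L
    } else if (op == "I") {
      read_off <- read_off + L
    } else { # D
      parts[[k]] <- tibble(pos = ref_start + ref_off + seq_len(L) - 1L,
                           base = "-", qual = NA_integer_, win = NA_real_,
                           is_del = TRUE)
      ref_off <- ref_off + L
    }
  }
  bind_rows(parts)
}
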