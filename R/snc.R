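# Genuine SNC calling, codon-aware merging and synonymous/non-synonymous
# classification, per-AMP summaries (SNC counts, per-codon frequency, omega)
# and position maps.

#' Call genuine single-nucleotide changes from a pileup
#'
#' A column qualifies when its quality-passing depth reaches `min_depth`
#' (default 30x); every non-reference base whose quality-passing frequency
#' reaches `min_freq` (default 3%) becomes one SNC. Deletions and insertions
#' never produce SNCs. Multi-allelic columns produce one SNC per alternate
#' allele. With `max_freq` set, changes at or above that frequency are
#' flagged for review (`fixed_flag`) as possible reference errors — fixed
#' differences present in essentially all reads — rather than dropped.
#'
#' @param pileup tibble from [build_pileup()].
#' @param panel an `amp_panel`.
#' @param min_depth minimum quality-passing coverage (default 30).
#' @param min_freq minimum alternate-allele frequency (default 0.03).
#' @param max_freq optional review threshold for near-fixed changes
#'   (default `NULL`, off).
#' @return tibble: `amp_id`, `amplicon_id`, `sample_id` (if present), `pos`
#'   (amplicon-local), `tx_pos` (transcript), `ref`, `alt`, `alt_count`,
#'   `depth` (quality-passing), `frequency`, `codon_index`, `region`,
#'   `in_cds`, `fixed_flag`.
#' @export
call_sncs <- function(pileup, panel, min_depth = 30, min_freq = 0.03,
                      max_freq = NULL) {
  if (nrow(pileup) == 0) return(empty_snc_tbl())
  grp <- intersect("sample_id", names(pileup))
  long <- pileup %>%
    filter(.data$qc_depth >= min_depth) %>%
    tidyr::pivot_longer(cols = c("A", "C", "G", "T"), names_to = "alt",
                        values_to = "alt_count") %>%
    filter(.data$alt != .data$ref, .data$alt_count > 0) %>%
    mutate(frequency = .data$alt_count / .data$qc_depth) %>%
    filter(.data$frequency >= min_freq)
  if (nrow(long) == 0) return(empty_snc_tbl())
  ann <- long %>%
    group_by(.data$amplicon_id) %>%
    dplyr::group_modify(function(df, key) {
      a <- amp_row(panel, key$amplicon_id)
      sp <- cds_span(a)
      df %>% mutate(
        amp_id = a$amp_id,
        tx_pos = tx_pos(a, .data$pos),
        in_cds = .data$pos >= sp[["start"]] & .data$pos <= sp[["end"]],
        codon_index = if_else(.data$in_cds,
                              tx_codon(a, tx_pos(a, .data$pos)), NA_integer_),
        region = locate_region(panel, key$amplicon_id, .data$pos)
      )
    }) %>%
    ungroup() %>%
    mutate(fixed_flag = if (is.null(max_freq)) FALSE
           else .data$frequency >= max_freq)
  select(ann, "amp_id", "amplicon_id", dplyr::all_of(grp), "pos", "tx_pos",
         "ref", "alt", "alt_count", depth = "qc_depth", "frequency",
         "codon_index", "region", "in_cds", "fixed_flag") %>%
    arrange(.data$amp_id, .data$tx_pos, .data$alt)
}

empty_snc_tbl <- function() {
  tibble(amp_id = character(), amplicon_id = character(),
         sample_id = character(), pos = integer(), tx_pos = integer(),
         ref = character(), alt = character(), alt_count = integer(),
         depth = integer(), frequency = numeric(), codon_index = integer(),
         region = character(), in_cds = logical(), fixed_flag = logical())
}

#' Merge same-codon SNCs and classify synonymous/non-synonymous
#'
#' SNCs inside the covered cds are first deduplicated across overlapping
#' amplicons of the same AMP (union on the shared transcript frame), then
#' grouped by precursor codon. The alternate codon applies all grouped
#' alternates simultaneously and the amino-acid change is deduced by virtual
#' translation; a change is synonymous iff the amino acid is unchanged. At a
#' multi-allelic position each alternate yields its own merged change
#' (combined with the single alternates at the codon's other positions).
#' SNCs outside the cds are not merged and are excluded from cds statistics.
#'
#' @param sncs tibble from [call_sncs()].
#' @param panel an `amp_panel`.
#' @return tibble: `amp_id`, `sample_id` (if present), `codon_index`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `synonymous`, `region`,
#'   `n_components`, `component_pos` (comma-joined transcript positions),
#'   `component_alt`.
#' @export
merge_and_classify <- function(sncs, panel) {
  grp <- intersect("sample_id", names(sncs))
  cds <- filter(sncs, .data$in_cds)
  if (nrow(cds) == 0) return(empty_change_tbl())
  # union across overlapping amplicons of one AMP
  cds <- cds %>%
    group_by(across(dplyr::all_of(c("amp_id", grp, "tx_pos", "alt")))) %>%
    arrange(dplyr::desc(.data$depth)) %>%
    slice(1) %>%
    ungroup()
  cds %>%
    group_by(across(dplyr::all_of(c("amp_id", grp, "codon_index")))) %>%
    dplyr::group_modify(function(df, key) merge_codon(df, key, panel)) %>%
    ungroup() %>%
    arrange(across(dplyr::all_of(c("amp_id", grp, "codon_index"))))
}

merge_codon <- function(df, key, panel) {
  a <- amp_row(panel, df$amplicon_id[1])
  codon_tx <- a$cds_tx_start + (key$codon_index - 1L) * 3L + 0:2
  codon_local <- codon_tx - a$tx_start + 1L
  ref_codon <- paste(substring(a$sequence, codon_local, codon_local),
                     collapse = "")
  offsets <- df$tx_pos - codon_tx[1] + 1L
  if (length(unique(offsets)) > 3)
    abort("internal error: more than 3 positions claim one codon")
  # one alt per position; multi-allelic positions fan out combinatorially
  alt_by_off <- split(df$alt, offsets)
  combos <- do.call(tidyr::expand_grid,
                    setNames(alt_by_off, paste0("o", names(alt_by_off))))
  offs <- as.integer(names(alt_by_off))
  out <- lapply(seq_len(nrow(combos)), function(r) {
    alt_codon <- ref_codon
    alts <- vapply(seq_along(offs), function(j) combos[[j]][r], character(1))
    for (j in seq_along(offs)) {
      substr(alt_codon, offs[j], offs[j]) <- alts[j]
    }
    ref_aa <- translate_cds(ref_codon)
    alt_aa <- translate_cds(alt_codon)
    tibble(ref_codon = ref_codon, alt_codon = alt_codon,
           ref_aa = ref_aa, alt_aa = alt_aa,
           synonymous = ref_aa == alt_aa,
           region = df$region[1],
           n_components = length(offs),
           component_pos = paste(codon_tx[1] + offs - 1L, collapse = ","),
           component_alt = paste(alts, collapse = ","))
  })
  bind_rows(out)
}

empty_change_tbl <- function() {
  tibble(amp_id = character(), sample_id = character(),
         codon_index = integer(), ref_codon = character(),
         alt_codon = character(), ref_aa = character(), alt_aa = character(),
         synonymous = logical(), region = character(),
         n_components = integer(), component_pos = character(),
         component_alt = character())
}

#' Per-AMP, per-sample variant-call summary
#'
#' The headline row of the analysis: total SNCs over the whole precursor
#' transcript (union across overlapping amplicons), merged cds changes,
#' non-synonymous and synonymous counts, the raw omega ratio
#' (non-synonymous / synonymous; undefined and reported bracketed when there
#' are no synonymous changes), and the SNC frequency — merged cds changes per
#' covered codon, with the per-nucleotide variant alongside. `omega_label`
#' and `frequency_2dp` carry the reporting-precision forms (1 and 2 decimals,
#' half-up).
#'
#' @param changes tibble from [merge_and_classify()].
#' @param sncs tibble from [call_sncs()].
#' @param panel an `amp_panel`.
#' @return tibble with one row per AMP x sample.
#' @export
summarize_variants <- function(changes, sncs, panel) {
  grp <- intersect("sample_id", names(sncs))
  cov <- covered_codons_by_amp(panel)
  tot <- sncs %>%
    group_by(across(dplyr::all_of(c("amp_id", grp)))) %>%
    summarise(snc_total = dplyr::n_distinct(paste(.data$tx_pos, .data$alt)),
              snc_total_by_amplicon = n(), .groups = "drop")
  ch <- changes %>%
    group_by(across(dplyr::all_of(c("amp_id", grp)))) %>%
    summarise(snc_cds = n(), ns_count = sum(!.data$synonymous),
              syn_count = sum(.data$synonymous), .groups = "drop")
  out <- tot %>%
    left_join(ch, by = c("amp_id", grp)) %>%
    mutate(across(c("snc_cds", "ns_count", "syn_count"),
                  ~ dplyr::coalesce(.x, 0L))) %>%
    left_join(cov, by = "amp_id") %>%
    mutate(
      omega = if_else(.data$syn_count > 0,
                      .data$ns_count / .data$syn_count, NA_real_),
      omega_undefined = .data$syn_count == 0 & .data$ns_count > 0,
      omega_label = format_omega(.data$ns_count, .data$syn_count),
      frequency = .data$snc_cds / .data$covered_codons,
      frequency_2dp = round_half_up(.data$snc_cds / .data$covered_codons, 2),
      frequency_per_nt = .data$snc_cds / (3 * .data$covered_codons)
    )
  stopifnot(all(out$ns_count + out$syn_count == out$snc_cds))
  out
}

# omega at reporting precision: 1 decimal, half-up; bracketed ns count when
# no synonymous changes exist; "0.0" when nothing is non-synonymous
format_omega <- function(ns, syn) {
  dplyr::case_when(
    syn > 0 ~ sprintf("%.1f", round_half_up(ns / syn, 1)),
    ns > 0 ~ sprintf("[%d]", ns),
    TRUE ~ "0.0"
  )
}

#' Position map of synonymous/non-synonymous changes
#'
#' One row per component substitution of each merged codon change, annotated
#' with region and classification — the tabular form of a variant map along
#' the precursor, ready for [plot_snc_map()].
#'
#' @param changes tibble from [merge_and_classify()].
#' @return tibble: `amp_id`, `sample_id` (if present), `tx_pos`,
#'   `codon_index`, `region`, `synonymous`, `alt`.
#' @export
snc_maps <- function(changes) {
  if (nrow(changes) == 0) {
    return(tibble(amp_id = character(), sample_id = character(),
                  tx_pos = integer(), codon_index = integer(),
                  region = character(), synonymous = logical(),
                  alt = character()))
  }
  grp <- intersect("sample_id", names(changes))
  changes %>%
    mutate(tx_pos = strsplit(.data$component_pos, ","),
           alt = strsplit(.data$component_alt, ",")) %>%
    tidyr::unnest(c("tx_pos", "alt")) %>%
    mutate(tx_pos = as.integer(.data$tx_pos)) %>%
    select("amp_id", dplyr::all_of(grp), "tx_pos", "codon_index", "region",
           "synonymous", "alt") %>%
    distinct() %>%
    arrange(.data$amp_id, .data$tx_pos)
}

#' Write SNCs as a minimal VCF 4.2 file (one contig per amplicon)
#'
#' @param sncs tibble from [call_sncs()].
#' @param panel an `amp_panel`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_snc_vcf <- function(sncs, panel, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", panel$amplicons$amplicon_id,
                  ",length=", panel$amplicons$length, ">"),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Quality-passing depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.4f;DP=%d",
                  sncs$amplicon_id, sncs$pos, sncs$ref, sncs$alt,
                  sncs$frequency, sncs$depth)
  writeLines(c(hdr, body), path)
  invisible(path)
}
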