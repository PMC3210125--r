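# Bundled reference dataset: the per-AMP, per-sample variant summary of a
# pyrosequencing survey of nine AMP transcripts in Mediterranean/Atlantic
# mussel hemolymph pools.

#' Published AMP variant-survey summary
#'
#' Per-AMP, per-sample results of an amplicon pyrosequencing survey of nine
#' mussel AMP precursor transcripts in six hemolymph pools (four of 100
#' mussels — Pa, Vi, Ve, Ve nc — and two Vibrio-injected pools of 40 — Ve
#' ft, Ve nt): total SNCs over the precursor, merged cds SNCs, the reported
#' per-codon SNC frequency, non-synonymous counts and the omega label
#' (bracketed when no synonymous changes exist). `covered_codons` is the
#' covered-cds codon denominator consistent with every reported
#' frequency/count pair. Useful as a worked-example input for the summary
#' and grouping statistics.
#'
#' @return tibble with columns `amp_id`, `sample_id`, `n_mussels`,
#'   `snc_total`, `snc_cds`, `frequency`, `ns_snc`, `omega`,
#'   `covered_codons`.
#' @export
#' @examples
#' s <- amp_survey_summary()
#' mean_sd_by_amp(s)
amp_survey_summary <- function() {
  p <- system.file("extdata", "amp_survey_summary.tsv",
                   package = "ampdiversity")
  readr::read_tsv(p, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    amp_id = "c", sample_id = "c", omega = "c",
                    .default = readr::col_number()
                  ))
}
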