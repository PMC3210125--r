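# End-to-end orchestration: simulate (or load) reads, demultiplex, trim,
# filter, map, pileup, call, merge, summarize, cluster, translate, and
# compute cross-sample statistics, with a run manifest of counts at every
# gate.

#' Pipeline configuration
#'
#' Collects the thresholds of the analysis (all with their standard
#' defaults: 30x minimum SNC coverage, 3% minimum frequency, base quality
#' >= 20 with >= 15 mean neighborhood quality over an 11-base window, Mott
#' trim limit 0.05, 100 bp minimum length, 3x minimum cluster coverage) plus
#' either simulator settings or FASTQ inputs. The resolved configuration is
#' embedded in every report for provenance.
#'
#' @param panel an `amp_panel` (default [demo_panel()]).
#' @param samples sample ids to process (default: all in the panel).
#' @param amplicon_ids amplicons to process (default: all).
#' @param n_reads reads to simulate per sample x amplicon.
#' @param n_variant_sites,freqs,linkage haplotype-pool settings passed to
#'   [build_haplotype_pool()].
#' @param model an `error_model_454`.
#' @param fastq optional named character vector of FASTQ paths; when given,
#'   simulation is skipped and these reads are analysed instead.
#' @param min_depth,min_freq,qual_min,neighborhood_min,neighborhood_radius,
#'   trim_limit,min_len,min_cov,min_identity,max_mismatch analysis
#'   thresholds (see the stage functions).
#' @param seed integer master seed for all randomness.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(panel = demo_panel(), samples = NULL,
                            amplicon_ids = NULL, n_reads = 400,
                            n_variant_sites = 3, freqs = c(0.2, 0.1, 0.06),
                            linkage = "haplotypic",
                            model = error_model_454(), fastq = NULL,
                            min_depth = 30, min_freq = 0.03, qual_min = 20,
                            neighborhood_min = 15, neighborhood_radius = 5,
                            trim_limit = 0.05, min_len = 100, min_cov = 3,
                            min_identity = 0.8, max_mismatch = 0, seed = 1) {
  stopifnot(min_depth >= 1, min_freq > 0, min_freq <= 1, qual_min >= 0,
            neighborhood_min >= 0, trim_limit > 0, trim_limit < 1,
            min_len >= 0, min_cov >= 1)
  structure(list(panel = panel,
                 samples = samples %||% unique(panel$barcodes$sample_id),
                 amplicon_ids = amplicon_ids %||% panel$amplicons$amplicon_id,
                 n_reads = n_reads, n_variant_sites = n_variant_sites,
                 freqs = freqs, linkage = linkage, model = model,
                 fastq = fastq, min_depth = min_depth, min_freq = min_freq,
                 qual_min = qual_min, neighborhood_min = neighborhood_min,
                 neighborhood_radius = neighborhood_radius,
                 trim_limit = trim_limit, min_len = min_len,
                 min_cov = min_cov, min_identity = min_identity,
                 max_mismatch = max_mismatch, seed = seed),
            class = "pipeline_config")
}

#' Run the full amplicon-diversity pipeline
#'
#' Executes simulate (unless FASTQ inputs are given) -> demultiplex -> trim
#' -> length-filter -> map -> pileup -> call SNCs -> merge codons ->
#' summarize -> cluster reads -> enumerate peptides -> common/exclusive SNCs
#' -> ANOVA/Tukey grouping, and assembles a manifest with read counts at
#' every gate. Any stage failure aborts with the stage name. Fully
#' deterministic for a fixed seed.
#'
#' @param config a `pipeline_config`.
#' @return an `amp_pipeline_result` list: `config`, `truth` (NULL for FASTQ
#'   input), `reads` counts manifest, `coverage`, `pileup`, `sncs`,
#'   `changes`, `summary`, `clusters`, `peptides`, `peptide_table`,
#'   `snc_map`, `common_exclusive`, `grouping`, `manifest`.
#' @export
run_amp_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  panel <- config$panel
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  truth <- NULL
  if (is.null(config$fastq)) {
    sim <- stage("simulate", simulate_study(config))
    reads <- sim$reads
    truth <- sim$truth
  } else {
    reads <- stage("load", bind_rows(lapply(config$fastq, read_fastq)))
  }
  n_input <- nrow(reads)

  dm <- stage("demultiplex",
              demultiplex(reads, panel, max_mismatch = config$max_mismatch))
  tr <- stage("trim", mott_trim(dm$assigned, error_limit = config$trim_limit))
  lf <- stage("length_filter", length_filter(tr, min_len = config$min_len))
  al <- stage("map", align_reads(lf$kept, panel,
                                 min_identity = config$min_identity))
  cov <- stage("coverage", coverage_stats(al, panel))
  pile <- stage("pileup",
                build_pileup(al, panel, qual_min = config$qual_min,
                             neighborhood_min = config$neighborhood_min,
                             neighborhood_radius = config$neighborhood_radius))
  sncs <- stage("call", call_sncs(pile, panel, min_depth = config$min_depth,
                                  min_freq = config$min_freq))
  changes <- stage("merge", merge_and_classify(sncs, panel))
  summ <- stage("summarize", summarize_variants(changes, sncs, panel))
  clusters <- stage("cluster", cluster_reads(lf$kept, panel))
  peptides <- stage("peptides",
                    enumerate_peptides(clusters, panel,
                                       min_cov = config$min_cov))
  ptab <- stage("peptide_table", peptide_variant_table(clusters, peptides))
  map <- stage("snc_map", snc_maps(changes))
  ce <- if (dplyr::n_distinct(sncs$sample_id) >= 2) {
    stage("common_exclusive", common_exclusive(sncs))
  } else NULL
  grouping <- if (nrow(summ) > 0 &&
                  dplyr::n_distinct(summ$amp_id) >= 2 &&
                  all(count(summ, .data$amp_id)$n >= 2)) {
    stage("grouping", anova_tukey(
      select(summ, "amp_id", "sample_id", "frequency")))
  } else NULL

  manifest <- tibble(
    n_input = n_input,
    n_assigned = nrow(dm$assigned), n_unassigned = nrow(dm$unassigned),
    n_kept = nrow(lf$kept), n_discarded = nrow(lf$discarded),
    n_aligned = sum(!al$nonspecific), n_nonspecific = sum(al$nonspecific),
    n_sncs = nrow(sncs), n_merged_changes = nrow(changes),
    n_clusters = nrow(clusters), n_peptides = nrow(peptides)
  )
  stopifnot(manifest$n_assigned + manifest$n_unassigned == manifest$n_input,
            manifest$n_kept + manifest$n_discarded == manifest$n_assigned)

  structure(list(config = config, truth = truth, manifest = manifest,
                 coverage = cov, pileup = pile, sncs = sncs,
                 changes = changes, summary = summ, clusters = clusters,
                 peptides = peptides, peptide_table = ptab, snc_map = map,
                 common_exclusive = ce, grouping = grouping),
            class = "amp_pipeline_result")
}

# simulate every requested sample x amplicon with sub-seeds drawn from the
# master seed
simulate_study <- function(config) {
  combos <- tidyr::expand_grid(sample_id = config$samples,
                               amplicon_id = config$amplicon_ids)
  sub <- withr_seed(config$seed, sample.int(.Machine$integer.max - 1,
                                            2 * nrow(combos)))
  reads <- vector("list", nrow(combos))
  truths <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pool <- build_haplotype_pool(config$panel, combos$amplicon_id[i],
                                 sample_id = combos$sample_id[i],
                                 n_variant_sites = config$n_variant_sites,
                                 freqs = config$freqs,
                                 linkage = config$linkage,
                                 seed = sub[2 * i - 1])
    sim <- simulate_reads(pool, config$panel, n_reads = config$n_reads,
                          model = config$model, seed = sub[2 * i])
    reads[[i]] <- sim$reads
    a <- amp_row(config$panel, combos$amplicon_id[i])
    truths[[i]] <- pool$true_sncs %>%
      mutate(sample_id = combos$sample_id[i],
             amplicon_id = combos$amplicon_id[i],
             amp_id = a$amp_id, tx_pos = tx_pos(a, .data$position))
  }
  list(reads = bind_rows(reads), truth = bind_rows(truths))
}

#' Per-AMP cluster and peptide-variant table
#'
#' For each AMP and sample: total read clusters, the percentage of clusters
#' differing by at least one change from the reference (cluster fraction,
#' not read fraction), and the number of non-redundant peptides.
#'
#' @param clusters tibble from [cluster_reads()].
#' @param peptides tibble from [enumerate_peptides()].
#' @return tibble: `amp_id`, `sample_id`, `total_clusters`,
#'   `pct_variant_clusters`, `non_redundant_peptides`.
#' @export
peptide_variant_table <- function(clusters, peptides) {
  if (nrow(clusters) == 0) {
    return(tibble(amp_id = character(), sample_id = character(),
                  total_clusters = integer(), pct_variant_clusters = numeric(),
                  non_redundant_peptides = integer()))
  }
  cl <- clusters %>%
    group_by(.data$amp_id, .data$sample_id) %>%
    summarise(total_clusters = n(),
              pct_variant_clusters = 100 * mean(.data$kind == "variant"),
              .groups = "drop")
  pp <- peptides %>%
    count(.data$amp_id, .data$sample_id, name = "non_redundant_peptides")
  cl %>%
    left_join(pp, by = c("amp_id", "sample_id")) %>%
    mutate(non_redundant_peptides =
             dplyr::coalesce(.data$non_redundant_peptides, 0L))
}

#' @export
print.amp_pipeline_result <- function(x, ...) {
  cat("<amp_pipeline_result>\n")
  print(x$manifest)
  cat("SNC summary:\n")
  print(x$summary, ...)
  invisible(x)
}

#' Write the pipeline report bundle to a directory
#'
#' Emits the summary, SNC, map, cluster/peptide, common-exclusive and
#' grouping tables as TSV plus a JSON manifest embedding the resolved
#' thresholds. Output is byte-identical for identical results.
#'
#' @param result an `amp_pipeline_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wt <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_tsv(df, p)
    paths <<- c(paths, p)
  }
  wt(result$summary, "summary.tsv")
  wt(result$sncs, "sncs.tsv")
  wt(result$snc_map, "snc_map.tsv")
  wt(result$peptide_table, "peptide_variants.tsv")
  wt(result$coverage, "coverage.tsv")
  if (!is.null(result$common_exclusive)) {
    wt(result$common_exclusive$by_sample, "common_exclusive.tsv")
  }
  if (!is.null(result$grouping)) wt(tidy(result$grouping), "grouping.tsv")
  cfg <- result$config
  manifest <- list(
    counts = as.list(result$manifest),
    thresholds = cfg[c("min_depth", "min_freq", "qual_min",
                       "neighborhood_min", "neighborhood_radius",
                       "trim_limit", "min_len", "min_cov", "min_identity",
                       "max_mismatch")],
    seed = cfg$seed,
    samples = cfg$samples, amplicons = cfg$amplicon_ids
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, mp)
  invisible(paths)
}
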