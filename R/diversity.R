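# Read clustering, peptide-variant enumeration, common/exclusive SNC
# partitioning and AMP variability grouping (one-way ANOVA + Tukey HSD).

#' Cluster identical reads per AMP and sample
#'
#' Exact clustering: reads with the same length and 100% identity form one
#' cluster (reverse reads are sense-oriented first). A cluster is
#' `reference_identical` when its sequence matches the reference transcript
#' exactly over its span, otherwise `variant`.
#'
#' @param reads kept read tibble (`bases`, `sample_id`, `amplicon_id`,
#'   `direction`) after demultiplexing, trimming and length filtering.
#' @param panel an `amp_panel`.
#' @return tibble: `amp_id`, `sample_id`, `amplicon_id` (of the first
#'   member), `representative`, `size`, `kind`; cluster sizes sum to the
#'   read count.
#' @export
cluster_reads <- function(reads, panel) {
  if (nrow(reads) == 0) {
    return(tibble(amp_id = character(), sample_id = character(),
                  amplicon_id = character(), representative = character(),
                  size = integer(), kind = character()))
  }
  amp_of <- setNames(panel$amplicons$amp_id, panel$amplicons$amplicon_id)
  refs_by_amp <- split(panel$amplicons$sequence, panel$amplicons$amp_id)
  oriented <- reads %>%
    mutate(sense = if_else(.data$direction == "reverse",
                           revcomp(.data$bases), .data$bases),
           amp_id = unname(amp_of[.data$amplicon_id]))
  cl <- oriented %>%
    group_by(.data$amp_id, .data$sample_id, .data$sense) %>%
    summarise(size = n(), amplicon_id = first(.data$amplicon_id),
              .groups = "drop") %>%
    rename(representative = "sense")
  cl %>%
    mutate(kind = if_else(
      vapply(seq_len(n()), function(i) {
        any(vapply(refs_by_amp[[cl$amp_id[i]]],
                   function(r) grepl(cl$representative[i], r, fixed = TRUE),
                   logical(1)))
      }, logical(1)),
      "reference_identical", "variant")) %>%
    select("amp_id", "sample_id", "amplicon_id", "representative", "size",
           "kind") %>%
    arrange(.data$amp_id, .data$sample_id, dplyr::desc(.data$size))
}

#' Enumerate non-redundant peptide variants
#'
#' Clusters covered at least `min_cov` times are virtually translated over
#' the covered cds (first to last complete codon inside the cluster's
#' alignment span); peptides identical after translation are merged, removing
#' redundancy due to silent substitutions. The count of distinct peptides per
#' AMP and sample is the peptide-variant statistic. A cluster not spanning
#' the AMP's whole covered cds is flagged `partial`;
#' `cysteine_array_retained` is TRUE when every covered cysteine-array
#' position still encodes cysteine.
#'
#' @param clusters tibble from [cluster_reads()].
#' @param panel an `amp_panel`.
#' @param min_cov minimum cluster size translated (default 3).
#' @return tibble: `amp_id`, `sample_id`, `peptide`, `supporting_clusters`,
#'   `total_support`, `partial`, `cysteine_array_retained`, `aa_start`,
#'   `aa_end`.
#' @export
enumerate_peptides <- function(clusters, panel, min_cov = 3) {
  cl <- filter(clusters, .data$size >= min_cov, nchar(.data$representative) > 0)
  if (nrow(cl) == 0) {
    return(tibble(amp_id = character(), sample_id = character(),
                  peptide = character(), supporting_clusters = integer(),
                  total_support = integer(), partial = logical(),
                  cysteine_array_retained = logical(),
                  aa_start = integer(), aa_end = integer()))
  }
  pseudo <- tibble(read_id = paste0("cl", seq_len(nrow(cl))),
                   bases = cl$representative,
                   quals = vapply(nchar(cl$representative),
                                  function(n) phred_to_ascii(rep(40, n)),
                                  character(1)),
                   sample_id = cl$sample_id, amplicon_id = cl$amplicon_id,
                   direction = "forward")
  al <- align_reads(pseudo, panel)
  al <- al[match(paste0("cl", seq_len(nrow(cl))), al$read_id), ]
  cov_amp <- covered_codons_by_amp(panel)
  pep <- lapply(seq_len(nrow(cl)), function(i) {
    a <- amp_row(panel, cl$amplicon_id[i])
    tr <- translate_cluster(al[i, ], a)
    if (is.null(tr)) return(NULL)
    cys <- a$cys_positions[[1]]
    covered_cys <- cys[cys >= tr$aa_start & cys <= tr$aa_end]
    cys_ok <- all(substring(tr$peptide, covered_cys - tr$aa_start + 1,
                            covered_cys - tr$aa_start + 1) == "C")
    full <- cov_amp$covered_codons[cov_amp$amp_id == a$amp_id]
    tibble(amp_id = cl$amp_id[i], sample_id = cl$sample_id[i],
           peptide = tr$peptide, size = cl$size[i],
           partial = (tr$aa_end - tr$aa_start + 1) < full,
           cysteine_array_retained = cys_ok,
           aa_start = tr$aa_start, aa_end = tr$aa_end)
  })
  bind_rows(pep) %>%
    group_by(.data$amp_id, .data$sample_id, .data$peptide) %>%
    summarise(supporting_clusters = n(), total_support = sum(.data$size),
              partial = all(.data$partial),
              cysteine_array_retained = all(.data$cysteine_array_retained),
              aa_start = min(.data$aa_start), aa_end = max(.data$aa_end),
              .groups = "drop") %>%
    arrange(.data$amp_id, .data$sample_id, dplyr::desc(.data$total_support))
}

# translate one aligned cluster representative over its covered complete
# codons; returns NULL when no complete codon is covered
translate_cluster <- function(alrow, a) {
  if (is.na(alrow$read_id) || alrow$nonspecific) return(NULL)
  sp <- cds_span(a)
  s <- max(alrow$ref_start, sp[["start"]])
  e <- min(alrow$ref_end, sp[["end"]])
  if (e < s + 2) return(NULL)
  # advance s to a codon boundary, retreat e to a codon end
  phase <- (tx_pos(a, s) - a$cds_tx_start) %% 3
  s <- s + (3 - phase) %% 3
  e <- e - (tx_pos(a, e) - a$cds_tx_start + 1) %% 3
  if (e < s + 2) return(NULL)
  seg <- read_segment(alrow, s, e)
  if (nchar(seg) < 3) return(NULL)
  list(peptide = translate_cds(seg),
       aa_start = tx_codon(a, tx_pos(a, s)),
       aa_end = tx_codon(a, tx_pos(a, e)))
}

# read bases aligned within reference window [p0, p1] (insertions inside the
# window included, deletions skipped)
read_segment <- function(alrow, p0, p1) {
  d <- decode_cigar(alrow$cigar)
  ch <- seq_chars(alrow$bases)
  ref <- alrow$ref_start
  ri <- 1L
  out <- character(0)
  for (k in seq_along(d$op)) {
    L <- d$len[k]; op <- d$op[k]
    if (op %in% c("M", "X")) {
      pos <- ref + seq_len(L) - 1L
      sel <- pos >= p0 & pos <= p1
      out <- c(out, ch[ri + which(sel) - 1L])
      ref <- ref + L; ri <- ri + L
    } else if (op == "I") {
      if (ref > p0 && ref <= p1 + 1L) out <- c(out, ch[ri + seq_len(L) - 1L])
      ri <- ri + L
    } else {
      ref <- ref + L
    }
  }
  paste(out, collapse = "")
}

#' Partition SNCs into common and exclusive sets across samples
#'
#' For any collection of samples: the changes present in every sample
#' (common), the changes private to one sample (exclusive), and the
#' remainder shared by some but not all. Percentages give each sample's
#' fraction of common changes.
#'
#' @param snc_keys tibble with `sample_id` and key columns `amp_id`,
#'   `tx_pos`, `alt` (e.g. a filtered [call_sncs()] result).
#' @return list with `counts` (n_union, n_common, n_shared_not_universal,
#'   n_exclusive_total) and `by_sample` (tibble: sample_id, n, n_common,
#'   pct_common, n_exclusive).
#' @export
common_exclusive <- function(snc_keys) {
  if (nrow(snc_keys) == 0 || !"sample_id" %in% names(snc_keys))
    abort("empty SNC collection")
  keys <- snc_keys %>%
    mutate(key = paste(.data$amp_id, .data$tx_pos, .data$alt, sep = ":")) %>%
    distinct(.data$sample_id, .data$key)
  samples <- unique(keys$sample_id)
  n_samples <- length(samples)
  occ <- keys %>% count(.data$key, name = "n_samples_with")
  common <- occ$key[occ$n_samples_with == n_samples]
  exclusive <- occ$key[occ$n_samples_with == 1]
  by_sample <- keys %>%
    group_by(.data$sample_id) %>%
    summarise(n = n(),
              n_common = sum(.data$key %in% common),
              n_exclusive = sum(.data$key %in% exclusive),
              .groups = "drop") %>%
    mutate(pct_common = 100 * .data$n_common / .data$n)
  counts <- tibble(
    n_union = nrow(occ), n_common = length(common),
    n_exclusive_total = length(exclusive),
    n_shared_not_universal = nrow(occ) - length(common) - length(exclusive)
  )
  list(counts = counts, by_sample = by_sample)
}

#' Group AMPs by variability: one-way ANOVA + Tukey HSD
#'
#' Tests the null hypothesis that all AMPs share the same SNC frequency,
#' with the per-sample frequencies as replicates. If the null is rejected at
#' `alpha_anova`, all-pairs Tukey HSD comparisons at `alpha_tukey` are
#' condensed into homogeneous subsets (compact letters): AMPs are ordered by
#' mean frequency and a subset grows while every within-subset pair is
#' non-significant. With zero residual variance the ANOVA is undefined and
#' reported as such.
#'
#' @param freq_table tibble with `amp_id`, `sample_id`, `frequency`
#'   (at least 2 AMPs with at least 2 samples each).
#' @param alpha_anova ANOVA rejection level (default 0.001).
#' @param alpha_tukey Tukey HSD level (default 0.05).
#' @return an object of class `amp_grouping`; see [tidy.amp_grouping()] and
#'   [glance.amp_grouping()].
#' @export
anova_tukey <- function(freq_table, alpha_anova = 0.001, alpha_tukey = 0.05) {
  stopifnot(all(c("amp_id", "sample_id", "frequency") %in% names(freq_table)))
  tab <- freq_table %>% mutate(amp_id = as.character(.data$amp_id))
  if (dplyr::n_distinct(tab$amp_id) < 2)
    abort("need at least 2 AMPs")
  if (any(count(tab, .data$amp_id)$n < 2))
    abort("need at least 2 samples per AMP")
  means <- tab %>%
    group_by(.data$amp_id) %>%
    summarise(mean = mean(.data$frequency), sd = sd(.data$frequency),
              n = n(), .groups = "drop") %>%
    arrange(dplyr::desc(.data$mean), .data$amp_id)
  fit <- aov(frequency ~ factor(amp_id), data = tab)
  ss <- summary(fit)[[1]]
  undefined <- ss["Residuals", "Mean Sq"] < .Machine$double.eps
  if (undefined && dplyr::n_distinct(tab$frequency) == 1) {
    # completely constant data: trivially fail to reject
    return(new_amp_grouping(NA_real_, NA_real_, alpha_anova, alpha_tukey,
                            rejected = FALSE, undefined = FALSE,
                            means = means, tukey = NULL,
                            groups = single_group(means)))
  }
  if (undefined) {
    return(new_amp_grouping(NA_real_, NA_real_, alpha_anova, alpha_tukey,
                            rejected = NA, undefined = TRUE, means = means,
                            tukey = NULL, groups = NULL))
  }
  f <- ss[1, "F value"]
  p <- ss[1, "Pr(>F)"]
  if (p >= alpha_anova) {
    return(new_amp_grouping(f, p, alpha_anova, alpha_tukey, rejected = FALSE,
                            undefined = FALSE, means = means, tukey = NULL,
                            groups = single_group(means)))
  }
  tk <- TukeyHSD(fit, conf.level = 1 - alpha_tukey)[[1]]
  pairs <- tibble(pair = rownames(tk), p_adj = tk[, "p adj"]) %>%
    tidyr::separate("pair", c("a", "b"), sep = "-")
  groups <- homogeneous_subsets(means$amp_id, pairs, alpha_tukey) %>%
    left_join(means, by = "amp_id")
  new_amp_grouping(f, p, alpha_anova, alpha_tukey, rejected = TRUE,
                   undefined = FALSE, means = means, tukey = pairs,
                   groups = groups)
}

single_group <- function(means) mutate(means, group = "a")

# compact-letter homogeneous subsets over amps ordered by descending mean
homogeneous_subsets <- function(amps_ordered, pairs, alpha) {
  sig <- function(x, y) {
    p <- pairs$p_adj[(pairs$a == x & pairs$b == y) |
                     (pairs$a == y & pairs$b == x)]
    length(p) > 0 && p[1] < alpha
  }
  n <- length(amps_ordered)
  # maximal contiguous run starting at each position (means are ordered, so
  # homogeneous subsets are contiguous)
  runs <- lapply(seq_len(n), function(i) {
    j <- i
    while (j + 1 <= n &&
           !any(vapply(amps_ordered[i:j],
                       function(m) sig(m, amps_ordered[j + 1]), logical(1)))) {
      j <- j + 1L
    }
    i:j
  })
  keep <- vapply(seq_along(runs), function(i) {
    !any(vapply(seq_along(runs), function(j) {
      j != i && all(runs[[i]] %in% runs[[j]])
    }, logical(1)))
  }, logical(1))
  subsets <- lapply(runs[keep], function(idx) amps_ordered[idx])
  letters_ <- letters[seq_along(subsets)]
  tibble(amp_id = amps_ordered) %>%
    mutate(group = vapply(.data$amp_id, function(a) {
      paste(letters_[vapply(subsets, function(s) a %in% s, logical(1))],
            collapse = "")
    }, character(1), USE.NAMES = FALSE))
}

new_amp_grouping <- function(f, p, alpha_anova, alpha_tukey, rejected,
                             undefined, means, tukey, groups) {
  structure(list(anova_F = f, anova_p = p, alpha_anova = alpha_anova,
                 alpha_tukey = alpha_tukey, rejected = rejected,
                 undefined = undefined, means = means, tukey = tukey,
                 groups = groups),
            class = "amp_grouping")
}

#' @export
print.amp_grouping <- function(x, ...) {
  cat("<amp_grouping> one-way ANOVA + Tukey HSD\n")
  if (x$undefined) {
    cat("  ANOVA undefined (zero residual variance)\n")
  } else if (is.na(x$anova_F)) {
    cat("  constant frequencies: null not rejected, single group\n")
  } else {
    cat(sprintf("  F = %.2f, p = %.3g (alpha = %g): null %s\n", x$anova_F,
                x$anova_p, x$alpha_anova,
                if (isTRUE(x$rejected)) "rejected" else "not rejected"))
  }
  if (!is.null(x$groups)) print(x$groups, ...)
  invisible(x)
}

#' Tidy an AMP variability grouping
#'
#' @param x an `amp_grouping` from [anova_tukey()].
#' @param ... unused.
#' @return tibble with one row per AMP: `amp_id`, `group` (compact letters;
#'   NA when the ANOVA was undefined), `mean`, `sd`, `n`.
#' @export
tidy.amp_grouping <- function(x, ...) {
  if (is.null(x$groups)) return(mutate(x$means, group = NA_character_))
  g <- x$groups
  if (!"mean" %in% names(g)) g <- left_join(g, x$means, by = "amp_id")
  select(g, "amp_id", "group", "mean", "sd", "n")
}

#' One-row summary of an AMP variability grouping
#'
#' @param x an `amp_grouping` from [anova_tukey()].
#' @param ... unused.
#' @return one-row tibble: `anova_F`, `anova_p`, `alpha_anova`,
#'   `alpha_tukey`, `rejected`, `undefined`, `n_groups`.
#' @export
glance.amp_grouping <- function(x, ...) {
  tibble(anova_F = x$anova_F, anova_p = x$anova_p,
         alpha_anova = x$alpha_anova, alpha_tukey = x$alpha_tukey,
         rejected = x$rejected, undefined = x$undefined,
         n_groups = if (is.null(x$groups)) NA_integer_
                    else dplyr::n_distinct(x$groups$group))
}

#' Per-AMP mean and standard deviation of SNC frequencies
#'
#' Sample mean and sample SD (n-1 denominator) across samples, with the
#' 2-decimal (half-up) reporting forms alongside.
#'
#' @param freq_table tibble with `amp_id`, `sample_id`, `frequency`.
#' @return tibble: `amp_id`, `mean`, `sd`, `mean_2dp`, `sd_2dp`, `n`
#'   (`sd` is NA for a single sample).
#' @export
mean_sd_by_amp <- function(freq_table) {
  freq_table %>%
    group_by(.data$amp_id) %>%
    summarise(mean = mean(.data$frequency), sd = sd(.data$frequency),
              n = n(), .groups = "drop") %>%
    mutate(mean_2dp = round_half_up(.data$mean, 2),
           sd_2dp = round_half_up(.data$sd, 2))
}
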