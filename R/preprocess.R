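# Read preprocessing: barcode demultiplexing with prefix clipping,
# modified-Mott quality trimming and minimum-length filtering.

#' Demultiplex reads by adaptor + barcode + primer prefix
#'
#' Matches each read's 5' prefix against every known
#' adaptor+barcode+gene-primer key, in both orientations (a read and its
#' reverse complement yield the same assignment). The adaptor+barcode tag is
#' matched with at most `max_mismatch` mismatches (default 0 — the
#' distance-2 barcode design makes exact matching safe), the gene-specific
#' primer IUPAC-aware with at most `primer_max_mismatch`. A best unique match
#' assigns sample/amplicon/direction and the whole prefix is clipped;
#' ties or no match go to the unassigned bin.
#'
#' @param reads tibble with `read_id`, `bases`, `quals` (phred+33 ascii).
#' @param panel an `amp_panel`.
#' @param max_mismatch allowed mismatches in the adaptor+barcode tag.
#' @param primer_max_mismatch allowed mismatches in the gene-specific primer.
#' @return list of tibbles `assigned` (with `sample_id`, `amplicon_id`,
#'   `direction`, prefix clipped) and `unassigned` (untouched rows);
#'   `nrow(assigned) + nrow(unassigned) == nrow(reads)`.
#' @export
demultiplex <- function(reads, panel, max_mismatch = 0, primer_max_mismatch = 2) {
  keys <- demux_keys(panel)
  n <- nrow(reads)
  assigned <- vector("list", n)
  ok <- logical(n)
  for (orient in c("as_is", "flipped")) {
    todo <- which(!ok)
    if (length(todo) == 0) break
    b <- reads$bases[todo]
    q <- reads$quals[todo]
    if (orient == "flipped") {
      b <- revcomp(b)
      q <- vapply(q, function(s) paste(rev(seq_chars(s)), collapse = ""), character(1),
                  USE.NAMES = FALSE)
    }
    hit <- match_prefixes(b, keys, max_mismatch, primer_max_mismatch)
    for (ii in seq_along(todo)) {
      k <- hit[[ii]]
      if (is.na(k)) next
      i <- todo[ii]
      clip <- keys$tag_len[k] + keys$plen[k]
      assigned[[i]] <- tibble(
        read_id = reads$read_id[i],
        bases = substr(b[ii], clip + 1, nchar(b[ii])),
        quals = substr(q[ii], clip + 1, nchar(q[ii])),
        sample_id = keys$sample_id[k], amplicon_id = keys$amplicon_id[k],
        direction = keys$direction[k]
      )
      ok[i] <- TRUE
    }
  }
  list(assigned = bind_rows(assigned[ok]),
       unassigned = reads[!ok, , drop = FALSE])
}

demux_keys <- function(panel) {
  amp <- select(panel$amplicons, "amplicon_id", "fwd_primer", "rev_primer")
  panel$barcodes %>%
    left_join(amp, by = "amplicon_id") %>%
    mutate(
      tag = if_else(.data$direction == "forward",
                    paste0(panel$adaptor_a, .data$barcode),
                    paste0(panel$adaptor_b, .data$barcode)),
      primer = if_else(.data$direction == "forward",
                       .data$fwd_primer, .data$rev_primer),
      tag_len = nchar(.data$tag), plen = nchar(.data$primer)
    )
}

# per read: index of the unique best-matching key, or NA
match_prefixes <- function(bases, keys, max_mismatch, primer_max_mismatch) {
  if (max_mismatch == 0 && length(unique(keys$tag_len)) == 1) {
    # fast path: exact tag lookup, then primer check on the few candidates
    tag_groups <- split(seq_len(nrow(keys)), keys$tag)
    tags <- substr(bases, 1, keys$tag_len[1])
    lapply(seq_along(bases), function(i) {
      cand <- tag_groups[[tags[i]]]
      if (is.null(cand)) return(NA_integer_)
      pick_unique(bases[i], keys, cand, primer_max_mismatch, tag_mm = 0L)
    })
  } else {
    lapply(seq_along(bases), function(i) {
      tag_mm <- vapply(seq_len(nrow(keys)), function(k) {
        obs <- substr(bases[i], 1, keys$tag_len[k])
        if (nchar(obs) < keys$tag_len[k]) Inf else hamming(obs, keys$tag[k])
      }, numeric(1))
      cand <- which(tag_mm <= max_mismatch)
      if (length(cand) == 0) return(NA_integer_)
      pick_unique(bases[i], keys, cand, primer_max_mismatch, tag_mm[cand])
    })
  }
}

pick_unique <- function(read, keys, cand, primer_max_mismatch, tag_mm) {
  tag_mm <- rep_len(tag_mm, length(cand))
  pm <- vapply(seq_along(cand), function(j) {
    k <- cand[j]
    obs <- substr(read, keys$tag_len[k] + 1, keys$tag_len[k] + keys$plen[k])
    if (nchar(obs) < keys$plen[k]) return(Inf)
    iupac_mismatches(obs, keys$primer[k])
  }, numeric(1))
  tot <- tag_mm + pm
  pass <- which(pm <= primer_max_mismatch)
  if (length(pass) == 0) return(NA_integer_)
  best <- min(tot[pass])
  hits <- pass[tot[pass] == best]
  if (length(hits) != 1) return(NA_integer_)  # ambiguous
  cand[hits]
}

#' Modified-Mott quality trimming
#'
#' Each base scores `error_limit - 10^(-q/10)`; the contiguous segment with
#' the maximal score sum is kept (leftmost, then shortest, on ties). A fully
#' low-quality read trims to an empty read.
#'
#' @param reads tibble with `read_id`, `bases`, `quals` (phred+33 ascii);
#'   extra columns pass through.
#' @param error_limit error-probability limit in (0,1); default 0.05.
#' @return the same tibble with `bases`/`quals` trimmed.
#' @export
mott_trim <- function(reads, error_limit = 0.05) {
  stopifnot(error_limit > 0, error_limit < 1)
  seg <- lapply(reads$quals, function(qs) {
    mott_segment(ascii_to_phred(qs), error_limit)
  })
  st <- vapply(seg, `[[`, integer(1), 1)
  en <- vapply(seg, `[[`, integer(1), 2)
  reads %>% mutate(bases = substr(.data$bases, st, en),
                   quals = substr(.data$quals, st, en))
}

# maximal-sum contiguous segment of (limit - perr); returns c(start, end),
# c(0, -1) for an empty result
mott_segment <- function(q, error_limit) {
  if (length(q) == 0) return(c(0L, -1L))
  s <- error_limit - phred_to_perr(q)
  best <- 0; bs <- 0L; be <- -1L
  cur <- 0; cs <- 1L
  for (i in seq_along(s)) {
    cur <- cur + s[i]
    if (cur > best + 1e-12) {
      best <- cur; bs <- cs; be <- i
    }
    if (cur < 0) { cur <- 0; cs <- i + 1L }
  }
  c(bs, be)
}

#' Minimum-length read filter
#'
#' @param reads read tibble (post-trim).
#' @param min_len minimum kept length in bases (default 100).
#' @return list of tibbles `kept` and `discarded`.
#' @export
length_filter <- function(reads, min_len = 100) {
  stopifnot(min_len >= 0)
  keep <- nchar(reads$bases) >= min_len
  list(kept = reads[keep, , drop = FALSE],
       discarded = reads[!keep, , drop = FALSE])
}
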