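# 454-style amplicon read simulator: haplotype pools with configurable
# variant frequencies, homopolymer-biased indel noise, positional quality
# decay and a junk-read fraction, with per-read ground truth for
# parameter-recovery testing.

#' 454-style error model
#'
#' Defaults are calibrated to typical amplicon pyrosequencing output: mean
#' usable (post-primer) read length 226 bp, ~15% short/low-quality junk reads
#' (88% of them shorter than 70 bp), a low per-base substitution rate and
#' homopolymer-length-dependent indel rates. `read_length["mean"] = Inf`
#' makes every read span its whole template.
#'
#' @param substitution_rate per-base substitution probability.
#' @param homopolymer_indel_rate numeric vector of indel probabilities per
#'   homopolymer run, indexed by run length 1..8 (runs longer than 8 use the
#'   last entry); must be non-decreasing.
#' @param read_length named numeric `c(mean, sd, min, max)` of the usable
#'   template segment (measured after the gene-specific primer), in bases.
#' @param junk_read_fraction proportion of short low-quality reads.
#' @param qual_start,qual_decay,qual_sd positional quality profile: mean
#'   phred `qual_start - qual_decay * position`, gaussian spread `qual_sd`.
#' @return an object of class `error_model_454`.
#' @export
error_model_454 <- function(substitution_rate = 1e-3,
                            homopolymer_indel_rate = c(1e-4, 3e-4, 1e-3, 3e-3,
                                                       6e-3, 1e-2, 1.5e-2, 2e-2),
                            read_length = c(mean = 226, sd = 45, min = 100, max = 440),
                            junk_read_fraction = 0.15,
                            qual_start = 36, qual_decay = 0.02, qual_sd = 3) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            all(homopolymer_indel_rate >= 0), all(homopolymer_indel_rate <= 1),
            !is.unsorted(homopolymer_indel_rate),
            junk_read_fraction >= 0, junk_read_fraction <= 1)
  structure(list(substitution_rate = substitution_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 read_length = read_length,
                 junk_read_fraction = junk_read_fraction,
                 qual_start = qual_start, qual_decay = qual_decay,
                 qual_sd = qual_sd),
            class = "error_model_454")
}

#' Error-free model (exact reads spanning the whole template)
#' @return an `error_model_454` with all error rates zero.
#' @export
perfect_model_454 <- function() {
  error_model_454(substitution_rate = 0,
                  homopolymer_indel_rate = rep(0, 8),
                  read_length = c(mean = Inf, sd = 0, min = 100, max = 440),
                  junk_read_fraction = 0,
                  qual_start = 40, qual_decay = 0, qual_sd = 0)
}

#' Build a haplotype pool with known variant structure
#'
#' Plants `n_variant_sites` substitution-only variant sites in one amplicon
#' and returns the ground truth. Sites are restricted to the covered cds
#' (optionally the whole amplicon) and never fall under the primer-binding
#' ends, where they would be clipped away and unobservable. In `haplotypic`
#' mode sites are nested into whole-amplicon haplotypes whose weights
#' reproduce the requested marginal frequencies exactly; in `independent`
#' mode each site is assigned per read at emission time.
#'
#' @param panel an `amp_panel`.
#' @param amplicon_id amplicon to mutate.
#' @param sample_id sample label carried into the truth.
#' @param n_variant_sites number of variant sites.
#' @param freqs allele frequencies in (0,1), one per site (recycled).
#' @param linkage `"haplotypic"` or `"independent"`.
#' @param cds_only restrict sites to the covered cds (default TRUE).
#' @param seed integer seed; site placement is deterministic given it.
#' @return an object of class `haplotype_truth`: list with `amplicon_id`,
#'   `sample_id`, `linkage`, tibbles `haplotypes` (hap_id, sequence,
#'   frequency) and `true_sncs` (position, ref, alt, expected_freq).
#' @export
build_haplotype_pool <- function(panel, amplicon_id, sample_id = "S1",
                                 n_variant_sites = 2, freqs = 0.2,
                                 linkage = c("haplotypic", "independent"),
                                 cds_only = TRUE, seed = 1) {
  linkage <- match.arg(linkage)
  a <- amp_row(panel, amplicon_id)
  ref <- a$sequence
  if (n_variant_sites > 0) {
    freqs <- rep_len(freqs, n_variant_sites)
    stopifnot(all(freqs > 0), all(freqs < 1))
  } else freqs <- numeric(0)
  plen_f <- nchar(a$fwd_primer)
  plen_r <- nchar(a$rev_primer)
  if (cds_only) {
    sp <- cds_span(a)
    avail <- seq(max(sp[["start"]], plen_f + 1), min(sp[["end"]], a$length - plen_r))
  } else {
    avail <- seq(plen_f + 1, a$length - plen_r)
  }
  if (n_variant_sites > length(avail))
    abort(paste0("requested ", n_variant_sites, " sites but only ",
                 length(avail), " positions available"))
  truth <- if (n_variant_sites == 0) {
    tibble(position = integer(), ref = character(), alt = character(),
           expected_freq = numeric())
  } else {
    withr_seed(seed, {
      pos <- sort(sample(avail, n_variant_sites))
      refb <- substring(ref, pos, pos)
      altb <- vapply(refb, function(b) sample(setdiff(DNA_BASES, b), 1),
                     character(1))
      tibble(position = as.integer(pos), ref = unname(refb),
             alt = unname(altb), expected_freq = freqs)
    })
  }
  haps <- hap_table(ref, truth, linkage)
  structure(list(amplicon_id = amplicon_id, sample_id = sample_id,
                 linkage = linkage, reference = ref,
                 haplotypes = haps, true_sncs = truth),
            class = "haplotype_truth")
}

# nested haplotype construction: sites sorted by descending frequency,
# haplotype k carries sites 1..k with weight f_k - f_(k+1); marginals equal
# the requested site frequencies exactly
hap_table <- function(ref, truth, linkage) {
  if (nrow(truth) == 0 || linkage == "independent") {
    return(tibble(hap_id = "H0", sequence = ref,
                  frequency = 1, n_sites = 0L))
  }
  ord <- order(-truth$expected_freq)
  t2 <- truth[ord, ]
  f <- c(t2$expected_freq, 0)
  seqs <- character(nrow(t2))
  s <- ref
  for (k in seq_len(nrow(t2))) {
    substr(s, t2$position[k], t2$position[k]) <- t2$alt[k]
    seqs[k] <- s
  }
  out <- tibble(hap_id = paste0("H", seq_len(nrow(t2))), sequence = seqs,
                frequency = f[-length(f)] - f[-1],
                n_sites = seq_len(nrow(t2)))
  out <- bind_rows(tibble(hap_id = "H0", sequence = ref,
                          frequency = 1 - t2$expected_freq[1], n_sites = 0L),
                   out)
  out <- out[out$frequency > 1e-12, ]
  stopifnot(abs(sum(out$frequency) - 1) < 1e-9)
  out
}

#' Simulate barcoded bidirectional 454-style reads
#'
#' Each read is adaptor + barcode + a template segment starting at the fusion
#' primer end (forward template or its reverse complement, with equal
#' direction probability), with substitutions, homopolymer-run indels and a
#' positional quality profile injected per the error model; a configurable
#' fraction of junk reads (short, low-quality) is mixed in. The returned
#' sidecar records each read's haplotype, direction and injected errors.
#'
#' @param truth a `haplotype_truth` from [build_haplotype_pool()].
#' @param panel the `amp_panel` holding barcodes and adaptors.
#' @param n_reads number of reads to emit (>= 1).
#' @param model an `error_model_454`.
#' @param seed integer seed; same seed gives byte-identical output.
#' @param forward_prob probability that a read starts at the forward fusion
#'   primer (default 0.5, bidirectional).
#' @param fastq optional path: write reads as Sanger FASTQ (phred+33).
#' @return list with `reads` (tibble: read_id, bases, quals ascii) and
#'   `sidecar` (tibble: read_id, sample_id, amplicon_id, haplotype_id,
#'   direction, junk, n_sub, n_indel, sub_pos, indel_pos — positions in
#'   amplicon coordinates).
#' @export
simulate_reads <- function(truth, panel, n_reads, model = error_model_454(),
                           seed = 1, forward_prob = 0.5, fastq = NULL) {
  stopifnot(inherits(truth, "haplotype_truth"), n_reads >= 1)
  a <- amp_row(panel, truth$amplicon_id)
  bc <- panel$barcodes %>%
    filter(.data$sample_id == truth$sample_id,
           .data$amplicon_id == truth$amplicon_id)
  if (nrow(bc) == 0)
    abort(paste0("no barcodes for sample ", truth$sample_id, " amplicon ",
                 truth$amplicon_id))
  bcf <- bc$barcode[bc$direction == "forward"]
  bcr <- bc$barcode[bc$direction == "reverse"]
  plen <- c(forward = nchar(a$fwd_primer), reverse = nchar(a$rev_primer))

  res <- withr_seed(seed, {
    reads <- vector("list", n_reads)
    side <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      rid <- sprintf("%s_%s_r%06d", truth$sample_id, truth$amplicon_id, i)
      junk <- runif(1) < model$junk_read_fraction
      dirn <- if (runif(1) < forward_prob) "forward" else "reverse"
      hap <- draw_haplotype(truth)
      template <- if (dirn == "forward") hap$sequence else revcomp(hap$sequence)
      prefix <- if (dirn == "forward") paste0(panel$adaptor_a, bcf)
                else paste0(panel$adaptor_b, bcr)
      avail <- nchar(template) - plen[[dirn]]
      if (junk) {
        # junk keeps enough prefix to demultiplex, then fails the trim and
        # length gates; 88% of junk is shorter than 70 template bases
        L <- if (runif(1) < 0.88) sample(24:69, 1) else sample(70:99, 1)
        emitted <- substr(template, 1, min(L, nchar(template)))
      } else {
        if (!is.finite(model$read_length[["mean"]])) {
          L <- avail
        } else {
          L <- round(rnorm(1, model$read_length[["mean"]], model$read_length[["sd"]]))
          L <- max(min(L, model$read_length[["max"]], avail),
                   model$read_length[["min"]])
        }
        emitted <- substr(template, 1, plen[[dirn]] + L)
      }
      err <- inject_errors(paste0(prefix, emitted), nchar(prefix), model, junk)
      # map template-coordinate errors back to amplicon coordinates
      tpos <- function(p) {
        p <- p[p > nchar(prefix)] - nchar(prefix)
        if (dirn == "forward") p else nchar(template) - p + 1L
      }
      reads[[i]] <- tibble(read_id = rid, bases = err$bases,
                           quals = phred_to_ascii(err$quals))
      side[[i]] <- tibble(read_id = rid, sample_id = truth$sample_id,
                          amplicon_id = truth$amplicon_id,
                          haplotype_id = hap$hap_id, direction = dirn,
                          junk = junk,
                          n_sub = length(err$sub_pos),
                          n_indel = length(err$indel_pos),
                          sub_pos = paste(tpos(err$sub_pos), collapse = ","),
                          indel_pos = paste(tpos(err$indel_pos), collapse = ","))
    }
    list(reads = bind_rows(reads), sidecar = bind_rows(side))
  })
  if (!is.null(fastq)) write_fastq(res$reads, fastq)
  res
}

draw_haplotype <- function(truth) {
  if (truth$linkage == "independent" && nrow(truth$true_sncs) > 0) {
    s <- truth$reference
    carried <- runif(nrow(truth$true_sncs)) < truth$true_sncs$expected_freq
    for (k in which(carried)) {
      substr(s, truth$true_sncs$position[k], truth$true_sncs$position[k]) <-
        truth$true_sncs$alt[k]
    }
    id <- if (any(carried)) paste0("I", paste(which(carried), collapse = "+")) else "H0"
    return(list(hap_id = id, sequence = s))
  }
  k <- sample.int(nrow(truth$haplotypes), 1, prob = truth$haplotypes$frequency)
  list(hap_id = truth$haplotypes$hap_id[k], sequence = truth$haplotypes$sequence[k])
}

# inject substitutions (whole read) and homopolymer indels (template part),
# then draw per-base qualities from the positional profile; error bases get
# down-shifted qualities
inject_errors <- function(read, prefix_len, model, junk) {
  ch <- seq_chars(read)
  n0 <- length(ch)
  sub_pos <- integer(0)
  if (model$substitution_rate > 0) {
    sub_pos <- which(runif(n0) < model$substitution_rate)
    for (p in sub_pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  }
  # homopolymer runs in the template portion (post-substitution sequence)
  indel_pos <- integer(0)
  is_ins <- logical(0)
  if (any(model$homopolymer_indel_rate > 0) && n0 > prefix_len) {
    r <- rle(ch[(prefix_len + 1):n0])
    run_end <- prefix_len + cumsum(r$lengths)
    rate <- model$homopolymer_indel_rate[pmin(r$lengths, length(model$homopolymer_indel_rate))]
    hit <- which(runif(length(r$lengths)) < rate)
    for (k in hit) {
      indel_pos <- c(indel_pos, run_end[k])
      is_ins <- c(is_ins, runif(1) < 0.5)
    }
  }
  err_mask <- rep(FALSE, n0)
  err_mask[sub_pos] <- TRUE
  # apply indels from rightmost to keep earlier coordinates stable
  if (length(indel_pos) > 0) {
    ord <- order(-indel_pos)
    for (k in ord) {
      p <- indel_pos[k]
      if (is_ins[k]) {
        ch <- append(ch, ch[p], after = p)
        err_mask <- append(err_mask, TRUE, after = p)
      } else {
        ch <- ch[-p]
        err_mask <- err_mask[-p]
      }
    }
  }
  n <- length(ch)
  if (junk) {
    q <- pmin(pmax(round(rnorm(n, 8, 2)), 2), 40)
  } else {
    mu <- model$qual_start - model$qual_decay * seq_len(n)
    mu[err_mask[seq_len(n)]] <- mu[err_mask[seq_len(n)]] - 12
    q <- pmin(pmax(round(rnorm(n, mu, model$qual_sd)), 2), 40)
  }
  list(bases = paste(ch, collapse = ""), quals = q,
       sub_pos = sub_pos, indel_pos = sort(indel_pos))
}

#' Write reads as Sanger FASTQ (phred+33)
#' @param reads tibble with `read_id`, `bases`, `quals` (ascii).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$bases,
                           "+", reads$quals))
  writeLines(lines, path)
  invisible(path)
}

#' Read Sanger FASTQ into a read tibble
#' @param path FASTQ path.
#' @return tibble with `read_id`, `bases`, `quals` (ascii).
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  tibble(read_id = names(x), bases = unname(as.character(x)),
         quals = unname(as.character(Biostrings::quality(x))))
}

#' Write reads as 454-style FASTA + QUAL file pair
#' @param reads tibble with `read_id`, `bases`, `quals` (ascii).
#' @param fasta,qual output paths.
#' @return invisibly, the two paths.
#' @export
write_fasta_qual <- function(reads, fasta, qual) {
  writeLines(as.vector(rbind(paste0(">", reads$read_id), reads$bases)), fasta)
  qlines <- as.vector(rbind(paste0(">", reads$read_id),
                            vapply(reads$quals,
                                   function(q) paste(ascii_to_phred(q), collapse = " "),
                                   character(1))))
  writeLines(qlines, qual)
  invisible(c(fasta = fasta, qual = qual))
}
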