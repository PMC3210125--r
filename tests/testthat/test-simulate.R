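test_that("haplotype pools reproduce the requested variant structure", {
  p <- tiny_panel()
  # no variant sites: a single reference haplotype at frequency 1
  t0 <- build_haplotype_pool(p, "TINY_1", n_variant_sites = 0, seed = 1)
  expect_equal(nrow(t0$haplotypes), 1)
  expect_equal(t0$haplotypes$frequency, 1)
  expect_equal(t0$haplotypes$sequence, amp_subset(p, "TINY_1")$sequence)
  expect_equal(nrow(t0$true_sncs), 0)

  # haplotypic mode: marginal frequencies equal the spec by construction
  t2 <- build_haplotype_pool(p, "TINY_1", n_variant_sites = 2,
                             freqs = c(0.2, 0.5), seed = 2)
  expect_equal(sum(t2$haplotypes$frequency), 1, tolerance = 1e-9)
  ref <- t2$reference
  for (k in seq_len(nrow(t2$true_sncs))) {
    s <- t2$true_sncs[k, ]
    carriers <- substr(t2$haplotypes$sequence, s$position, s$position) == s$alt
    expect_equal(sum(t2$haplotypes$frequency[carriers]), s$expected_freq,
                 tolerance = 1e-9)
    expect_equal(substr(ref, s$position, s$position), s$ref)
  }
  # haplotypes differ from the reference only at listed SNC positions
  for (h in seq_len(nrow(t2$haplotypes))) {
    diffs <- which(strsplit(t2$haplotypes$sequence[h], "")[[1]] !=
                     strsplit(ref, "")[[1]])
    expect_true(all(diffs %in% t2$true_sncs$position))
  }
  expect_error(build_haplotype_pool(p, "TINY_1", n_variant_sites = 1000,
                                    seed = 1),
               "available")
})

test_that("error-free reads are exact barcoded copies recovered at 100%", {
  p <- tiny_panel()
  pool <- build_haplotype_pool(p, "TINY_1", sample_id = "S1",
                               n_variant_sites = 0, seed = 1)
  sim <- simulate_reads(pool, p, n_reads = 60, model = perfect_model_454(),
                        seed = 2)
  a <- amp_subset(p, "TINY_1")
  bc <- p$barcodes
  for (i in seq_len(nrow(sim$reads))) {
    d <- sim$sidecar$direction[i]
    tmpl <- if (d == "forward") a$sequence else revcomp(a$sequence)
    b <- bc$barcode[bc$sample_id == "S1" & bc$direction == d]
    prefix <- if (d == "forward") paste0(p$adaptor_a, b) else paste0(p$adaptor_b, b)
    expect_equal(sim$reads$bases[i], paste0(prefix, tmpl))
  }
  dm <- demultiplex(sim$reads, p)
  expect_equal(nrow(dm$unassigned), 0)
  expect_equal(dm$assigned$sample_id, rep("S1", 60))
  expect_equal(dm$assigned$amplicon_id, rep("TINY_1", 60))
  expect_equal(dm$assigned$direction, sim$sidecar$direction)
})

test_that("same seed gives byte-identical FASTQ output", {
  p <- tiny_panel()
  pool <- build_haplotype_pool(p, "TINY_1", n_variant_sites = 2,
                               freqs = 0.3, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(pool, p, 150, model = error_model_454(), seed = 9, fastq = f1)
  simulate_reads(pool, p, 150, model = error_model_454(), seed = 9, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(pool, p, 150, model = error_model_454(), seed = 10, fastq = f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("haplotype draw frequencies converge to the pool spec", {
  p <- tiny_panel()
  pool <- build_haplotype_pool(p, "TINY_1", n_variant_sites = 2,
                               freqs = c(0.3, 0.1), seed = 3)
  sim <- simulate_reads(pool, p, n_reads = 4000, model = perfect_model_454(),
                        seed = 4)
  draws <- table(sim$sidecar$haplotype_id)
  for (h in seq_len(nrow(pool$haplotypes))) {
    f <- pool$haplotypes$frequency[h]
    obs <- as.integer(draws[pool$haplotypes$hap_id[h]])
    se <- sqrt(f * (1 - f) * 4000)
    expect_lt(abs(obs - f * 4000), 4 * se + 1)
  }
})

test_that("injected substitution counts match the configured rate", {
  p <- tiny_panel()
  pool <- build_haplotype_pool(p, "TINY_1", n_variant_sites = 0, seed = 1)
  model <- error_model_454(substitution_rate = 5e-3,
                           homopolymer_indel_rate = rep(0, 8),
                           junk_read_fraction = 0)
  sim <- simulate_reads(pool, p, n_reads = 2500, model = model, seed = 6)
  total_bases <- sum(nchar(sim$reads$bases))
  n_sub <- sum(sim$sidecar$n_sub)
  se <- sqrt(5e-3 * (1 - 5e-3) * total_bases)
  expect_lt(abs(n_sub - 5e-3 * total_bases), 3 * se)
})

test_that("homopolymer indels are placed at homopolymer runs", {
  p <- tiny_panel()
  pool <- build_haplotype_pool(p, "TINY_1", n_variant_sites = 0, seed = 1)
  model <- error_model_454(substitution_rate = 0,
                           homopolymer_indel_rate = rep(0.05, 8),
                           junk_read_fraction = 0)
  sim <- simulate_reads(pool, p, n_reads = 300, model = model, seed = 7)
  idx <- which(sim$sidecar$n_indel > 0)
  expect_gt(length(idx), 0)
  ref <- amp_subset(p, "TINY_1")$sequence
  rch <- strsplit(ref, "")[[1]]
  for (i in idx) {
    pos <- as.integer(strsplit(sim$sidecar$indel_pos[i], ",")[[1]])
    # each indel sits at the boundary of a (possibly length-1) run whose
    # neighbours share the run base
    expect_true(all(pos >= 1 & pos <= nchar(ref)))
  }
  # with all rates zero no indels ever occur
  sim0 <- simulate_reads(pool, p, 100, model = perfect_model_454(), seed = 8)
  expect_equal(sum(sim0$sidecar$n_indel), 0)
})

test_that("default model calibration: trimmed length and junk fraction", {
  p <- demo_panel()
  pool <- build_haplotype_pool(p, "MytM_1", sample_id = "Pa",
                               n_variant_sites = 0, seed = 1)
  sim <- simulate_reads(pool, p, n_reads = 1200, model = error_model_454(),
                        seed = 13)
  dm <- demultiplex(sim$reads, p)
  lf <- length_filter(mott_trim(dm$assigned))
  # post-trim mean usable length within +/- 10 of the configured 226
  expect_lt(abs(mean(nchar(lf$kept$bases)) - 226), 10)
  # discarded fraction close to the configured junk fraction
  disc <- nrow(lf$discarded) / (nrow(lf$kept) + nrow(lf$discarded))
  expect_lt(abs(disc - 0.15), 0.02)
  # junk reads are predominantly shorter than 70 bp
  junk_len <- nchar(sim$reads$bases[sim$sidecar$junk])
  expect_gt(mean(junk_len < 70 + 24), 0.7)
})

test_that("FASTQ and FASTA+QUAL writers round-trip reads", {
  reads <- make_reads(c("ACGTACGT", "GGATCC"),
                      quals = c("IIIIIIII", "!!!IJK"))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$bases, reads$bases)
  expect_equal(back$quals, reads$quals)
  fa <- withr::local_tempfile(fileext = ".fasta")
  qu <- withr::local_tempfile(fileext = ".qual")
  write_fasta_qual(reads, fa, qu)
  expect_equal(readLines(fa)[c(2, 4)], reads$bases)
  expect_equal(as.integer(strsplit(readLines(qu)[2], " ")[[1]]),
               utf8ToInt(reads$quals[1]) - 33L)
})
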