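test_that("genuine-SNC thresholds: 30x coverage and 3% frequency", {
  p <- tiny_panel()
  # depth 29 with a 10% alternate: no call
  pile <- make_pileup("TINY_1", pos = 40, ref = "T", T = 26, A = 3)
  expect_equal(nrow(call_sncs(pile, p)), 0)
  # depth 30 with exactly 3%: called
  pile2 <- make_pileup("TINY_1", pos = 40, ref = "T", T = 29, A = 1)
  s2 <- call_sncs(pile2, p, min_depth = 30, min_freq = 1 / 30)
  expect_equal(nrow(s2), 1)
  # depth 1000: 29 alternate observations miss 3%, 30 make it
  pile3 <- make_pileup("TINY_1", pos = 40, ref = "T", T = 971, A = 29)
  expect_equal(nrow(call_sncs(pile3, p)), 0)
  pile4 <- make_pileup("TINY_1", pos = 40, ref = "T", T = 970, A = 30)
  s4 <- call_sncs(pile4, p)
  expect_equal(nrow(s4), 1)
  expect_equal(s4$alt, "A")
  expect_equal(s4$frequency, 0.03)
  expect_equal(s4$region, "mature")
  expect_true(s4$in_cds)
})

test_that("multi-allelic columns yield one SNC per alternate allele", {
  p <- tiny_panel()
  pile <- make_pileup("TINY_1", pos = 50, ref = "G", G = 800, A = 100, C = 100)
  s <- call_sncs(pile, p)
  expect_equal(nrow(s), 2)
  expect_equal(sort(s$alt), c("A", "C"))
})

test_that("near-fixed changes are flagged for review when max_freq is set", {
  p <- tiny_panel()
  pile <- make_pileup("TINY_1", pos = 58, ref = "C", T = 990, C = 10)
  off <- call_sncs(pile, p)
  expect_false(any(off$fixed_flag))
  on <- call_sncs(pile, p, max_freq = 0.95)
  expect_equal(nrow(on), 1)          # still reported, not dropped
  expect_true(all(on$fixed_flag))
})

test_that("raising thresholds never increases the number of genuine SNCs", {
  p <- tiny_panel()
  set.seed(31)
  rows <- lapply(sample(16:105, 40), function(pos) {
    ref <- substr(TINY_TX, pos, pos)
    counts <- setNames(rep(0, 4), c("A", "C", "G", "T"))
    counts[ref] <- sample(10:500, 1)
    alt <- sample(setdiff(names(counts), ref), 1)
    counts[alt] <- sample(0:60, 1)
    make_pileup("TINY_1", pos = pos, ref = ref, A = counts[["A"]],
                C = counts[["C"]], G = counts[["G"]], T = counts[["T"]])
  })
  pile <- dplyr::bind_rows(rows)
  base <- nrow(call_sncs(pile, p, min_depth = 30, min_freq = 0.03))
  for (md in c(30, 50, 100, 200)) {
    for (mf in c(0.03, 0.05, 0.1, 0.5)) {
      n <- nrow(call_sncs(pile, p, min_depth = md, min_freq = mf))
      expect_lte(n, base)
      expect_lte(nrow(call_sncs(pile, p, min_depth = md * 2, min_freq = mf)), n)
      expect_lte(nrow(call_sncs(pile, p, min_depth = md, min_freq = mf * 1.5)), n)
    }
  }
})

test_that("same-codon SNCs merge and classify by virtual translation", {
  p <- tiny_panel()
  # codon 2 of the tiny cds is GCT (Ala) at positions 19-21
  # GCT -> GCC: synonymous third-position change
  pile <- make_pileup("TINY_1", pos = 21, ref = "T", T = 180, C = 20)
  s <- call_sncs(pile, p)
  ch <- merge_and_classify(s, p)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$ref_codon, "GCT")
  expect_equal(ch$alt_codon, "GCC")
  expect_true(ch$synonymous)
  expect_equal(ch$ref_aa, "A")

  # codon 9 is TGT (Cys) at 40-42; TGT -> AGT is Cys -> Ser
  pile2 <- make_pileup("TINY_1", pos = 40, ref = "T", T = 180, A = 20)
  ch2 <- merge_and_classify(call_sncs(pile2, p), p)
  expect_false(ch2$synonymous)
  expect_equal(ch2$ref_aa, "C")
  expect_equal(ch2$alt_aa, "S")
  expect_equal(ch2$region, "mature")

  # two SNCs in one codon merge into a single change applied jointly
  pile3 <- dplyr::bind_rows(
    make_pileup("TINY_1", pos = 19, ref = "G", G = 180, A = 20),
    make_pileup("TINY_1", pos = 21, ref = "T", T = 180, C = 20)
  )
  ch3 <- merge_and_classify(call_sncs(pile3, p), p)
  expect_equal(nrow(ch3), 1)
  expect_equal(ch3$alt_codon, "ACC")
  expect_equal(ch3$n_components, 2)
  expect_false(ch3$synonymous)  # GCT(Ala) -> ACC(Thr)
})

test_that("SNCs outside the cds are excluded from merged cds changes", {
  p <- tiny_panel()
  pile <- make_pileup("TINY_1", pos = 5, ref = substr(TINY_TX, 5, 5),
                      A = 50, G = 150)
  s <- call_sncs(pile, p)
  expect_equal(nrow(s), 1)
  expect_false(s$in_cds)
  expect_equal(s$region, "flank")
  expect_equal(nrow(merge_and_classify(s, p)), 0)
})

test_that("summaries count changes, compute omega and per-codon frequency", {
  p <- tiny_panel()
  mk_change <- function(n, syn) {
    tibble::tibble(amp_id = "MGD1", sample_id = "S1",
                   codon_index = seq_len(n), ref_codon = "GCT",
                   alt_codon = "GCC", ref_aa = "A",
                   alt_aa = ifelse(syn, "A", "T"), synonymous = syn,
                   region = "mature", n_components = 1L,
                   component_pos = "1", component_alt = "C")
  }
  sncs <- tibble::tibble(amp_id = "MGD1", amplicon_id = "TINY_1",
                         sample_id = "S1", pos = 1:25, tx_pos = 1:25,
                         ref = "A", alt = "C", alt_count = 10L, depth = 100L,
                         frequency = 0.1, codon_index = 1:25,
                         region = "mature", in_cds = TRUE, fixed_flag = FALSE)
  ch <- dplyr::bind_rows(mk_change(10, FALSE),
                         dplyr::mutate(mk_change(15, TRUE),
                                       codon_index = codon_index + 10L))
  s <- summarize_variants(ch, sncs, p)
  expect_equal(s$ns_count, 10L)
  expect_equal(s$syn_count, 15L)
  expect_equal(s$omega, 10 / 15)
  expect_equal(s$omega_label, "0.7")
  expect_equal(s$snc_cds, 25L)
  expect_equal(s$covered_codons, 30L)
  expect_equal(s$frequency_2dp, 0.83)
  expect_equal(s$frequency_per_nt, 25 / 90)

  # no non-synonymous changes: omega 0.0
  s0 <- summarize_variants(mk_change(5, TRUE), sncs[1:5, ], p)
  expect_equal(s0$omega_label, "0.0")
  expect_equal(s0$omega, 0)
  # no synonymous changes: undefined omega, bracketed count
  s11 <- summarize_variants(mk_change(11, FALSE), sncs[1:11, ], p)
  expect_true(s11$omega_undefined)
  expect_equal(s11$omega_label, "[11]")
  expect_true(is.na(s11$omega))
})

test_that("overlapping amplicons of one AMP pool to a union of changes", {
  p <- demo_panel()
  # the same transcript change seen in both MytC amplicons (overlap zone)
  a1 <- amp_subset(p, "MytC_1")
  a2 <- amp_subset(p, "MytC_2")
  # codon 50 is inside both amplicons; its transcript positions:
  txp <- a1$cds_tx_start + (50 - 1) * 3
  pos1 <- txp - a1$tx_start + 1
  pos2 <- txp - a2$tx_start + 1
  ref_b <- substr(a1$sequence, pos1, pos1)
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  counts <- function(ref_n, alt_n) {
    out <- setNames(rep(0, 4), c("A", "C", "G", "T"))
    out[ref_b] <- ref_n; out[alt_b] <- alt_n
    out
  }
  c1 <- counts(90, 10)
  pile <- dplyr::bind_rows(
    make_pileup("MytC_1", pos = pos1, ref = ref_b, A = c1[["A"]],
                C = c1[["C"]], G = c1[["G"]], T = c1[["T"]], sample_id = "Pa"),
    make_pileup("MytC_2", pos = pos2, ref = ref_b, A = c1[["A"]],
                C = c1[["C"]], G = c1[["G"]], T = c1[["T"]], sample_id = "Pa")
  )
  s <- call_sncs(pile, p)
  expect_equal(nrow(s), 2)              # one record per amplicon
  expect_equal(length(unique(s$tx_pos)), 1)
  ch <- merge_and_classify(s, p)
  expect_equal(nrow(ch), 1)             # merged on the shared frame
  summ <- summarize_variants(ch, s, p)
  expect_equal(summ$snc_total, 1L)      # per-AMP union
  expect_equal(summ$snc_total_by_amplicon, 2L)
  expect_equal(summ$snc_cds, 1L)
})

test_that("snc_maps lays changes out by position, type and region", {
  p <- tiny_panel()
  expect_equal(nrow(snc_maps(ampdiversity:::empty_change_tbl())), 0)
  pile <- make_pileup("TINY_1", pos = 40, ref = "T", T = 180, A = 20)
  ch <- merge_and_classify(call_sncs(pile, p), p)
  m <- snc_maps(ch)
  expect_equal(nrow(m), 1)
  expect_equal(m$tx_pos, 40L)
  expect_equal(m$region, "mature")
  expect_false(m$synonymous)
})

test_that("SNC table exports as minimal VCF", {
  p <- tiny_panel()
  pile <- make_pileup("TINY_1", pos = 40, ref = "T", T = 180, A = 20)
  s <- call_sncs(pile, p)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_snc_vcf(s, p, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 1)
  expect_match(body, "^TINY_1\t40\t\\.\tT\tA\t")
})
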