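---
title: "Methods: quantifying AMP transcript diversity from barcoded amplicon pyrosequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying AMP transcript diversity from barcoded amplicon pyrosequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampdiversity)
library(dplyr)
```

## The problem

Mussel hemocytes express a repertoire of antimicrobial peptides (AMPs) —
mytilins, myticins, mytimycin and defensins — whose precursor transcripts are
strikingly polymorphic. Each precursor is a pre-pro-peptide: an N-terminal
signal peptide, the mature cationic peptide stabilized by a conserved array
of 8 cysteines (12 in mytimycin), and (except for the truncated defensin
MGDt) a C-terminal extension. Deep amplicon sequencing of hemolymph pools
can map this diversity: amplicons covering nine AMP precursor transcripts
are tagged with sample barcodes, pyrosequenced bidirectionally, and each
single-nucleotide change (SNC) against the reference transcript is called,
classified as synonymous or non-synonymous, and compared across samples.

`ampdiversity` implements that analysis as a tidyverse-native pipeline —
tibbles in, tibbles out — together with a 454-style read simulator that
provides ground truth for every stage, so the whole pipeline is testable
without any sequencing data.

## Pipeline model

The stages, in order, with their tunable parameters (all exposed through
`pipeline_config()`):

1. **Demultiplexing** (`demultiplex()`). Each read starts
   adaptor (19 nt) + barcode (5 nt) + gene-specific primer. The
   adaptor+barcode tag is matched exactly by default (`max_mismatch = 0`):
   the barcode design guarantees pairwise Hamming distance ≥ 2, so a single
   error cannot convert one barcode into another, and tolerating one
   mismatch is ambiguous by construction. The primer is matched IUPAC-aware
   with up to 2 mismatches (degenerate primers are part of the design; a
   tolerance is not stated anywhere, so it is configurable). The entire
   prefix is clipped: variants under the primer are unobservable in any
   case, because primer-derived bases reproduce the primer, not the
   template.
2. **Quality trimming** (`mott_trim()`): modified-Mott trimming at error
   limit 0.05 — each base scores `0.05 − 10^(−q/10)` and the kept segment
   maximizes the running sum. Ties are resolved to the leftmost, then
   shortest, segment, making trimming fully deterministic.
3. **Length filter** (`length_filter()`): minimum 100 bp by default. A
   70 bp threshold is a reasonable alternative (most discarded reads in
   this kind of run are shorter than 70 bp) and is available through the
   same argument.
4. **Mapping** (`align_reads()`): semi-global alignment of each read
   against its reference amplicon (free end gaps on the reference, read
   aligned end-to-end), scores +1/−2/−3/−1 for
   match/mismatch/gap-open/gap-extend. Homopolymer gaps are deliberately
   *not* discounted relative to mismatches: under-penalizing gaps would
   let 454's dominant error mode absorb true substitutions into
   alignments, and the substitution calls are meant to stay conservative.
   Reads below 80% identity are flagged non-specific and ignored.
5. **Pileup** (`build_pileup()`): an observation counts as
   quality-passing only if its base quality is ≥ 20 **and** the mean
   quality in a ±5-base window is ≥ 15. The window half-width is not
   standardized anywhere; 5 (an 11-base window) matches common
   variant-caller practice and is a parameter.
6. **Genuine SNC calling** (`call_sncs()`): a column must reach 30×
   quality-passing coverage, and an alternate allele 3% frequency.
   Insertions and deletions never produce SNCs (they are tracked per
   column but are overwhelmingly sequencing noise on this platform).
   Multi-allelic columns yield one SNC per alternate allele — the
   conservative superset. An optional `max_freq` flag marks near-fixed
   columns (e.g. 100% differences that more likely reflect an error in
   the reference EST than a variant) for review instead of silently
   dropping them.
7. **Codon merging and ω** (`merge_and_classify()`,
   `summarize_variants()`): SNCs in the same codon are merged, the
   alternate codon is translated, and a change is synonymous iff the amino
   acid is unchanged. ω is the *raw ratio* of non-synonymous to synonymous
   merged changes — deliberately not an opportunity-normalized dN/dS — and
   is undefined when there are no synonymous changes, in which case it is
   reported as the bracketed non-synonymous count. Overlapping amplicons of
   one AMP are pooled by union on the shared transcript coordinate frame
   before counting.
8. **SNC frequency**: the headline frequency is merged cds changes per
   covered codon. The bundled survey table's printed frequencies are
   reproduced exactly by this per-codon denominator (e.g. MytC: 27 changes
   over 100 codons → 0.27), and not by a per-nucleotide one; the
   per-nucleotide variant is emitted alongside (`frequency_per_nt`) for
   completeness.
9. **Clustering and peptides** (`cluster_reads()`,
   `enumerate_peptides()`): reads identical in length and sequence form
   clusters (reference-identical vs variant); clusters covered ≥ 3× are
   virtually translated over their covered complete codons and peptides
   identical after translation are merged, removing silent redundancy. The
   "fraction with ≥ 1 SNC" statistic is computed as a fraction of
   *clusters*, not reads (the natural reading; the alternative is one
   `summarise()` away from the cluster table). Translation is limited to
   the covered cds window, so peptides from partial clusters are flagged
   `partial`; the cysteine-array retention flag checks only covered array
   positions.
10. **Variability statistics** (`anova_tukey()`, `mean_sd_by_amp()`,
    `common_exclusive()`): one-way ANOVA (α = 0.001) of SNC frequency with
    AMP as the factor and samples as replicates; if rejected, all-pairs
    Tukey HSD (α = 0.05) condensed into homogeneous subsets. Subsets are
    built by the standard compact-letter construction — sort AMPs by mean,
    grow a subset while every within-subset pair is non-significant — since
    no specific grouping algorithm is standard for this table. The result
    object supports `tidy()`, `glance()` and `autoplot()`.

## The synthetic-data generator

`build_haplotype_pool()` plants substitution-only variant sites (truth
variants are SNCs; indels exist only as sequencing noise) inside the covered
cds, away from primer-binding ends where they would be clipped and
unobservable. In `haplotypic` mode, sites are nested into whole-amplicon
haplotypes whose weights reproduce the requested marginal frequencies
exactly; `independent` mode draws each site per read.

`simulate_reads()` emits adaptor + barcode + template reads from the fusion
primer end, forward or reverse-complement with a configurable direction
probability (default 0.5), with no random fragmentation — this is amplicon
sequencing, and total or partial overlap of the two directions is what
covers the reference completely. The default `error_model_454()` is
calibrated to the platform's printed behavior rather than to any stated
error rates (none are published for this design):

* usable read length (after the primer) normal with mean 226 and sd 45,
  clamped to [100, 440] and to the template;
* 15% junk reads — short (88% under 70 bases) and low quality (q ≈ 8), so
  they demultiplex but fail the trim/length gates, reproducing the
  expected discard fraction;
* per-base substitution rate 10⁻³, with error bases drawn toward lower
  qualities so the q20/q15 gates are informative;
* homopolymer indel probability per run rising monotonically from 10⁻⁴
  (run length 1) to 2×10⁻² (run length ≥ 8);
* positional quality decay (mean phred 36 − 0.02·position, sd 3), keeping
  the implied average error probability near the substitution rate.

These defaults were fixed once, from the published read-length and discard
statistics, and are the conditions under which the acceptance checks run.

What the simulator does **not** emulate: flowgram (SFF-level) noise, PCR
chimeras, barcode cross-talk beyond point errors, and real haplotype
linkage structure. Passing tests therefore demonstrate that the pipeline's
filters and statistics behave correctly under a faithful error *model*, not
that any particular biological dataset would be reproduced read-for-read.

## Numerical choices

* Rounding for reported values is half-up (ω to 1 decimal, frequencies and
  SDs to 2), matching how such tables are conventionally printed; base R's
  round-half-to-even would print 9/4 as 2.2 instead of the expected 2.3.
  Unrounded values are always retained alongside.
* Alignment tie-breaks follow the aligner's deterministic leftmost-gap
  convention; Mott trimming ties are leftmost-shortest; the barcode
  generator is a deterministic lexicographic greedy code (86 valid 5-mers
  at distance 2; verified against exhaustive search over all 1024
  candidates) from which a seeded subset is drawn, so any requested set is
  reproducible and any subset of the code remains valid.
* Degenerate (IUPAC) bases are allowed in primers only, never in
  references.
* Melting temperatures in `check_primer_pair()` use unified
  nearest-neighbor parameters with a salt correction and are advisory
  only; the dimer screen is string-complementarity (longest complementary
  run), not a thermodynamic model.
* Empty inputs degrade gracefully: empty read sets give empty tibbles,
  a fully low-quality read trims to an empty read, coverage of an unmapped
  amplicon is 0, and an all-constant frequency table yields a single
  variability group rather than an ANOVA error; zero residual variance
  with unequal means is reported as "ANOVA undefined".

## Known discrepancies and limitations

* Published per-sample SNC totals can be counted per amplicon or per AMP;
  overlapping amplicons double-count shared positions in the former. The
  summary table reports both (`snc_total` as the per-AMP union,
  `snc_total_by_amplicon` as the raw sum), which likely explains why one
  published grand total (292 for the Vi sample) exceeds the column sum of
  per-AMP counts (264).
* The bundled `demo_panel()` is synthetic: sequences were generated once
  with a fixed seed under the real panel's structural constraints
  (13 amplicons, 9 AMPs, two overlapping amplicons for the longer cds,
  ≤ 440 bp, Table-style region layouts and cysteine arrays). Real
  reference coordinates are user-supplied through `load_panel()`.
* Peptide properties (`peptide_properties()`) are computed on reduced
  chains with documented, configurable conventions (average residue
  masses; EMBOSS or Bjellqvist pKa sets; hydrophobic set
  {A,C,F,I,L,M,V,W}); published peptide-property tables rarely state their
  exact conventions, so digit-for-digit agreement is not asserted.
* ω is a raw count ratio; no substitution-opportunity normalization, no
  phasing of SNCs into haplotypes (read clusters serve that role).

## Problem sizes used by the test suite

The suite exercises the pipeline at deliberately desk-friendly sizes: unit
fixtures of a few hundred reads on a 120-bp designed amplicon;
calibration checks at 1,200–2,500 simulated reads; and the
parameter-recovery check on three demo amplicons at ≥ 500× mean coverage
(≈ 2,900 reads) with planted alleles at 5–30% frequency, where genuine-SNC
calling at 30×/3%/q20/q15 must reach recall and precision ≥ 0.95. Oracle
equivalence checks (translation, trimming, alignment scores, barcode
packing, mean/SD) run on hundreds of randomized small instances against
independent brute-force implementations.
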