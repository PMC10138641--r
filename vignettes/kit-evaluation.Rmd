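---
title: "Evaluating exome capture kits against clinical quality standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating exome capture kits against clinical quality standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kiteval)
```

## The problem

A diagnostic laboratory replacing gene-panel sequencing with whole-exome
sequencing has to show that the new assay is at least as reliable as the old
one. kiteval structures that demonstration as four steps: a theoretical
comparison of the candidate capture designs; run-level sequencing quality
checks; sample-level quality metrics with acceptability thresholds; and a
clinical validation that asks how much sequencing each kit needs before a
diagnostic gene panel — or the OMIM morbid-gene set — is adequately covered.
The end product is a kit-comparison matrix plus a verdict ledger per kit.

Everything user-facing takes and returns plain tibbles, so the pieces
compose with ordinary dplyr pipelines.

## Conventions

All interval sets (capture designs, panels, annotation features) use BED
coordinates: 0-based, half-open, sorted, merged. SAM/BAM positions are
1-based and are converted once, at ingestion, in `read_alignments()`.
Secondary and supplementary alignments are loaded but excluded from every
metric. Soft-clipped bases and deletion gaps never count as sequenced bases.

## The metrics

**Insert size.** Median/mean of template length over proper pairs, each
template counted once. Templates above 2000 bp (configurable) are treated as
chimeric outliers so the median stays robust; short-read exome libraries are
expected around 200–250 bp. For 2×L reads of an insert I, mates overlap by
`max(0, 2L − I)` bases (`read_overlap()`): overlap wastes sequencing and
feeds the duplicate rate, which is why insert size is worth tracking even
without a hard bound.

**Duplicate rate.** `mark_duplicates()` groups pairs by the coordinate key
*(chrom, unclipped 5′ start, strand)* of both mates — the standard
coordinate criterion for PCR duplicates — and keeps, per group, the pair
with the highest summed base quality (ties: first encountered, so output is
deterministic for identical input). Unpaired reads fall back to single-end
keys. The rate is flagged reads over mapped reads. No optical-duplicate
subclassification is attempted: the synthetic fixtures carry no flowcell
geometry, and the clinical thresholds are on the total rate.

**On-target rate.** Aligned bases inside the target over all aligned bases,
duplicates included — the quantity describes the capture chemistry, which
acts before amplification is visible. No near-target padding is added by
default; a `padding` argument exists because some laboratories count
near-bait bases.

**Depth of coverage.** Per-base pileup over every target base, zeros
included, with or without duplicate-flagged reads. The conservation identity
`sum(depth) = sum(per-read on-target aligned bases)` is tested against a
brute-force pileup oracle.

**Coverage rate at nX.** Fraction of target bases with depth ≥ n. The
"at least n" reading (rather than strictly above n) matches the way
minimal sequencing efforts are quoted — a kit whose 30X rate is exactly
90% is considered to have reached "90% at 30X" — and is applied
consistently in `coverage_rate()`, `minimal_effort()` and the threshold
engine.

**Uniformity.** Two summaries of the same per-base distribution:

* *Fold-80 base penalty* = mean depth / P20, where P20 is the depth at
  ascending rank `ceiling(0.2 N)` over all N target bases, zeros included.
  It reads as "how much extra sequencing would bring the worst-covered 20%
  of the target up to the current mean"; 1 is perfect uniformity. When
  P20 = 0 the statistic is undefined and `fold80()` returns `NA` with a
  warning instead of an infinity, since a fifth of the target is simply
  not covered at any scaling.
* *Evenness score* in percent. The default is the truncated-mean form
  `E = 100 · Σ min(d_b, C) / (C·N)` with C the mean depth: coverage above
  the mean earns no credit, so piling reads onto already-covered bases
  lowers the score. The literature also carries a discrete variant that
  averages the fraction of bases covered at each integer depth up to
  `round(C)`; both are implemented (`method = "discrete"`) and agree at
  uniformity, where both give exactly 100. The truncated form is the
  default because it is continuous in the depths and needs no rounding
  convention.

Both metrics are invariant to multiplying all depths by a constant, which
the tests check, and `fold80 = 1 ⇔ evenness = 100 ⇔ constant profile`.

**Ts/Tv ratio.** Transitions (A↔G, C↔T) over transversions among biallelic
SNVs; multiallelic SNV records are decomposed per alt allele, indels and
MNVs ignored, filter-failed records excluded by default. Random
substitution gives 0.5 (4 of the 12 ordered changes are transitions), real
variant sets sit near 2 genome-wide and a little above 3 in coding
sequence, so a collapse toward 0.5 signals false-positive calls. An
optional region restriction supports the CDS-versus-genome contrast; both
restricted and unrestricted values are worth reporting since published kit
tables rarely say which one they used.

## Thresholds and boundary semantics

`threshold_config()` carries the default acceptability rules: duplicate
rate under 20%, on-target above 80%, mean coverage at least 100X, at least
90% of target bases at 30X, Ts/Tv above 2.4; run level, %PF ≥ 65%,
Q30 ≥ 80%, PhiX strictly above 0.3% (with ~1% the informal aim) and cluster
density inside the instrument's band (`instrument_density_table()`).
Operators follow how such rules are conventionally printed: "under" and ">"
strict, bare percentages and "at least" inclusive. Three metrics are
advisory rather than pass/fail — insert size (an expectation, not a bound)
and the two uniformity scores (whose acceptable values depend on the
calculation method) — so a complete evaluation always covers four run
parameters and seven sample parameters, with advisory rows marked `NA`.

Two tensions are deliberately preserved rather than smoothed over. First,
the conventional on-target bound (>80%) is above what current whole-exome
captures typically achieve (low 70s); `evaluate_sample()` records the fail
and attaches the context note instead of hiding the rule or the result.
Second, the 100X depth rule does not say whether it applies before or after
deduplication; it is applied to the duplicate-inclusive mean here (the
quantity the sequencing run actually delivers), and both means are always
reported side by side.

## Downsampling and effort curves

Coverage efficiency is measured by downsampling whole read pairs (mates are
never separated) to a ladder of efforts, re-marking duplicates within each
subsample, and tabulating coverage rates at 15/30/50/100X. Sampling is
seeded and, by default, *nested*: one permutation is drawn and each effort
takes a prefix, so every smaller subsample is contained in every larger one
and the curves are non-decreasing in effort by construction rather than up
to noise. An independent-per-effort mode (`nested = FALSE`) mimics
independent FASTQ downsampling. Efforts are counted in read pairs;
published "M reads" labels can be attached verbatim via `effort_labels`.
`minimal_effort()` then answers the operational question — the smallest
tabulated effort whose rate at a given depth meets a requirement — and
works equally on grids computed from alignments or typed in from a
published table (`effort_grid()`). `panel_coverage_report()` is the same
pipeline with depth restricted to a panel built by `build_panel_bed()`,
which pads every exon of the requested genes by 25 bp (default) to keep
canonical splice sites, clamps at position 0, and reports unresolvable
symbols instead of dropping them silently.

## Design comparison

`multi_intersect()` tabulates, for 2–4 designs, the bases covered by each
exact subset of designs (the `multiIntersectBed` view); the subset counts
sum to the union size by construction, and a per-base boolean-array oracle
checks them exactly in the tests. `partition_design()` assigns every
targeted base to coding, UTR, intron or intergenic with the fixed
precedence CDS > UTR > intron across overlapping transcripts, so category
totals are disjoint and sum to the design size; UTR means exonic-not-CDS.
All transcripts of a gene contribute by default — the choice of a canonical
transcript per gene is a configuration (`transcripts =`) rather than a
hard-coded policy, because annotation releases disagree on canonical
choices and the partition should be reproducible from stated inputs.

## The synthetic-data generator

`simulate_experiment()` emulates the quantities the metrics measure, not
the physics that produces them. Fragments of Normal(mean, sd) length
(truncated at ±4 sd and to positive sizes) are placed fully inside a design
interval with probability `1 − off_target_fraction`, interval choice
weighted by length times a gamma multiplier with shape `k` (mean 1):
`k = Inf` gives uniform capture weights, small `k` concentrates coverage
and drives fold-80 up and evenness down smoothly. Off-target fragments land
entirely in inter-target gaps, so the injected on-target fraction is
recovered exactly at the base level. Duplicates re-emit an already placed
fragment at identical coordinates with fresh qualities —
`duplicate_fraction` is the fraction of final pairs that are duplicates, so
the marker should recover it up to rare coordinate collisions between
independent fragments. Base qualities are a two-level mixture (Q35 with
probability `q30_target`, else Q20), which keeps records compact, makes the
Q30 fraction exactly recoverable, and lets SAM/FASTQ writing regenerate
byte-identical files. Variants are drawn at distinct positions with
transition probability `t/(1+t)`.

What the generator does *not* emulate — and what passing recovery tests
therefore do not show about real data: sequencing errors and indels, GC and
probe-affinity bias, optical duplicates, clipped or split alignments
(clipping is exercised by hand-built records in the unit tests), real
quality-score profiles, and real sequence content (reads are written as
poly-A over a coordinate-only toy genome). One real-data feature appears as
an honest artefact: because fragments sit fully inside their interval,
coverage ramps down over roughly a read length at interval edges, so even
`k = Inf` does not reach fold-80 = 1 — the exact uniform limit is checked
on constructed profiles instead.

Defaults mirror the study conditions the package is calibrated against:
2×150 bp pairs, inserts 206 ± 30 bp, 12% duplicates, 26% off-target, 90%
Q30, 20 000 SNVs at Ts/Tv 2.7. The default toy genome (two 150 kb
chromosomes, ~30% under the design) keeps a 50 000-pair experiment — the
scale used for parameter-recovery tests — in the tens-of-megabase-pair
range, which runs in seconds while leaving per-base coverage deep enough
(~100X) for stable uniformity statistics. Oracle-equivalence tests run on
≤ 10 kb genomes where per-base boolean arrays are cheap; 40 seeded trials
per operation.

## Numerical and degenerate-input choices

* `merge_intervals()` fuses abutting intervals; malformed intervals
  (end ≤ start, negative start) are rejected with row numbers.
* Empty target, empty profile, zero mapped bases, no proper pairs, no
  transversions, P20 = 0 and all-zero profiles each produce a specific
  error or flagged `NA`, never a silent 0, `Inf` or `NaN`.
* Report rendering fixes ordering and float formatting so regeneration
  from identical inputs is byte-identical.
* `downsample_pairs()` errors (with counts) when asked for more pairs than
  exist; requesting all pairs is the identity.

## Limitations

kiteval consumes aligned reads and called variants; mapping and calling
quality are upstream concerns it can only reflect, not diagnose. The
duplicate marker is coordinate-based and will call natural coincident
fragments duplicates at very high depth. Visual review of repeat-region
coverage (e.g. the repeated exon blocks of *TTN* and *NEB*) is part of the
clinical workflow this package supports but stays in a genome browser;
kiteval quantifies, it does not inspect. No liftover is attempted: all
inputs must share one assembly. Cost, storage and incidental-findings
policy are out of scope.
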