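---
title: "Methods: hDNA tract calling, mechanism classification and efficiency decomposition in gap-repair assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gap-repair hDNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaphdna)
```

## The model

A gapped plasmid is repaired off a diverged chromosomal donor. Because the
assay runs in a mismatch-repair-deficient background, heteroduplex DNA
(hDNA) formed during repair retains its mismatches, which segregate at the
next replication and show up as double peaks (`H` codes) at individual SNPs
when both alleles of a recombinant are Sanger-sequenced. `gaphdna` takes the
per-SNP genotype codes as its input abstraction — translating chromatograms
to codes is upstream of the package — and everything downstream is
deterministic arithmetic and counting:

1. **Tract calling.** On each allele, a tract is a maximal contiguous run of
   `H` codes; runs are split at the gap by construction, so every tract lies
   on one side. A `D` (fully converted) SNP between two `H` runs does *not*
   merge them — conversion may reflect tract-internal repair the assay
   cannot resolve, so merging would assert structure the data do not show.
   Classification, however, only consumes per-side presence/absence of hDNA,
   so tract multiplicity affects rendering but never class assignment.

2. **Classification.** Each NCO event reduces to five booleans (plasmid hDNA
   left/right, donor hDNA left/right, any conversion) and maps to exactly
   one class: unidirectional (plasmid one side only — the SDSA prediction),
   bidirectional (plasmid both sides — dissolution), cleavage pattern
   (plasmid one side, donor the opposite side), conversion-only,
   no-transfer, or ambiguous. Ambiguous is a *reported* class, not an error:
   real data contain patterns outside the predictions (e.g. donor-only
   hDNA, or donor hDNA on the same side as plasmid hDNA), and dropping them
   silently would bias proportions invisibly. Conversion accompanying hDNA
   does not change the class: events are categorized by `H` presence only.

3. **Efficiency decomposition.** Repair efficiency is the mean His⁺:Leu⁺
   ratio normalized to the reference-strain mean *of the same plasmid mix*
   (two mixes with different absolute ratios were used; normalization is a
   mix-keyed map, then values are pooled). CO/NCO efficiencies are the
   repair efficiency times the stability-scored proportions;
   unidirectional/bidirectional efficiencies are the NCO efficiency times
   the class proportions among hDNA-detected events. The denominators of the
   class proportions include hDNA-bearing events of neither class (a
   cleavage-pattern event counts in the denominator while being reported
   separately) — that is the only reading consistent with the published
   `36/47` and `10/47` cells, whose denominator is 36 + 10 + 1.

## Numerical choices

- All chained computations use full-precision intermediates; rounding
  (half-even, 2 decimals for efficiencies, whole percent for proportions)
  happens only in `round_report()`. The published tables chained unrounded
  intermediates that are not printed, so recomputing from printed inputs can
  differ by one unit in the last place (e.g. a unidirectional efficiency of
  0.19 printed where printed inputs give 0.18). Reproduction checks
  therefore use a ±0.01 tolerance; exact equality is asserted only for the
  conservation identities (`co + nco = repair`, `uni + bi = nco` when no
  other hDNA class is present), which hold to 1e-12 by construction.
- Degenerate statistics: two constant, equal samples give *t*-test p = 1
  (no evidence of difference); constant but unequal give p = 0. An all-zero
  2×2 table is an error.
- The Fisher test is two-sided by the point-probability rule (sum of table
  probabilities ≤ the observed one, with a 1e-7 relative tolerance against
  floating ties). Two-sided conventions differ between tools; this one
  matches `stats::fisher.test` and common 2×2 calculators, and the test
  suite pins it to an exhaustive `choose()`-based enumeration.
- The *t*-test is pooled-variance Student's by default (the analysis this
  package mirrors used a Student's-t calculator); Welch is available behind
  `welch = TRUE`. Per-strain class comparisons multiply each strain's
  normalized ratios by that strain's own fixed class proportion — the only
  reading consistent with "a distribution of CO-type ratios".

## The substrate map

Only side membership and ordering of SNPs matter to the analysis, so the
default 800-bp map anchors what is physically stated — a central 8-bp gap at
positions 397–404 and nearest SNPs 18 bp from each edge (379 and 422) — and
distributes the remaining SNPs deterministically and approximately evenly
(9 left / 10 right; the true left/right split is unpublished, so the split
is a documented default). Orientation (which published figure side is LEFT)
is arbitrary but fixed. Maps are fully configurable via a JSON config
(`read_snp_map()` / `write_snp_map()`), and `validate_map()` enforces the
invariants (sorted positions, nothing inside the gap).

## What the simulator emulates — and what it does not

`simulate_cohort()` draws mechanisms i.i.d. from configurable weights
(default 89% SDSA / 11% dissolution, the reference-strain pattern) and
places hDNA by each mechanism's predicted topology. Tunable parameters:

- `tract_mean` (bp, default 150): mean of a geometric tract-length model
  measured beyond the gap edge, drawn independently per involved side. No
  tract-length distribution is published; a monotone-decreasing family
  qualitatively matches the observed spread of tract extents, and the
  default mean makes roughly `1 - (1 - 1/151)^18 ≈ 11%` of single tracts
  miss the nearest SNP, a realistic undetected fraction. The choice is
  configurable precisely so that no biological claim is embedded.
- `tract_min` (bp, default 0): a floor on drawn lengths. Setting it ≥ 18
  guarantees detectability, which is how the recovery tests make
  classification exact.
- `mmr_repair_prob` (default 0): per-mismatch chance that residual mismatch
  repair erases an `H` call; nonzero values support sensitivity
  experiments, the default models the MMR-deficient background.
- `transformation_sim_params()`: Leu⁺ counts Poisson around `leu_mean`
  (zeros redrawn); each culture's realised repair efficiency is gamma-mixed
  with variance `dispersion`, and His⁺ counts are Poisson around efficiency
  × Leu⁺. This yields overdispersed His⁺:Leu⁺ ratios centred on the true
  efficiency; `dispersion = 0` recovers the Poisson sampling floor.

Deliberate simplifications: dissolution and two independent SDSA reactions
are generated as distinct truth labels but identical observables
(bidirectional plasmid hDNA, clean donor) — the assay cannot distinguish
them and neither does the classifier; crossover events carry no simulated
sequence (an NCO-only sequencing design); chromatogram noise, chimeras and
replication dynamics are not modelled. A green recovery test therefore
establishes that the calling/classification/tabulation arithmetic is
faithful to the generative assumptions, *not* that those assumptions hold
for any particular real dataset.

## Known limitations

- Mixed `H`/`D` patterns on one side are categorized by `H` presence alone;
  how borderline patterns were hand-curated in the original tabulations is
  not recoverable from the publication.
- Printed p-values are not reproduction targets: the per-transformation
  ratio distributions behind them were never published, so the statistical
  stage is validated by calibration (type-I error) and oracle equality
  instead.
- The geometric tract model is a stated default, not an inference; nothing
  in the package estimates tract-length parameters from data.
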