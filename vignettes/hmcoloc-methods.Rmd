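---
title: "hmcoloc: methods, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hmcoloc: methods, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcoloc)
```

# The analysis in one paragraph

`hmcoloc` asks a layered question of a two-condition (wild type vs
knockout) epigenomic study: do the genes that become upregulated in the
knockout also gain an epigenetic mark (5hmC) along their bodies and
promoters, and does a transcription factor accumulate on the promoters of
exactly those genes? The pipeline partitions a differential-expression
table, profiles the mark over the gene sets (metagene curves), classifies
each upregulated gene by the knockout/wild-type ratio of its per-gene
density with an exact binomial test of the resulting split, repeats the
classification for promoter TF binding on the subset that gained the mark,
and tests peak-level co-localization of the TF against the mark with a
genome-coverage binomial null. A synthetic-data generator with planted
structure closes the loop: it provides datasets where the right answer is
known, so the whole chain can be scored for recovery.

# Coordinates, tags and densities

All coordinates are 0-based half-open (BED native); an interval
`[start, end)` covers `end - start` bases. Strand enters only through gene
models: the TSS of a `+` gene is `tx_start`, of a `-` gene `tx_end - 1`,
and "upstream" always means 5′ of the TSS in transcript orientation.

A mapped read ("tag") is assigned to at most one position — its midpoint,
`floor((start + end) / 2)` — so a tag is counted exactly once per region
and never double-counted at bin or region boundaries. The choice of
`floor` is a tie-break: for even-length tags it sits half a base left of
the geometric centre, which is why exact mirror-image invariance (tested in
the suite) holds for odd tag lengths, while for even lengths reflected
midpoints shift by one base. Nothing downstream is sensitive to this
beyond that one-base effect.

Densities are reads per million mapped, `RPM = count * 1e6 /
library_size`, optionally per kb of region (`RPKM`). The library size is an
explicit field of a tag set rather than the tag count, so filtered tag
files remain correctly normalized; it defaults to the tag count on
reading. Whether per-gene intragenic levels are length-normalized is
immaterial for the classification: the knockout/wild-type ratio of the same
gene's region cancels the length either way.

# Anchored regions

Region definitions follow the conventions of the motivating study:

| region | definition | default use |
|---|---|---|
| promoter | `u` bp upstream + `d` bp downstream of the TSS (width `u + d`; the TSS base belongs to the downstream part) | 1 kb each side for the TF-binding classification; 500 bp each side for cohort matrices |
| gene body | TSS + offset → TES | offset 500 bp |
| intragenic | TSS → TES (whole transcription unit) | the 5hmC ratio classification |
| flanks | fixed-width windows outside the transcription unit | 5 kb metagene flanks |

Regions are clipped at zero and at the chromosome end when a chromosome-
sizes table is supplied. Genes whose body would be empty after the TSS
offset (or whose region is clipped away entirely) are excluded from the
affected analysis with a logged count — they are not silently dropped.

# Metagene profiles

Each gene contributes `2 * 50` flank bins (100 bp each over 5 kb) and 100
body bins (each `L/100` bp for a gene of length `L`). Per-gene bin values
are RPM divided by the bin width in kb, which puts the fixed-width flank
bins and the variable-width body bins on one axis: under a homogeneous tag
distribution every bin has the same expectation (`1e9 / G` RPM/kb for a
genome of `G` bases when the library equals the tag count), a property the
test suite checks against the analytic value. Minus-strand genes are
reversed so bin order runs 5′→3′; genes shorter than the number of body
bins (100 bp) are excluded with a diagnostic. The non-enriched input track
is profiled alongside the enriched samples, not subtracted from them.

# The statistical layer

**DE partition.** A gene is significant iff its p-value (or q-value,
selectable) is *strictly* below `alpha = 0.05`; the sign of the log2 fold
change gives the direction and exact zeros are excluded.

**Binomial tests.** Exact tails from the binomial distribution. The
two-sided p-value doubles the smaller tail and caps at 1. This is a
deliberate, documented convention — the minimum-likelihood two-sided
convention of `stats::binom.test` differs for asymmetric nulls; at
p₀ = 0.5 (the classification null) the two agree. One-sided tails agree
with `binom.test` exactly, which the tests use as a cross-check.

**Ratio classification.** `higher` iff `rpm_KO > rpm_WT + epsilon` with
`epsilon = 0` by default (exact equality is a tie); ties are excluded from
the binomial denominator and logged. The test is two-sided against
p₀ = 0.5: the claim being tested is "the split is uneven", not a
pre-specified direction. Swapping the conditions maps k to n−k and leaves
the p-value unchanged (antisymmetry, tested).

**Proximity co-localization.** A query peak is a hit iff some subject peak
on the same chromosome overlaps it or lies within 500 bp edge-to-edge
(inclusive; overlap and touching count as distance 0). The null proportion
is the fraction of the genome within 500 bp of the subject set — the hit
probability of a uniformly placed point — and the test is one-sided
(greater), matching the direction of the enrichment claim. This null is an
explicit modelling choice, declared in the run report; it treats query
peaks as points, an approximation that is excellent when peaks are narrow
relative to the window. The suite calibrates the test by Monte-Carlo
resampling: with point queries the type-I error at α = 0.05 sits at the
analytic value ≈ 0.05 (the test is exact but discrete).

**Cohort comparisons.** Welch's unequal-variance t-test on the per-gene
log₂(RPM + 1) values of two matrix columns, two-sided. Welch rather than
pooled-variance Student is the robust default for "unpaired t-test"; at
the sample sizes involved the difference is immaterial. Two constant
columns with equal means report t = 0, p = 1 by convention.

**Percentages.** `fraction_summary` rounds half away from zero, so
310/439 prints as 70.6 (banker's rounding would also give 70.6 here, but
the convention matters at exact halves: 1/8 prints as 13%, not 12%).

**Over-representation.** Upper-tail hypergeometric per gene set (sets are
intersected with the universe first), Benjamini–Hochberg across sets via
`stats::p.adjust`.

**log2 pseudocount.** Matrices use `log2(rpm + 1)`: bounded at 0 for empty
regions, and 1 RPM is a natural unit for promoter-scale windows at typical
depths.

# The synthetic-data generator

`simulate_dataset` emulates the structure of the motivating study's
deposited data: two conditions × two enriched marks of tag and peak data
plus an input track over shared gene models, a DE table, and a truth
record. Its defaults *are* the study conditions used by the acceptance
checks, chosen once:

* **Geometry.** 4 chromosomes × 5 Mb, 2000 non-overlapping genes with
  lognormal lengths (median 3 kb), placed by broken-stick gap sampling
  with 6 kb chromosome-end margins so promoters and flanks stay
  on-chromosome. Non-overlap keeps per-gene attribution unambiguous;
  overlapping-gene disambiguation is out of scope, as in the analysis
  itself.
* **Intensity model.** Tags are drawn from an inhomogeneous Poisson
  process with a piecewise-constant intensity: `background_rate` (default
  1) outside planted regions and the product of planted fold factors
  inside them, rescaled so the expected total equals `library_size`
  (default 5 × 10⁵). Setting `background_rate = 0` therefore confines tags
  to planted regions. The drawn position is the tag midpoint; the read
  interval (50 bp) is built around it, so midpoint counting recovers the
  sampled process exactly.
* **Planted structure.** Every gene body carries ×4 5hmC enrichment and
  every promoter (±1 kb of the TSS) ×4 TF enrichment in both conditions —
  typical ChIP/hMe-Seal enrichment over input. 25% of genes are planted
  upregulated and 25% downregulated, with p-values drawn below the 0.05
  threshold (null genes uniform) so the DE partition is exact by
  construction; the DE table is generated, not estimated, because DE
  estimation is out of scope. Among the upregulated genes, a fraction
  `frac_co = 0.25` is co-regulated: one contiguous promoter-plus-body span
  gains ×3 5hmC and the promoter gains ×3 TF in the knockout.
  `frac_co = 0.25` is derived analytically from the motivating study's
  printed fractions: if a fraction `f` of upregulated genes carries a real
  5hmC gain and the rest split evenly, the expected higher-5hmC fraction
  is `f + (1-f)/2` ≈ 62% and the expected higher-TF fraction among those
  is `(f + (1-f)/4) / (f + (1-f)/2)` ≈ 70% — both printed values are
  matched at `f = 0.25`.
  Downregulated genes lose body 5hmC (×0.5) in the knockout.
* **Peaks.** Truth intervals whose intensity multiple over background is
  strictly above `peak_rate_threshold = 2` are emitted as that sample's
  peaks. Peak calling is out of scope, so the simulator supplies what a
  peak caller would have: at the defaults, every gene body is a 5hmC peak
  in both conditions except downregulated bodies in the knockout, which
  fall to exactly the threshold and drop out.
* **Determinism.** All randomness flows from one seed through R's default
  generator in a fixed sampling order; the same configuration yields
  byte-identical files, and the seed is written into the truth JSON.

**What the simulator does not model.** Fragment-size and GC effects,
mappability, replicate-level variance, read sequences, and — importantly —
biological effect-size variation: planted folds are constant across co-
regulated genes. Passing recovery tests therefore demonstrates that the
chain of interval arithmetic, normalization and testing is correct and
well-calibrated, not that the thresholds would behave identically on real
data.

**A property worth knowing: composition bias.** RPM normalization divides
by the total library, so planting extra enrichment in the knockout
dilutes the relative share of every unchanged region; unchanged genes then
drift slightly below a 50/50 knockout/wild-type split. At the default
configuration the co-regulated gains and downregulated losses roughly
balance and the up-gene fraction lands near its naive expectation, but the
promoter TF comparison (gains only) shows the effect: the recovered
higher-TF fraction among higher-5hmC genes sits below the naive 70%
prediction. This is a faithful property of RPM-based ratio classification
— the motivating study's numbers carry it too — not an artifact of the
generator. The null-calibration checks disable all planted 5hmC effects
(`frac_co = 0`, `down_hmc_fold = 1`) precisely so that the null really is
null.

# Problem sizes used by the test suite

Unit tests run on toy chromosomes (≤ 100 kb masks, ≤ 500 intervals, 20
seeds for the oracle-equivalence sweeps) where brute-force per-base and
all-pairs oracles are exact and fast. Calibration and recovery checks use
the full default study conditions (2000 genes, 5 × 10⁵ tags per sample);
the Monte-Carlo proximity calibration uses 1000 replicates of 300 point
queries against a fixed subject set whose analytic rejection rate is
0.050. The end-to-end smoke tests use a scaled-down configuration
(200 genes, 8 × 10⁴ tags) where classification power is limited — those
tests assert structure and composition, leaving significance claims to the
full-scale runs.

# Known limitations

* The proximity null treats queries as points; for queries wide relative
  to the window the reported p-value is anticonservative. A width-aware
  null would integrate the query length into the coverage computation.
* Ratio classification ignores count magnitude: a gene with 1 vs 2 reads
  and one with 100 vs 200 reads contribute equally. The binomial test on
  the split inherits this; the per-gene tables carry the raw values so
  users can filter.
* RPM composition bias (above) is not corrected; a median-of-ratios size
  factor would reduce it but would depart from the reads-per-million
  convention the analysis mirrors.
* Overlapping genes are treated independently; tags in shared regions
  count toward every overlapping gene's regions.
* The GO step is replaced by a generic hypergeometric over-representation
  test on user-supplied gene sets; no term hierarchy handling.
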