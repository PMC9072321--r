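---
title: "Models and methods behind tilefate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tilefate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilefate)
```

## The assay and the quantities estimated

tilefate analyses massively parallel reporter RNA experiments in which short
sequence tiles (typically 110 or 140 nt) are inserted into a linear or
circular reporter backbone, the pool is transfected, and amplicon sequencing
of fractionated RNA reads out how each tile shifts the reporter's subcellular
localization, expression, and stability. The package covers five analysis
stages plus a synthetic-data generator with known ground truth:

1. **Read-to-tile matching** — each R1 read is `[UMI][adapter][insert]`;
   the insert is assigned to a library tile under quality- and
   mismatch-constrained gapless comparison.
2. **Localization statistics** — normalized log2(Nuc/Cyto) ratios per tile
   with per-tile significance and a joint effect-size/alpha classification.
3. **Stability** — spike-in normalized, log-linear decay fits over a
   transcription-shutoff time course, with half-lives from the fitted line.
4. **circRNA quantification** — back-splice junction records matched to
   annotated circle boundaries with a coordinate tolerance, then filtered
   and ratioed between compartments.
5. **Annotation** — RBP motif counts, filtered eCLIP-cluster overlaps, G/C
   content, optional folding energy, and stratified group comparisons.

## Read matching model

A read is used only if it contains the exact amplicon adapter
(`TAGGAGGCCTCATCTGACTG` by default) preceded by a complete UMI. The insert —
everything after the adapter — is compared gaplessly to each tile from tile
position 0 over the overlap of the two lengths. Indels are not modeled:
the amplicons are fixed-layout PCR products, so a gapless comparison is both
faster and closer to the error process (substitutions dominate on this
platform). Three rules gate a candidate tile:

* a mismatch is only tolerated where the read's Phred quality is at least
  `quality_min` (default 35) — low-quality disagreements are treated as
  sequencing error, not evidence;
* at most `max_seed_mm = 2` mismatches in the first `seed_length = 15`
  compared bases;
* at most `max_total_mm = 4` mismatches overall.

Among valid candidates the unique minimum-mismatch tile wins; ties are
discarded as ambiguous rather than arbitrarily resolved. The four outcome
classes (matched, no adapter, unmatched, ambiguous) partition every input
read, which the tests assert as a conservation property.

Two choices here were genuinely open:

* **UMI handling.** UMIs exist to collapse amplification duplicates, so the
  default `count_mode = "umi"` counts distinct UMIs per tile per sample;
  `count_mode = "read"` reproduces plain read counting. The UMI length is a
  library-prep parameter, configurable with a 10-nt default.
* **Adapter stringency.** The adapter is matched exactly at its first
  occurrence: it is a constant primer-derived sequence, and tolerating
  mismatches there would mostly admit reads whose layout is already suspect.

The matcher core is compiled (Rcpp) with an exact-match fast path and early
termination once a candidate exceeds the running mismatch bound; an R-level
`score_candidate()` keeps the reference semantics, and the tests hold the
two equal against an independent brute-force scorer.

## Localization statistics

Counts are normalized per sample to counts per million so that each
fraction's sequencing depth cancels. A pseudocount of 0.5 is added to the
**raw** counts before normalization — a count-scale pseudocount would be
meaningless after scaling — and per-replicate ratios are

\[ r_{t} = \log_2 \frac{\mathrm{CPM}(n_t + 0.5)}{\mathrm{CPM}(c_t + 0.5)} \]

for nuclear count \(n_t\) and cytoplasmic count \(c_t\) of tile \(t\). A tile
enters a replicate's ratios only with at least `min_reads = 20` raw reads in
*both* members of the pair; requiring both sides is the stricter reading of
the per-sample filter and avoids ratios dominated by the pseudocount.

Per tile, replicates are summarized by their median, and a two-sided
one-sample t-test of the replicate ratios against 0 supplies the P-value
(the replicate-level test is not named in the assay's description; the
t-test is the simplest test consistent with per-tile P-values at n = 3, and
`test = "wilcoxon"` is available). Classification is joint: cytoplasmic if
median < −0.3 and P < 0.05, nuclear if median > +0.3 and P < 0.05,
otherwise unclassified. The ±0.3 log2 threshold corresponds to roughly a
25% abundance difference. No multiple-testing correction enters the calls —
the effect-size threshold does that work — but a BH-adjusted column is
emitted for reference.

Because CPM normalization removes any shift common to all tiles, a uniform
true shift is unidentifiable by design; what the method measures (and what
the recovery tests check) is each tile's shift relative to the library
average. Group contrasts (G/C strata, motif strata) use the two-sided
Wilcoxon rank-sum test, exact for groups of at most 10 without ties and the
tie-corrected normal approximation otherwise.

## Stability model

During transcription shutoff, tile levels are first normalized to the summed
counts of spike-in RNAs added at fixed amounts per sample (two species at a
10:1 ratio in the generator, mirroring common practice); this cancels
per-sample recovery and depth. Levels are then expressed relative to the
geometric mean of the t = 0 samples and fitted by ordinary least squares on
the log2 scale:

\[ \log_2 \frac{L(t)}{L(0)} = a + bt, \qquad
   t_{1/2} = \frac{\log_2(0.5) - a}{b} . \]

Base 2 makes the slope interpretable as halvings per hour and the formula's
numerator −1; the t = 0 normalization makes the intercept ≈ 0 and the
half-life equal to the time to reach 50% of the initial level. Both choices
are exposed (`base`, `t0_normalize`) since the literal formula can also be
applied to unnormalized levels. Non-positive levels are dropped with a
warning; fits with a non-negative slope report an undefined half-life rather
than a negative time. Noiseless simulated series round-trip the input
half-lives to below 1e-9 relative error, and with 10% lognormal noise and
three replicates the per-tier median stays within 20% of truth.

## circRNA junction quantification

Junction records come in the tab-separated chimeric-alignment dialect
(1-based donor/acceptor positions); annotations are BED-style 0-based
half-open spans with exon count and mature length. Conversion between the
conventions happens once, in the parser/assigner. A record supports a
circle when its two coordinates are each within `tolerance = 5` nt of the
annotated back-splice boundaries on the same chromosome and strand (records
with strand "." match either; both boundary orientations are accepted so
the caller need not know the aligner's donor/acceptor polarity). When a
record is within tolerance of several circles it goes to the smallest
summed boundary distance; exact ties are counted for every tied circle and
flagged rather than silently double-counted. Filters keep circles with at
least 10 read pairs in at least one sample, at most 5 exons, and at most
5 kb mature length; compartment ratios reuse the pseudocount/CPM convention
of the tile ratios.

## Annotation

Motifs are configuration inputs — IUPAC consensus strings or 4×L position
weight matrices with a log2-odds threshold — because the assay's motif sets
are themselves derived objects, not constants of the method. Scanning is
left-to-right and non-overlapping by default (the scan restarts after each
match end); stratification uses small integer bins (0 / 1 / >1 motifs), which
are insensitive to the overlap policy, and an overlapping mode exists.
eCLIP clusters are filtered to P < 0.01 and at least 2-fold enrichment over
the input control before strand-aware, half-open interval intersection
(implemented on GenomicRanges; verified against an all-pairs oracle).
Folding energy is a thin wrapper over the external `RNAfold` binary and
degrades to an absent column when the program is missing.

## The synthetic-data generator

The generator produces every pipeline input with known ground truth:

* **Libraries** — uniform-random tiles with per-tile G/C targets drawn from
  a feasible range; an infeasible range errors rather than clipping.
* **Reads** — `[UMI][adapter][insert]` with uniform substitution errors
  (default 0.5%), an optional indel rate for robustness checks, and Phred
  qualities from a truncated normal, 37 ± 4 on [2, 41] — deliberately
  straddling the Q35 rule so the quality gate is exercised. Per tile and
  sample, read counts are Poisson with expectation `depth` in cytoplasmic
  samples and `depth · 2^shift` in nuclear ones, so the expected count
  ratio equals the true fold change. UMIs are drawn uniformly, so
  collisions occur and deduplication is observable.
* **Decay series** — exact exponential decay times a per-sample scale
  factor carried by the spike-ins, with lognormal noise of a given CV.
* **Junctions** — records jittered around annotated boundaries
  (rounded-normal jitter, or a forced constant offset for boundary tests),
  Poisson counts around the requested abundance.

Everything is seeded and byte-reproducible. What the generator does *not*
emulate: position-dependent error profiles, PCR amplification bias beyond
UMI reuse, splicing or circularization efficiency, and partial-length
inserts. Passing the recovery tests therefore demonstrates correctness of
the estimators under the stated noise model, not robustness to every
artifact of real libraries.

## Problem sizes and defaults

Sequencing depth per tile is not a published constant of the assay, so the
generator's defaults were chosen once for statistical power: the
localization recovery experiment uses 300 tiles with true shifts
δ ∈ {−1, 0, +1}, three replicate pairs, 2,000 reads per tile per fraction
and a 0.5% error rate — enough that a |δ| = 1 tile is essentially always
detected while δ = 0 tiles stay below the false-call rate of the test.
Half-life recovery uses tiers {1, 2, 4, 8} h sampled at t = {0, 2, 4, 8} h,
matching the shutoff design the stability model targets. The demo pipeline
(`default_config()`) is smaller (60 tiles, depth 150) so an end-to-end run
takes seconds.

## Known limitations

* The matcher compares inserts from tile position 0 only; tiles sequenced
  with 5′ truncations would need an offset search.
* The per-tile t-test assumes approximately normal replicate ratios; at
  n = 3 it is a convention, not an inference guarantee.
* Junction assignment trusts the annotation set; unannotated circles are
  reported only as unmatched records.
* `fold_energy()` shells out to RNAfold; batch folding of large libraries
  is better done directly with the external tool.
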