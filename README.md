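# tilefate

Analysis toolkit for massively parallel reporter RNA assays (MPRNAs) that
measure how short sequence tiles change the subcellular localization and
stability of linear and circular reporter RNAs.

In these experiments a pooled library of designed tiles (110–140 nt) is
inserted into a reporter backbone, cells are fractionated into nuclear and
cytoplasmic RNA, and each fraction is read out by UMI-tagged amplicon
sequencing. tilefate turns those reads — and related inputs such as
chimeric-alignment junction records, eCLIP cluster intervals, and
transcription-shutoff time courses — into per-tile statistics, and ships a
synthetic-data generator that produces every input with known ground truth
so the whole pipeline can be validated end to end.

## What it computes

**Read-to-tile counting.** Each R1 read is `[UMI][adapter][insert]`. The
insert is compared gaplessly against every library tile; mismatches are
tolerated only at bases with Phred quality ≥ 35, with at most 2 mismatches
in the first 15 compared nt ("seed") and 4 overall. The unique
minimum-mismatch tile wins; ties are discarded as ambiguous. Counts are
distinct UMIs per tile per sample by default (raw-read mode available).

**Localization.** With nuclear count $n_t$ and cytoplasmic count $c_t$, the
per-replicate ratio is

$$ r_t = \log_2 \frac{\mathrm{CPM}(n_t + 0.5)}{\mathrm{CPM}(c_t + 0.5)} $$

for tiles with ≥ 20 raw reads in both samples of the pair. Tiles are called
cytoplasmic when the replicate median is < −0.3 with P < 0.05 (two-sided
one-sample test against 0), nuclear when > +0.3 with P < 0.05. WCE/input
expression ratios use the identical convention. Group contrasts use the
two-sided Wilcoxon rank-sum test (exact for small untied groups).

**Stability.** Counts are normalized to spike-in RNAs, expressed relative
to t = 0, and fitted by OLS on the log2 scale; the half-life is
$(\log_2 0.5 - a)/b$ for intercept $a$ and slope $b$.

**circRNA quantification.** Back-splice junction records support an
annotated circRNA when both coordinates fall within 5 nt of its boundaries
(same chromosome/strand); circles are kept with ≥ 10 read pairs in at least
one sample, ≤ 5 exons, and ≤ 5 kb mature length, then ratioed between
compartments.

**Annotation.** IUPAC/PWM motif counts, eCLIP clusters filtered to
P < 0.01 and ≥ 2-fold enrichment with strand-aware interval intersection,
G/C content, optional RNAfold minimum free energy, and stratified
comparisons of localization by annotation dose (0 / 1 / >1 motifs).

## Worked example

Simulate a 30-tile experiment in which ten tiles carry a true
log2(Nuc/Cyto) shift of −1, ten of 0 and ten of +1, with three replicate
fraction pairs at 500 reads per tile per fraction, then recover the calls:

```r
library(tilefate)

lib    <- generate_tile_library(n_tiles = 30, tile_length = 110,
                                gc_range = c(0.3, 0.7), seed = 42)
shifts <- setNames(rep(c(-1, 0, 1), each = 10), lib$tile_id)
design <- data.frame(sample_id = c("nuc_1", "cyt_1", "nuc_2", "cyt_2",
                                   "nuc_3", "cyt_3"),
                     fraction = rep(c("nuclear", "cytoplasmic"), 3))
sim    <- simulate_fragment_reads(lib, design, shifts, depth = 500,
                                  error_rate = 0.005, seed = 43)
cm     <- build_count_matrix(sim$reads, lib)
ratios <- compute_ratios(cm$counts,
                         data.frame(numerator  = c("nuc_1", "nuc_2", "nuc_3"),
                                    denominator = c("cyt_1", "cyt_2", "cyt_3"),
                                    replicate = 1:3))
calls  <- call_localized_tiles(ratios)
table(calls$class, shifts[calls$tile_id])
```

```
               -1  0  1
  cytoplasmic  10  0  0
  nuclear       0  0 10
  unclassified  0 10  0
```

Every shifted tile is classified with the correct sign and no unshifted
tile is called localized. The strongest cytoplasmic tiles look like:

```
     tile_id n_rep median_log2_ratio      p_value        padj       class
1: tile_0002     3         -1.324799 0.0022402439 0.006720732 cytoplasmic
2: tile_0006     3         -1.319475 0.0009808833 0.004904416 cytoplasmic
3: tile_0010     3         -1.279660 0.0041292132 0.009791994 cytoplasmic
```

Medians sit near −1.3 rather than −1.0 because per-fraction CPM
normalization measures each tile against the library average, which the
+1 tiles pull upward; relative spacing between the shift groups is exactly
2 log2 units, as designed. About 14% of reads are unmatched
(`cm$stats`): with a 0.5% error rate, errors landing on bases below Q35
disqualify the read, which is the intended behavior of the quality rule.

`run_pipeline(default_config())` runs all stages on synthetic data and
writes TSV outputs plus a log; `inst/scripts/tilefate.R` exposes the same
stages as shell subcommands (`simulate`, `count`, `localize`, `stability`,
`circquant`, `annotate`, `run`).

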