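---
title: "Screening sporulation genes with Tn-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening sporulation genes with Tn-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnspore)
```

## The screen

A Mariner (himar1) transposon inserts exclusively at TA dinucleotides. A
saturating insertion library in *Bacillus subtilis* therefore carries, for
essentially every non-essential gene, dozens of independent insertion mutants
whose abundance can be read out by sequencing transposon-genome junctions and
tallying reads at each TA site. Sporulation imposes a clean selection on such
a pool: heating a sporulating culture at 80 °C kills vegetative cells and
sporulation-defective mutants, so only clones that formed mature spores are
recovered. Comparing a library sampled at the onset of starvation (T0)
against libraries heat-selected 5 h (T5) or 24 h (T24) later distinguishes
three phenotype classes:

* **defective** — insertions depleted at both T5 and T24 (the gene is needed
  to sporulate at all);
* **delayed** — insertions depleted at T5 but recovered by T24 (the gene is
  needed for *timely* spore maturation);
* **accelerated** — insertions *over*-represented at T5, typically upstream
  of sporulation-initiation loci (over-expression) or within repressors of
  initiation (inactivation).

`tnspore` implements the complete analysis path for such screens — TA-site
indexing, junction-read tag mapping, the per-gene depletion screen, the
sliding-window enrichment scan, and the colony-count statistics used for
validation — together with a synthetic-library simulator that provides
designed ground truth for every stage.

## Per-gene depletion statistic

For a gene with $n$ TA sites the screen compares the per-site normalized read
counts of the reference and selected libraries with a two-sided Mann-Whitney
U test, treating each TA site as one observation and *including unoccupied
sites as zeros in both samples* (the site, not the read, is the sampling
unit). Counts are first scaled to reads-per-10-million within each library,
which makes every reported statistic invariant to sequencing depth — the
package's tests verify exact invariance under uniform count scaling.

Ties are pervasive in insertion-count data (shared zeros especially), so the
implementation enumerates the exact conditional null distribution of the rank
sum given the observed tie pattern by dynamic programming whenever both
samples have at most 8 observations, and otherwise uses the normal
approximation with tie correction and continuity correction. The exact
routine agrees with brute-force enumeration over all $\binom{2n}{n}$ rank
splits for arbitrary tied data, and the approximation stays within 0.01 of
the exact p-value at $n = 20$ in tie-free data.

The effect size is the fold reduction
$f = (R + c)/(S + c)$, where $R$ and $S$ are the normalized gene totals in
the reference and selected libraries and $c$ is a pseudocount of one
normalized read, so a completely depleted gene yields a finite, flagged value
(the pseudocount-free ratio is reported alongside). Hits require
$p < \alpha$ **and** $f > f_{\min}$; the defaults $\alpha = 0.05,
f_{\min} = 2$ match the primary (T24) screen convention, and $f_{\min} = 5$
is conventional for the early, more stringent T5 screen. The two-sided test
with a directional fold filter reproduces one-sided screening while keeping
the p-value label-symmetric.

Two curation flags replace manual inspection of insertion profiles with
explicit rules, both configurable and both reported rather than silently
filtering:

* `low_coverage`: fewer than 5 reference-occupied TA sites — such genes
  cannot support a meaningful rank comparison and are excluded from hit
  calls (roughly the "very few insertions at T0" failure mode);
* `dispersed`: fold change below 3 while at least 80% of reference-occupied
  sites remain occupied after selection — a modest, evenly spread reduction
  rather than a localized knockout signal. Note that by this rule every
  strictly neutral gene (fold near 1, full retention) is also flagged; the
  flag is informative only near the hit threshold.

No multiple-testing correction is applied by default because the screen
thresholds raw p-values; a Benjamini-Hochberg column is available
(`screen_config(adjust = TRUE)`).

### Calibration under a clonal null

A property worth understanding before interpreting p-values: the selected
library is not an independent sample — it is resampled *from the same clone
pool* as the reference. Per-site counts are therefore positively paired
between the two samples, and the Mann-Whitney independent-samples null
overstates the variance of U. In neutral simulations at the package's default
study conditions (200 genes, 63% saturation, 50 reads per occupied site,
7.5 × 10⁵-clone bottleneck) the realized fraction of genes with $p < 0.05$
is about 0.01, far below nominal, and it approaches nominal only when the
selection bottleneck is small enough to decorrelate the libraries. The test
is thus *conservative* for screening purposes — consistent with thresholding
raw p-values without multiplicity correction — but its p-values should not
be read as calibrated tail probabilities. The joint hit rule
($p<0.05$, fold $>2$) produced zero false hits in every neutral run we
simulate in the acceptance suite.

## Sliding-window enrichment scan

Over-representation at T5 is not gene-shaped: it occurs in upstream windows
and operon fragments. The scan therefore slides a window of 13 consecutive
*eligible* TA sites — sites with at least one raw read in both libraries —
in steps of one site, testing normalized selected vs reference counts per
window with the exact Mann-Whitney test (at $n = 13$ per group the exact
conditional null costs microseconds via the same dynamic program) and
computing the window enrichment as the ratio of normalized sums. A window is
significant at $p \le 0.02$ and $\ge 3$-fold enrichment; significant windows
sharing an eligible site are merged into regions.

Merged regions report two coordinate pairs:

* `start`/`end` — the min/max TA positions over member windows (the raw
  union). Because a window is already significant when roughly 8 of its 13
  sites are enriched, this union systematically overshoots a true enriched
  run by up to half a window (3–7 eligible sites) on each side;
* `peak_start`/`peak_end` — the outermost eligible sites whose *individual*
  normalized fold reaches the window threshold, the usual peak-caller
  refinement. In simulations with 10× enriched loci this estimator
  recovered every designed boundary exactly (offset 0 eligible sites across
  all acceptance runs); it is the localization estimate, and the union span
  is retained for window bookkeeping.

Regions are classified by midpoint: `intragenic` when inside a gene body
(likely inactivation), otherwise `upstream` of the nearest downstream gene
start within 500 bp on either strand (likely over-expression), otherwise
`unassigned`. The 500 bp assignment distance and the one-site step are
declared dialect parameters: sensible, but not uniquely determined by the
screen design. Classification against real operon structure still needs
human judgment — an enriched window 5′ of an operon often lies physically
inside the preceding gene, and the midpoint rule then reports `intragenic`.

## Colony-count statistics

Validation experiments use two numbers, both computed from dilution-corrected
CFU/mL (`colonies × dilution / volume`):

* **sporulation efficiency** — heat-resistant CFU of a mutant as a percentage
  of wild-type heat-resistant CFU at the same timepoint;
* **competitive index** — for a 1:1 co-culture,
  $\mathrm{CI} = (m_{sel}/w_{sel}) / (m_{t0}/w_{t0})$; CI of a neutral
  mutant is 1, CI > 1 means earlier spore maturation. CI is invariant to
  common dilution and maps to $1/\mathrm{CI}$ under label swap.

Replicates are summarized as mean ± SEM (sample SD/√n, the two-biological-
replicate convention). A co-culture replicate with zero mutant spores is
censored at its detection limit (the CI one observed colony would give)
rather than reported as CI = 0.

## The simulator: what it emulates, and what it does not

The generator is the package's test bed, and its defaults are the study
conditions of the screen it models:

| parameter | default | rationale |
|---|---|---|
| saturation | 0.63 | fraction of TA sites carrying an insertion at T0 |
| mean gene length | 660 bp | ~41 TA sites/gene at density 1/16, hence ~26 occupied sites per gene at 63% saturation |
| reads per occupied site | 50 | desk-scale depth that leaves per-site counts well away from the detection floor |
| bottleneck size | 7.5 × 10⁵ | the ~750,000-colony pools of the modelled protocol |
| clone-abundance dispersion | lognormal, σ = 0.5 | jackpot effects in pooled transformant libraries; a modelling choice, not a measured value |
| tag length | 16 nt | MmeI releases ~16 nt of genomic sequence |
| accelerator-locus width | 500 bp | ≈ 31 TA sites, comfortably above one scan window of eligible sites |

Genomes are i.i.d. uniform bases (TA density 1/16 per position) with
non-overlapping genes tiled left-to-right; gene classes apply fitness
factors at selection: defective genes at T5 and T24, delayed genes at T5
only, accelerator loci are *enriched* (factor > 1) at T5 and neutral at T24,
matching the transient T5-specific peaks that motivate the scan. Selection
is a single multinomial draw of `bottleneck_size` clones with weights
`abundance × fitness`, followed by a multinomial read draw — one clean
bottleneck rather than the continuous growth-and-killing dynamics of a real
culture. Junction reads are ITR + 16 nt tag + constant adapter at Q40,
error-free by default.

Every stage draws from a named RNG sub-stream derived from the master seed,
so adding a stage never perturbs another stage's draws and all outputs are
byte-reproducible under a fixed seed (verified in the tests).

Features of real data the generator deliberately omits: PCR duplicates and
amplification bias, sequencing errors driving mismapping (substitutions can
be switched on, but the mapper is exact-match by design), local TA-density
and GC structure, operon structure and polar effects, condition-dependent
essentiality, and growth during outgrowth after germination. Passing
recovery tests on simulated data therefore demonstrates that the statistics
and bookkeeping are correct — not that real libraries satisfy the model's
independence assumptions. The calibration caveat above is the clearest
example of a property that only a faithful simulation exposes.

## Numerical choices and degenerate inputs

* Exact Mann-Whitney enumeration is limited to pooled sample sizes ≤ 100
  (the DP table grows quadratically); the screen's default cut-over to the
  normal approximation is at 8 sites per group, and the scan always uses the
  exact null at its fixed window size.
* All-tied samples (e.g. a gene unoccupied in both libraries) give p = 1;
  genes with zero TA sites are reported with `no_sites` and an `NA` p-value,
  never dropped silently.
* `-log10(p)` is capped at 320 in volcano outputs against underflow.
* A TA site belongs to a gene only if both bases lie inside the gene body;
  coordinates are 1-based and sites are identified by the coordinate of
  their T. Circular genomes are handled linearly — an origin-spanning TA
  site is not called, affecting at most one site genome-wide.
* Insertions in both orientations collapse to one count per TA site;
  orientation is not tracked.
* Sites whose 16 nt tag would run past a genome end are skipped at read
  emission (with a warning) and registered one-flank-only in the tag index.
* Library depth scaling is exactly neutral for every statistic; this is an
  invariant of the code, not an approximation.

## Problem sizes used in the automated checks

The test and acceptance suites run the full pipeline at desk scale:
200-gene genomes (~160 kb, ~10,000 TA sites) for screen calibration and
power, 60-gene genomes for the window scan (~1,900 eligible sites per
scan), 20 replicate seeds for null and localization properties, and
~100,000 simulated junction reads for the mapping round trip. These sizes
give the binomial checks and recovery rates tight expectations while
keeping a complete run in minutes on one CPU; all of them scale linearly if
larger experiments are wanted.

## Known limitations

* Single-chromosome analysis only; plasmids and multi-record references are
  not jointly analysed (the first FASTA record is used unless an id is
  given).
* The mapper is exact-match by declared design; junction reads with
  sequencing errors in the tag are dropped rather than rescued, so absolute
  mapped fractions on error-containing data will undercount relative to a
  mismatch-tolerant aligner.
* The screen's p-values are conservative under clonal pairing (see above);
  ranking and thresholding behaviour is what the acceptance suite
  guarantees.
* Whether a study's reported fold changes use read counts or unique
  insertion-site counts is sometimes ambiguous; this package reports read
  counts as primary and emits occupied-site counts alongside.
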