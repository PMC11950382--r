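---
title: "Methods: normalization, chromatin states, CRE linkage and pausing in zgakit"
author: "zgakit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, chromatin states, CRE linkage and pausing in zgakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zgakit)
```

zgakit implements the quantitative backbone of a single-cell multiome +
CUT&Tag analysis of early *Drosophila* embryos around zygotic genome
activation (ZGA): spike-in/H3-normalized chromatin signal, cross-stage
H3K27me3/H3K27ac "ambivalent" state calling, background-matched
peak-to-gene linkage with promoter/enhancer assignment, germ-layer gene
identity scoring, and an RNA polymerase II pausing index. This vignette
explains each model, its assumptions, the tunable parameters, and the
design decisions taken where reasonable alternatives existed.

## Coordinate and container conventions

All interval arithmetic is 0-based half-open (`[start, end)`), matching
BED. Converting to the 1-based closed convention of
`GenomicRanges` shifts `start` by +1; the package does this internally
and converts back, so user-facing coordinates are always BED-like. A
consequence worth noting: book-ended intervals such as `[0, 100)` and
`[100, 200)` share no base and are *not* merged by `unify_peaks()`.

Signal tracks (`signal_track()`) are fixed-grid per-chromosome vectors of
signal density (units per bp) with a 10 bp default bin in the synthetic
data; window statistics (`quantify_peaks()`, `pausing_index()`)
length-weight bins that partially overlap a window, which makes them
exactly equal to per-bp summation for piecewise-constant tracks.

## Spike-in and total-H3 normalization

CUT&Tag libraries carry a fixed amount of tagmented lambda phage DNA, so
lambda read counts are proportional to sequencing depth and independent
of input chromatin. `spike_factor()` returns `K / n_lambda_reads` with
`K = 1e6`; `K` is an arbitrary common scale (the upstream tooling leaves
the constant implicit) and cancels from every ratio the package computes.

A total-H3 control from the same nuclei pool measures input material:
H3 content per nucleus is constant, so the spike-normalized H3 genome
read total is proportional to the number of nuclei. `h3_correction()`
anchors every library at a declared reference sample (by convention the
first wild-type sample):

$$c = \frac{f_{\lambda}(\mathrm{H3}_{ref})\, N(\mathrm{H3}_{ref})}
           {f_{\lambda}(\mathrm{H3})\, N(\mathrm{H3})}$$

so that `spike_factor(lib) * c` puts all tracks on a per-nucleus scale.
Two samples with identical per-nucleus signal but different depth and
nuclei input then recover identical normalized tracks — exactly, when the
underlying signal is identical (this is the invariance the test suite
asserts at 1%). The correction is applied at the track level only; we do
not re-enter peak calling (peaks are inputs throughout). An optional
exclusion BED can be subtracted from H3K27me3 peak sets before
classification to handle antibody cross-reactivity; no algorithmic
detail beyond set subtraction is implied.

`quantify_peaks()` integrates normalized signal over `±1 kb` around each
peak's *midpoint* (`floor((start + end)/2)`). "Around each peak" is
ambiguous between edges and midpoint; the midpoint gives every peak an
equal-width window and is the documented choice.

## Ambivalent chromatin states from pooled cell types

H3K27me3 and H3K27ac are mutually exclusive on the same histone tail,
yet pooled (whole-embryo) profiles can show peaks carrying both. The
classification is deliberately simple: after merging all per-stage peak
sets into a unified list (`unify_peaks()`, transitive overlap merge), a
unified peak is

* `ambivalent` if it overlaps (≥ 1 shared base) both an me3 peak and an
  ac peak at that stage,
* `me3` or `ac` if it overlaps only one set,
* `unassigned` otherwise.

Any-overlap rather than reciprocal-fraction overlap is used; only
"overlap" is specified by the definition and 1 bp is the convention that
needs no extra parameter. `transitions()` cross-tabulates states between
consecutive stages (the alluvial-plot accounting); peaks absent at a
stage and peaks present-but-unmarked share the single `unassigned`
state. The central testable claim is the *mixture property*: pooling
cell types whose marks are mutually exclusive creates ambivalent calls
at exactly the loci where cell types disagree, while each sorted cell
type alone shows none. The synthetic generator plants such discordant
loci and the acceptance suite recovers them with precision = recall = 1.

`peaks_to_genes()` assigns a peak to every gene whose TSS lies strictly
closer than 10 kb (distance 0 when the TSS falls inside the peak);
the inequality is strict, so a TSS exactly 10 kb away is not assigned.
Peak width QC keeps widths in `[20, 10000]`, bounds inclusive —
"between" is read inclusively and documented as such.

## Multiome core

Cell QC discards cells with fewer than 300 total RNA counts, fewer than
200 detected genes, or more than 20% mitochondrial counts; all three are
strict inequalities, so boundary cells are kept. RNA normalization is
`ln(1 + count/total × 10^4)`; ATAC normalization is log-TF-IDF,
`ln(1 + (c_{ij}/colsum_j)(n_{cells}/n_{open,i}) 10^4)` — the method name
admits several dialects and this is the one implemented, stated
explicitly so results are reproducible.

HVG selection scores genes by standardized variance: a loess trend
(span 0.3, degree 2) of log10 variance on log10 mean predicts each
gene's expected sd; values standardized by it are clipped at
`sqrt(n_cells)` and their variance ranks the genes, ties broken by gene
id. Below 200 genes the local trend would absorb genuine biological
variance (the fit neighbourhoods become dominated by the very genes
being scored), so plain variance is used there.

Signature scores follow the binned-control construction: genes are cut
into 25 equal-size mean-expression bins and, per signature gene, 50
control genes are sampled (seeded) from its bin, excluding the signature
itself; the score is the per-cell mean over the signature minus the mean
over the pooled controls. Random gene sets therefore score ≈ 0.

Differential expression uses the two-sided Wilcoxon rank-sum test —
exact when the smaller group has ≤ 10 cells and no ties force the
approximation, tie-corrected normal approximation otherwise — with
Benjamini–Hochberg adjustment across tested genes. Genes expressed in
fewer than 1% of cells in *either* compared group are excluded; "in any
condition" is read per compared group. Fold changes are computed on
de-logged means with a `1e-9` guard,
`log2((mean(expm1 x) + ε)/(mean(expm1 y) + ε))`.

The gene identity score takes each gene's primary germ layer as the
layer with the highest mean wild-type expression, then reports the
fraction of the gene's expressing cells (count > 0) lying in that layer,
within each genotype. It is invariant to cell order and to any positive
scaling of expression. Regulator depletion that lets markers leak into
foreign layers lowers the mean score — the property the acceptance suite
checks on synthetic knockdown-like data.

## Peak-to-gene linkage with a matched background null

For each gene, every peak within ±20 kb of the TSS is a candidate. The
statistic is the Pearson correlation r between peak accessibility and
gene expression across cells. Raw correlations are biased by GC content,
overall accessibility and peak size, so significance is calibrated
against a matched background: the candidate's `n_background = 200`
nearest neighbours in standardized (GC, mean accessibility, log width)
space, excluding itself. With null mean m and sd s, `z = (r − m)/s` and
`p = 1 − Φ(z)` — one-sided, because the assignment targets positive
regulation; negative links stay in the table but are never chosen as
enhancers. k-NN matching in covariate space is our mechanism choice (the
alternative, per-covariate binning, needs bin-width parameters and
degrades in sparse bins); it is documented as a choice, not asserted as
what any particular published tool does. Records with p below
`alpha = 0.05` are returned, ranked by r within gene; `alpha = 1`
returns every candidate, and the candidate total is attached as an
attribute so null calibration (the fraction of null candidates passing
0.05 must be 5% ± 2%) needs no second code path.

Promoter assignment takes the most WT-accessible peak within ±500 bp of
the TSS; enhancer assignment takes the significant link with maximal r
within ±20 kb but outside the promoter window. Both break ties to the
lexicographically smaller peak id; genes without an element are excluded
downstream rather than imputed. Per-cell and per-layer Spearman
correlations and the Mann–Whitney comparison between the promoter-based
and enhancer-based distributions follow directly; per-cell correlations
use the genes having the requested element (the HVG intersection, for
the headline comparison — genes with both elements, since each
distribution conditions only on its own element's presence).

## RNAPII pausing index

For a gene with TSS t, the promoter window is `[t − 300, t + 300)` on
either strand and the body window `[t + 300, t + 5000)` on `+`
(mirrored on `−`). The index is the ratio of *mean densities* (not
sums), so the unequal window lengths (600 vs 4700 bp) compare as
enrichment. Genes with zero body signal are reported missing rather than
infinite, keeping rank tests well-defined; genes shorter than the body
window are scored on the truncated body and flagged `short_gene`. The
index is invariant to track scaling and to genome reflection
(strand-mirror symmetry), both asserted in tests to machine precision.
`compare_pausing()` reports, per gene set, the two-sided Mann–Whitney p
and the KD/WT ratio of medians.

## The synthetic-data generator

The generator exists so that every estimator can be tested against a
planted truth. Its defaults are the simulated study conditions and were
fixed once:

| parameter | default | rationale |
|---|---|---|
| cell types × cells | 4 × 250 | three germ layers + yolk; 1000 cells is ample for per-cell correlations |
| genes | 400 (+5% mito) | enough detected genes per cell to pass the fixed 300/200/20% QC gates |
| peaks per gene | 1 promoter + 4 distal | 2000 candidate links, sufficient for null calibration |
| RNA model | NB, dispersion 0.3 | typical droplet-style overdispersion |
| baseline mean `mu0` | 0.8 | markers mostly off outside their layer, yet ~300 genes detected per cell |
| ATAC model | Bernoulli-thinned Poisson(2) | minimal model with a tunable open probability |
| enhancer open prob | 0.8 home / 0.1 elsewhere | strong but imperfect layer specificity |
| promoter open prob | 0.8 everywhere | promoters ubiquitously open, independent of expression |
| neutral distal peaks | open 0.3 everywhere | uncorrelated background candidates |
| gene spacing | 50 kb | ±20 kb windows never reach a neighbouring gene's peaks |
| mark tracks | 1 kb peaks / 3 kb spacing, 10 bp bins, amplitude 5 over background 0.02 | desk-scale exact window arithmetic |
| spike-in | 1e5 × depth lambda reads | proportional to depth, independent of nuclei |
| pausing ratios | 2 (WT), 4 (KD) | a planted doubling, recoverable to ±10% under Poisson noise |

Expression is coupled to accessibility *within* each cell — the NB mean
is `mu0 (1 + effect × enhancer count)` — which is what peak-to-gene
linkage across cells actually assumes. Setting `enhancer_effect = 0`
removes all cell-type structure and yields the linkage null. A
knockdown-like condition lets each enhancer leak into extra layers
(`leak_layers`, `leak_rate`), blurring germ-layer identity.

Deterministic modes (`noise = FALSE` in the track generators) emit exact
expected coverage; they are used where a property holds exactly —
normalization invariance, brute-force oracle equality — so that the test
tolerance reflects the property, not the generator's sampling depth.
Every generator derives its RNG stream from `cfg$seed` and restores the
caller's RNG state.

What the generator does **not** emulate: read-level artifacts (no
FASTQ, alignment or duplicates), doublets, batch effects, chromatin
contact structure, more than one chromosome, overlapping genes,
isoforms, or empirically calibrated effect sizes — no published effect
or noise magnitudes were available to calibrate against, so defaults
are realistic-by-judgement, not fitted. Green tests therefore show the
estimators are correct and well-calibrated under the stated model, not
that the model captures every property of the real data.

## Problem sizes and numerical choices

The test and acceptance runs use 200–400 genes, 500–1200 cells, 200-peak
mark panels and 2–10 Mb single-chromosome tracks at 10 bp bins — sizes
chosen so the full suite completes on a laptop-class single core in a
few minutes. Degenerate inputs are handled explicitly: constant
expression or accessibility vectors are skipped (correlation undefined),
a degenerate linkage null (sd 0) flags the record instead of producing
an infinite z, zero-body pausing genes become missing values, and peaks
on chromosomes absent from a track score 0 with a warning.

## Pipeline

`run_pipeline()` executes the stages in dependency order from a single
YAML/JSON config with every analysis default exposed and logged
(windows ±500 bp / ±20 kb / 10 kb / ±1 kb / 300–5000 bp; QC 300 counts,
200 genes, 20% mito; 1% expression filter; p < 0.05; 2000 HVGs), writes
TSV/BED/bedGraph/JSON outputs plus a manifest with seeds and record
counts, and is byte-reproducible under a fixed seed. The package is
driven from R; `demo_pipeline()` is the one-call smoke run. A requested
stage whose dependency stage is disabled fails with an error naming the
missing stage.
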