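# zgakit

Chromatin-state, cis-regulatory-element linkage and RNAPII pausing
analysis for early-embryo single-cell multiome and CUT&Tag data.

## The problem

Around zygotic genome activation (ZGA), a *Drosophila* embryo is a
mixture of emerging germ layers. Bulk chromatin profiles of such a
mixture can show peaks that apparently carry both the repressive
H3K27me3 and the active H3K27ac mark ("ambivalent" regions) even though
the two marks are mutually exclusive on a histone tail — pooling cell
types with opposite marks is enough. Quantitative comparison across
developmental stages and knockdown conditions additionally requires
normalizing chromatin signal for sequencing depth (lambda spike-in) and
input material (total-H3 control), linking distal accessibility peaks to
the genes they regulate against a covariate-matched null, and measuring
promoter-proximal RNA polymerase II pausing.

zgakit implements this analysis core for bioinformaticians working with
peak sets (BED), coverage tracks (bedGraph) and single-cell RNA/ATAC
count matrices, together with a synthetic-data generator that plants
known enhancers, mark-discordant loci and pausing ratios so every
estimator is tested against ground truth.

## The statistics at the core

* **Spike/H3 normalization.** Scale factor `K / n_lambda` (lambda reads
  track depth); H3 correction
  `(f_ref · N_ref) / (f_H3 · N_H3)` anchors libraries to a reference
  pool so signal is per-nucleus comparable. Peak signal is the
  integrated normalized density over ±1 kb around each peak midpoint.
* **Ambivalent states.** Unified peaks (transitive overlap merge) are
  `ambivalent` when overlapping both an me3 and an ac peak at a stage,
  with transition tables across stages.
* **Peak-to-gene linkage.** For each gene × peak within ±20 kb of the
  TSS, Pearson r across cells; z-score against the correlations of the
  200 background peaks nearest in standardized (GC, accessibility,
  log-width) space; one-sided p, significant links at p < 0.05.
  Promoter = most accessible peak within ±500 bp of the TSS; enhancer =
  top-r significant link outside the promoter window.
* **Pausing index.** Mean RNAPII-S5P density over TSS ± 300 bp divided
  by mean density over 300–5000 bp downstream (strand-aware), compared
  between conditions with a Mann–Whitney test.
* **Multiome core.** QC (≥300 counts, ≥200 genes, ≤20% mito),
  log-normalization and TF-IDF, standardized-variance HVGs,
  binned-control signature scores, Wilcoxon + BH differential testing,
  and the germ-layer gene identity score (fraction of a gene's
  expressing cells in its wild-type-defined primary layer).

## Worked example

```r
library(zgakit)

## pooled dual-mark CUT&Tag: ambivalence is a mixture artifact
cfg2 <- synthetic_config(n_cell_types = 2, n_genes = 200,
                         mark_discordance_rate = 0.2, seed = 1)
ml <- simulate_mark_libraries(cfg2)
h3_ref <- ml$libraries$h3_s1
me3 <- call_marked_peaks(normalize_library(ml$libraries$me3_s1,
                                           ml$libraries$h3_s1, h3_ref), ml$peaks)
ac  <- call_marked_peaks(normalize_library(ml$libraries$ac_s1,
                                           ml$libraries$h3_s1, h3_ref), ml$peaks)
states <- classify_stage(ml$peaks, me3, ac, stage = "pooled")
table(states$state)
#>        me3         ac ambivalent unassigned
#>         66         59         42         33
setequal(states$id[states$state == "ambivalent"], ml$truth$discordant)
#> [1] TRUE     # the 42 ambivalent calls are exactly the planted discordant loci

## multiome: linkage, CRE map, enhancer-vs-promoter coupling
mo <- simulate_multiome(synthetic_config(seed = 1))   # 4 layers x 250 cells
qc <- qc_filter(mo$rna, mo$cells, mo$truth$mito_genes)
rna <- normalize_rna(qc$counts)
atac <- tfidf(mo$atac[, colnames(qc$counts)])
links <- link_peaks(rna, atac, mo$genes, mo$peaks)
head(links, 3)
#>       gene      peak         r        z            p flag
#> 1 gene_001 enh_001_1 0.5660739 7.014694 1.152267e-12   ok
#> 2 gene_002 enh_002_1 0.5478534 8.010278 5.722491e-16   ok
#> 3 gene_003 enh_003_1 0.5109261 7.876405 1.684679e-15   ok

cre <- build_cre_map(atac, mo$genes, mo$peaks, links)
hvgs <- select_hvgs(rna, n = 200)
rho_e <- per_cell_correlation(rna, atac, cre, hvgs, "enhancer")
rho_p <- per_cell_correlation(rna, atac, cre, hvgs, "promoter")
median(rho_e, na.rm = TRUE); median(rho_p, na.rm = TRUE)
#> [1] 0.5828357     # expression tracks enhancer accessibility...
#> [1] 0.0005285854  # ...but not promoter accessibility (uniformly open)

## RNAPII pausing: planted KD/WT ratio of 2 is recovered
s5 <- simulate_rnapii_tracks(synthetic_config(seed = 1), mo$genes)
compare_pausing(pausing_index(s5$s5p_wt, mo$genes),
                pausing_index(s5$s5p_kd, mo$genes))
#>   set n_wt n_kd      U             p median_ratio
#> 1 all  400  400 160000 2.445399e-132      1.99792
```

The linkage table reads: `gene_001`'s top link is its planted enhancer
peak (`enh_001_1`), correlation r = 0.57, z = 7.0 against the matched
background null, one-sided p ≈ 1e-12. The per-cell Spearman medians say
that within single cells expression co-varies with enhancer, not
promoter, accessibility; the pausing comparison recovers the simulated
doubling of the promoter/body density ratio (`median_ratio` ≈ 2).

`run_pipeline()` / `demo_pipeline()` chain all stages from one YAML/JSON
config and write TSV/BED/bedGraph outputs plus a run manifest; see the
methods vignette (`vignettes/zgakit-methods.Rmd`) for the models,
parameter meanings and design decisions.

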