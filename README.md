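# linchk

Discovery and annotation of **housekeeping long intergenic noncoding RNAs
(lincRNAs)** — the small minority of lincRNAs that, like classical
housekeeping genes, are expressed across essentially all tissues at stable
levels, and that conservation, structure, tumour and methylation evidence
mark as candidates for core cellular roles.

The package is aimed at computational biologists who want a tested, seeded,
end-to-end implementation of this analysis: each stage is an ordinary R
function over plain containers (matrices, data frames), every stochastic
step takes a seed, and a synthetic-data module with planted ground truth
makes the whole pipeline verifiable without any external cohort.

## The pipeline

1. **Classification.** Per gene, detection breadth and the coefficient of
   variation CV = s / x̄ across tissues (sample SD, zeros included).
   Housekeeping candidates (cHK) are detected (> 0.5 FPKM, strict) in ≥ 75%
   of tissues with CV < 1.5; tissue-specific genes (TS) in < 25% of tissues
   with CV > 3.5; lincRNAs within 1 kb of a coding gene are excluded first.
2. **Sequence features.** Exon-restricted mean conservation, SNPs per kb of
   exon, merged repeat-class coverage, and best-hit orthologue calls at
   ≥ 30% identity.
3. **Structure.** A Randfold-style permutation test: the folding score of
   each transcript versus dinucleotide-preserving (Altschul–Erickson)
   shuffles, p = (1 + #{null ≤ obs}) / (N + 1), BH FDR across genes. Engines:
   a built-in Nussinov pair-maximisation dynamic program (C++), or RNAfold
   for thermodynamic MFE.
4. **Tumour refinement.** 'Core' housekeeping = never downregulated
   (|FC| > 2, q < 0.05 in any tumour type), never recurrently homozygously
   deleted (≥ 1% of samples), never inside a focal deletion.
5. **Methylation.** Promoter-window (−2000..+200 around the strand-aware
   TSS) probe means; per-sample group medians; paired Wilcoxon signed-rank.
6. **Function.** Per lincRNA, coding genes ranked by Pearson correlation;
   weighted-KS preranked enrichment with permutation NES and pooled FDR;
   terms recurring in ≥ 10% of lincRNAs kept; Wang semantic-similarity
   clustering (tree cut at 0.85) reduces redundant terms.
7. **Survival.** Kaplan–Meier curves and log-rank test between patients
   above versus below the 75th expression percentile.

## Worked example

```r
library(linchk)

# a 16-tissue atlas with 50 planted housekeeping, 50 tissue-specific and
# 100 background genes
tm <- make_tissue_matrix(n_hk = 50, n_ts = 50, n_bg = 100, seed = 1)
cls <- classify_lincrnas(tm$matrix)
table(planted = tm$truth$class, called = cls$label)
#>             called
#> planted       HK neither  TS
#>   background   0     100   0
#>   HK          50       0   0
#>   TS           0       0  50
```

Every planted housekeeping gene is recovered (detection 16/16, CV ≈ 0.3)
and every tissue-specific gene lands in TS (detection 1/16, CV ≈ 4);
background genes, detected in 7–9 tissues, can satisfy neither rule.

The one-command demo generates a full synthetic input set, runs all seven
stages, and scores the funnel against the planted truth:

```r
s <- run_demo(seed = 7)
s$funnel
#> $n_genes                  120
#> $n_chk                    30
#> $n_ts                     30
#> $n_structured_significant 30
#> $n_core                   19
s$funnel_recall   # 1: every planted clean-HK gene survives all filters
s$logrank_p       # 1.6e-06: planted hazard ratio 2 at the quartile split
```

30 of 120 genes pass the housekeeping rules (the 30 planted ones); their
planted stem-loop sequences are all flagged as significantly structured; the
tumour filters remove the 11 genes planted with downregulation, deletion or
focal loss, leaving 19 core genes — exactly the planted clean set. The same
run writes per-stage TSVs and a `summary.json` under `s$dir`.

A thin shell front end wraps the same functions:

```sh
exec/linchk demo --seed 7
exec/linchk simulate --dir inputs --seed 1
exec/linchk run --in inputs --out outputs --seed 1
```

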