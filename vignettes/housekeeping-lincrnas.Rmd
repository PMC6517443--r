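---
title: "Discovering housekeeping lincRNAs: methods and design notes"
author: "linchk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering housekeeping lincRNAs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most long intergenic noncoding RNAs (lincRNAs) are expressed in narrow,
tissue-restricted patterns, but a small minority behaves like classical
housekeeping genes: detectable in essentially every tissue, at stable levels,
with conserved sequence and structure, and rarely lost in tumours. `linchk`
implements a complete in silico pipeline for finding and characterising such
housekeeping lincRNAs from multi-tissue expression data, and for annotating
them with structural, genomic, epigenetic, functional and clinical evidence.
Because the public cohorts this kind of analysis is usually run on are far too
large to ship with a package, every stage is exercised instead on synthetic
data with planted ground truth, which makes the whole pipeline testable
end to end.

## The classification model

For each gene the pipeline computes a detection profile across tissues. A
tissue's expression is the mean of that tissue's samples (in the
single-sample-per-tissue design of a body-map style atlas, the sample
itself); a gene counts as *detected* in a tissue when that mean strictly
exceeds the detection threshold (default 0.5 FPKM). Variability is the
coefficient of variation

$$\mathrm{CV} = \frac{s}{\bar{x}}$$

computed over **all** tissue values, zeros included, with the sample standard
deviation ($n-1$ denominator). Zeros must contribute: a gene silent in half
the tissues is variable in precisely the sense the statistic is meant to
capture. The labels are:

* **HK** (housekeeping candidate): detected in at least 75% of tissues
  (inclusive, so 12 of 16) *and* CV strictly below 1.5;
* **TS** (tissue-specific): detected in strictly fewer than 25% of tissues
  *and* CV strictly above 3.5;
* **neither** otherwise. Genes whose CV is undefined (zero mean) are
  *neither*.

A genomic prefilter removes lincRNAs whose gene span lies within 1 kb
(strict: a gap of exactly 1000 bp excludes) of any protein-coding gene span
on the same chromosome, strand-agnostically — expression estimates that close
to a coding locus are unreliable and the transcript may be a fragment of it.

Two genuinely open choices are exposed as options rather than hard-coded:
whether the CV is taken over per-tissue means of replicates or pooled samples
(`aggregate`), and whether it is computed on linear or log2(x+1) abundances
(`log_scale`). Defaults are per-tissue means on the linear scale, which is
the natural reading for FPKM-style atlases.

## Sequence and structure evidence

Conservation is summarised as the arithmetic mean of per-base scores over the
union of a gene's exons; bases with no score are **skipped**, not
zero-filled, because conservation tracks are sparse over masked repeats and
zero-filling would conflate "not conserved" with "not scored". SNP density is
1000 × (SNP positions inside the exon union) / exonic length, i.e. SNPs per
kb of exon. Repeat coverage merges same-class repeat copies before
intersection so overlapping annotations are not double counted. Cross-species
orthologue summaries consume a BLAST-style hit table, keep the best-identity
hit per (gene, species) and call an orthologue at $\geq$ 30% identity
(inclusive); re-running the alignment itself is out of scope — the filter and
the cross-species variability summary are what matter here.

### The folding permutation test

Structural stability is tested Randfold-style: the observed folding score of
a transcript is compared against the scores of the same sequence shuffled
many times while preserving its exact dinucleotide composition, so the null
keeps both base composition and the nearest-neighbour statistics that drive
folding energies. The shuffle is the Altschul–Erickson Eulerian-path
construction: build the multigraph of adjacent-base transitions, pick a
random last-exit edge per vertex until those edges form a tree into the
terminal base, then walk the remaining edges in random order. This preserves
the dinucleotide count multiset, the first and last base, and the length —
properties asserted on every call in the test suite.

The one-sided (stability) p-value uses the add-one convention

$$p = \frac{1 + \#\{\text{null} \le \text{observed}\}}{N + 1},$$

which is valid (never anti-conservative) for any score, and q-values are
Benjamini–Hochberg across all tested sequences. Two folding engines are
provided:

* **nussinov** (default, dependency-free): minus the maximum number of
  nested Watson–Crick/GU pairs with a minimum hairpin loop of 3 unpaired
  bases, computed by the $O(n^3)$ dynamic program in C++. It is validated
  against an exhaustive structure-enumeration oracle for short sequences.
* **vienna**: the thermodynamic minimum free energy (kcal/mol) from an
  external `RNAfold` call, batched over all shuffles of a sequence.

The two engines differ in one statistically important way: the Nussinov
score is an integer, so shuffles of the same sequence frequently tie with
the observed score, and counting ties in the $\le$ direction makes the
permutation p-value conservative (its null distribution is stochastically
larger than uniform). That is safe — it never inflates significance — but it
means strict type-I calibration holds only for a continuous score. The
calibration checks in the acceptance suite therefore run the vienna engine,
whose MFE is continuous, while the planted-structure power checks pass under
both engines. The calibration simulations use 100–150 nt sequences and 100
shuffles; the planted-stem power simulations use 200 nt sequences whose stem
arms together occupy 30% of the sequence.

Per-sequence child seeds are derived by a stable string hash of the sequence
name, so results are independent of iteration order.

## Tumour refinement

A candidate housekeeping gene survives to the 'core' set iff it is
**none** of:

* downregulated in any tumour type — some type with $\log_2 FC < -\log_2 2$
  and $q < 0.05$, both strict;
* recurrently homozygously deleted — homozygous-deletion category in at
  least 1% of samples (inclusive), pooled across tumour types by default
  (a per-type mode is available);
* inside a focal deletion — any shared base between the gene span and a
  deletion-type focal region (half-open coordinates, so abutting regions do
  not count).

The strict/inclusive senses follow the wording of the decision rules
("greater than 2-fold", "at least 1%") literally and each boundary is pinned
by a unit test. Missing evidence passes a gene through by default
(`missing = "exclude"` drops it instead). A deliberately simple two-group DE
stand-in (`simple_de`: Welch t on log2(x+1), BH correction, fold change from
linear group means) is provided for synthetic runs and clearly labelled as
such; real count-model DE tables can be imported wherever a DE table is
consumed.

## Promoter methylation

Gene-level methylation is the mean beta of all probes inside the promoter
window, −2000 bp to +200 bp around the TSS. The window is reflected through
the strand-aware TSS on minus-strand genes ([tss − 200, tss + 2000)); the
underlying data sources leave strand handling unstated, so a strand-agnostic
switch is provided. Group comparison computes the per-sample median beta over
each gene group; because both medians are indexed by the same samples, the
primary test is a paired two-sided Wilcoxon signed-rank across samples, with
the unpaired rank-sum reported as secondary.

## Function prediction by preranked enrichment

For each lincRNA, protein-coding genes are ranked by Pearson correlation to
it across samples (descending, ties broken by gene id). The weighted
Kolmogorov–Smirnov enrichment score walks the ranking: member genes add
$|r|^p / \sum_{hits} |r|^p$ (default $p = 1$), non-members subtract
$1/(N - N_{hit})$, and ES is the signed maximum deviation. When the positive
and negative extremes have equal magnitude the ES is 0 (the standard GSEA
convention); that comparison uses a $10^{-9}$ tolerance because
equal-magnitude extremes arise from rational step sizes and must not flip
sign on floating-point noise.

The null randomises set membership over the ranking (gene-label
permutation — the only permutation scheme available for an externally ranked
list). NES is ES divided by the mean of same-sign null ES values; the
p-value is the add-one same-sign tail; the FDR is the pooled-null procedure:
the fraction of all normalised null scores at least as extreme, divided by
the fraction of observed NES at least as extreme, clipped to [0, 1].
Eligible set sizes default to 15–500. Each set's permutations come from a
child seed keyed by the set name.

Terms significant (FDR < 0.05, strict) in at least
$\lceil 0.10 \times n_\mathrm{lincRNA} \rceil$ lincRNAs are kept (the
recurrence fraction is printed in the decision rule; the ceiling makes "at
least 10%" exact for any count). Redundancy among the surviving terms is
removed with Wang-method semantic similarity (edge contributions 0.8 for
`is_a`, 0.6 for `part_of`; similarity = shared S-mass over total S-mass),
average-linkage clustering on distance $1 - sim$, a tree cut at height 0.85,
and one representative per cluster — picked by seeded RNG to mirror a random
choice among near-synonymous terms, with a deterministic lowest-id option.
Wang's measure and average linkage are our choices; the upstream description
names the similarity package but not the measure or linkage. A knockdown
mode applies the |NES| > 1.7 and FDR < 10% significance rule (both strict)
to any ranked-list enrichment result.

## Survival

Patients strictly above the type-7 (linear interpolation) 75th percentile of
expression form the high group; ties at the threshold go low. Kaplan–Meier
curves and the 1-df log-rank test come from the survival package — these are
entirely standard estimators and re-implementing them would add nothing.
Tests verify the product-limit identity with empirical survival under no
censoring, type-I calibration at hazard ratio 1, and power at hazard ratio 2
with 200 patients per arm and ~50% censoring.

## What the synthetic data emulates — and what it does not

Each generator is a pure function of its seed and returns a truth object
sufficient to score the downstream stage:

* `make_tissue_matrix` — housekeeping genes get a lognormal baseline
  (median ~20 FPKM) with multiplicative per-tissue noise (sdlog 0.3,
  realised CV ≈ 0.3); tissue-specific genes are expressed in a single
  dominant tissue (lognormal, median ~50) and near zero elsewhere, so the
  realised CV sits near $\sqrt{n_\mathrm{tissues}} = 4$ for 16 tissues —
  a single-tissue archetype chosen because it guarantees the CV > 3.5
  criterion by construction while staying within the "restricted to under a
  quarter of tissues" definition; background genes are detected in 7–9 of 16
  tissues, placing their detection fraction strictly between the TS and HK
  bands so neither rule can fire.
* `make_sequences` — structured sequences carry a perfect inverted repeat
  (two arms totalling 30% of the length, 4-base loop) inside flanks drawn
  from a first-order dinucleotide Markov chain; random sequences come from
  the chain alone, so the shuffle null is exactly exchangeable for them.
* `make_tumour_tables` — disjoint planted down / recurrently-deleted /
  focally-deleted gene sets (20% / 10% / 5% by default, plus 15%
  upregulated) over 13 tumour types and 500 copy-number samples; clean genes
  get sub-threshold fold changes and no homozygous deletions.
* `make_methylation` — Beta(2, 10) promoter betas for the housekeeping
  group versus Beta(5, 5) for the tissue-specific group, five probes per
  promoter window plus one decoy outside it.
* `make_coexpression` — a latent Gaussian factor per pathway; the pathway's
  lincRNA and coding members load on it with loading $\sqrt{0.7}$, giving
  pairwise Pearson $r \approx 0.7$; values are mapped affinely to a
  non-negative FPKM-like scale, which preserves Pearson correlations.
* `make_survival` — lognormal expression; the above-75th-percentile group's
  exponential event hazard is multiplied by the hazard ratio; independent
  exponential censoring tuned to ~50%.

The noise families (lognormal expression, Beta methylation, exponential
survival, Gaussian factors) were chosen for support correctness, not
realism of tails. The generated abundances are not count-derived, so there
is no mean–variance relationship of the kind count models exploit — which is
exactly why the DE stand-in is a t-test on log values rather than a negative
binomial fit. Passing tests on these data show the *decision logic* and the
*statistics* are implemented correctly at the stated effect sizes; they say
nothing about upstream quantification error, batch structure, or the messier
correlation structure of real cohorts.

## Numerical and reproducibility choices

* All intervals are 0-based half-open internally; GTF input is converted at
  the I/O boundary, BED is native. Abutting intervals share no base.
* Rank tests use midranks with tie-corrected variance (exact enumeration for
  small untied samples).
* Every stochastic routine takes a seed and restores the caller's RNG state;
  per-item child seeds come from a 31-bit polynomial string hash, so no
  result depends on iteration order and all seeds stay inside R's integer
  range.
* Degenerate inputs fail loudly: negative expression, betas outside [0, 1],
  unknown copy-number categories, cyclic ontologies and malformed BED12
  lines are errors, not warnings.
* The pipeline demo (`run_demo`) uses 30/30/60 planted HK/TS/background
  genes, 99 shuffles and 100 enrichment permutations; the acceptance
  simulations use 20 classifier seeds, 1000 shuffle-exactness draws, 200
  calibration sequences, 1000 ES-oracle cases and 50 co-expression
  datasets. These sizes give the recovery and calibration checks enough
  resolution (binomial 95% bands around the nominal rates) while keeping a
  full run on one core comfortable.

## Known limitations

* The Nussinov engine maximises pair count, not free energy; its permutation
  p-values are conservative (see above) and its score should not be read in
  kcal/mol. Use the vienna engine when a thermodynamic MFE is wanted.
* BLAST, count-model DE, focal-region discovery and network analyses are
  consumed as tables, not computed.
* The GSEA FDR is the standard pooled-permutation estimate; with few eligible
  sets it is grainy, and with very few permutations it is upward-biased —
  both inherent to the procedure, not to this implementation.
* Antisense transcripts are out of scope; the proximity filter only handles
  the intergenic definition.
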