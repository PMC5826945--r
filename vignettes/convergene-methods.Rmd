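---
title: "Methods: integrative risk-gene prioritization in convergene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative risk-gene prioritization in convergene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`convergene` prioritizes candidate risk genes for polygenic brain
disorders by integrating a disease GWAS with brain eQTL data and
accumulating orthogonal evidence layers into a cumulative score. This
vignette is the package's account of the statistical methods, the
defaults and why they were chosen, the design decisions that were
genuinely open, and what the synthetic-data tests do and do not
establish.

## The gene-scoring model

All association statistics are handled on the standardized scale: a
z-score with unit standard error, interconvertible with a two-sided
p-value through the normal quantile (`p_from_z()`, `z_from_p()`). When a
summary file carries only p-values, the recovered z is non-negative and
flagged sign-unknown; every statistic in the package depends on z only
through z², so no information that the pipeline uses is lost.

### Per-eSNP log Bayes factor

For gene *g*, the eSNPs are the eQTL records with p below
`esnp_p_threshold` (default `1e-5`; this is deliberately larger than a
genome-wide threshold because moderately associated eSNPs carry real
signal for the gene-level score, and it admits instrument-grade eQTLs
comfortably). Each eSNP is scored from its **GWAS** z with the
approximate Bayes factor for a normal prior on the true standardized
effect, variance `W`, against the point null:

$$\mathrm{LBF}(z) = \tfrac12\log\frac{1}{1+W} +
  \frac{z^2}{2}\cdot\frac{W}{1+W}.$$

The functional form gives exactly the behaviour the integrative scoring
strategy requires: it is strictly increasing in z², **negative** at
z = 0 (a gene whose expression-associated SNPs carry no disease signal
accumulates negative evidence), positive once
$z^2 > \frac{1+W}{W}\log(1+W)$, and additive over eSNPs. The gene score
is the **sum** of its per-eSNP LBFs; SNPs with disease association but
no eQTL record never enter the sum. `exp(LBF)` is the evidence odds
against the null.

The prior variance `W` (default 0.15) is the one free parameter. On the
standardized scale it says that true disease effects of eSNPs are
expected at |z| ≈ 0.4 per unit standard error — a weak-effect prior
appropriate for a highly polygenic disorder. Larger `W` rewards only
very strong GWAS signals; smaller `W` flattens the score toward zero
(`W → 0` gives LBF → 0 for any fixed z). The default is not critical
for ranking, because LBF is monotone in z² at any fixed `W` and common
across genes.

### Empirical p-values

The null distribution of a gene's total LBF depends only on its eSNP
count *k*: under no disease association, the GWAS z of each eSNP is
standard normal. `lbf_empirical_p()` therefore draws
`n_null_draws_lbf` (default 10 000) null genes with *k* standard-normal
z-scores each and reports the add-one estimate
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n)$. The add-one form
keeps the p-value strictly positive and exactly uniform on its
attainable grid under the null. The genome-wide scan shares null draws
across genes with equal eSNP counts (the null law is identical, and the
per-gene p-values remain marginally calibrated), and Bonferroni-corrects
over the genes actually tested: `corrected_p = min(1, p × n_genes)`,
equivalently a per-test threshold of α/n. Note the resolution
constraint: with *n* null draws the smallest attainable corrected p is
`n_genes/(n+1)`, so the default of 10 000 draws is the minimum sensible
for ~100 genes at α = 0.05.

### SMR validation

Per gene the instrument is the *cis* eQTL with the smallest p among
those below `smr_instrument_p_threshold` (default `5e-8`: instruments
must be unambiguous, genome-wide-significant eQTLs; trans records are
never used because a trans association is weaker evidence that the
variant acts through that gene's expression). The statistic

$$T_{\mathrm{SMR}} =
  \frac{z_{\mathrm{GWAS}}^2\,z_{\mathrm{eQTL}}^2}
       {z_{\mathrm{GWAS}}^2 + z_{\mathrm{eQTL}}^2}$$

is referred to χ²(1). It is symmetric, sign-invariant, bounded by
min(z²), and approaches z²GWAS as the instrument grows strong — the
null calibration check in the test suite exploits that limit. No
heterogeneity (multi-instrument) test is implemented; single-instrument
SMR is the validation layer here. Genes without a qualifying instrument
are skipped and logged, and the Bonferroni correction runs over the
genes actually tested — correcting over all genes with instruments is
the conservative reading when the alternative (correcting only over
pre-selected candidates) is not clearly specified.

## Permutation evidence layers

All three permutation tests share one logic: an integer connectivity or
count statistic for the candidate set, re-computed for random gene sets
of **matched size** drawn without replacement from an explicit
background universe, with

$$p = \frac{\#\{\mathrm{perm} \ge \mathrm{observed}\}}{n_{\mathrm{perm}}},$$

reported as "< 1/n" when no permutation reaches the observed value. The
plain k/n estimator (not add-one) is used deliberately, so that a
clean exceedance of all 1 000 default permutations reports the
conventional "P < 1.0e-3". A permutation p of exactly 0 is therefore a
*censored* value, and the `below_resolution` flag carries that
information into downstream thresholding (a below-resolution result
counts as significant at any α ≥ 1/n).

Decisions that were genuinely open:

* **Cross-set edges only.** The statistic counts edges with one endpoint
  in the candidate set and the other in the reference set; edges inside
  either set are excluded, since candidate–candidate edges say nothing
  about enrichment *with the reference*. The count is symmetric in the
  two sets.
* **Overlap handling.** A gene in both sets is counted on the reference
  side; its edges to true candidates remain cross-set edges, and it is
  excluded from the permutation draw.
* **Background pool.** Permutation draws exclude the reference set —
  otherwise drawn sets could score by containing reference genes
  adjacent to other reference genes, inflating the null. The background
  universe itself must be supplied explicitly; the package does not
  presume a genome.
* **Missing genes shrink the draw.** Candidates absent from the network
  (or flat/absent in an expression cluster) cannot contribute edges, so
  each permutation draws only as many genes as are measurable, keeping
  observed and permuted statistics comparable.

The co-expression layer builds, per brain-region cluster, the graph
connecting gene pairs with |Pearson r| > `coexpr_r_threshold` (default
0.8) across the cluster's samples. The canonical four-cluster map
(visual/temporal, prefrontal–motor–somatosensory, striatum–
hippocampus–amygdala, thalamus–cerebellum) ships as
`brain_region_clusters()`. Correlations are computed over all samples
assigned to the cluster; an alternative (correlating donor-level
averages) would reduce effective sample size and is not implemented.
Genes with zero variance in a cluster have undefined correlations and
are excluded from edges (logged), not errored, so flat genes cannot
abort a batch run.

## Developmental expression pattern

Trajectories are min–max standardized per gene across all of the gene's
samples: x' = (x − min)/(max − min), mapping each gene onto [0, 1]. A
constant gene maps to all zeros with a warning rather than an error
(again so that flat genes do not abort batch runs); since the early/late
comparison uses a strict inequality, such genes simply never count as
early-high.

Ages are a single real axis in **post-conception days** with stage
labels attached as metadata — this avoids mixed week/month/year
arithmetic. The early window is age ≤ `early_stage_max` (default 400
days ≈ conception through ~4 months after birth) and the late window is
age ≥ `late_stage_min` (default 3200 days ≈ 8 years onward);
intermediate ages are deliberately ignored, since the scientific claim
being tested contrasts the embryonic/fetal program with the mature
brain.

The set-level statistic is the **count of candidate genes whose mean
normalized expression is strictly higher in the early window than in
the late window**. "Having the early-high pattern" is not uniquely
defined for a permuted gene set; the count statistic was chosen because
it matches the per-gene reading of the claim, is integer-valued with an
exact enumeration oracle at small sizes, and is invariant under
per-gene positive affine transforms of expression (which min–max
standardization makes exact). Under the null each gene is early-high
with probability ½, so the resolution of the test is limited by the
candidate count: with 8 measurable candidates the best attainable
meaningful p is about 0.5⁸ ≈ 0.004.

## Case–control differential expression

`de_test()` is the classical pooled-variance two-sample Student's
t-test (the unequal-variance form is a switch), two-sided, per gene and
region; `de_scan()` requires at least two cases and two controls per
region and reports **raw** p-values — the CFG layer, not this stage,
applies its significance threshold, because the evidence channel is
"differentially expressed in at least one region with a consistent
direction", not a family-wise claim over all genes and regions. Zero
pooled variance is an error at the single-test level and a logged skip
at scan level.

## CFG integration

Nine channels, one point each, in fixed order: discovery scoring, PPI,
co-expression, differential expression, replication scoring with an
independent eQTL panel, SMR, and three externally supplied channels
(brain-structure association, cognition association, functional
assays). Unit weights are used; weighted CFG variants exist in the
literature but introduce arbitrariness the cumulative count avoids.
The in-pipeline award rules are:

* channels 1, 5, 6: Bonferroni-corrected p < α (default α = 0.05);
* channels 2, 3: the set-level permutation p must be significant (or
  below resolution), **and** the gene itself must have at least one
  cross-edge to the reference set (in at least one significant cluster
  for co-expression). A set-level test alone cannot attribute evidence
  to an individual gene; the cross-degree requirement is the minimal
  per-gene attribution. When the CFG stage is driven from written stage
  tables alone (the standalone `cfg` subcommand), per-gene cross-degrees
  are unavailable and the channel falls back to the set-level rule —
  the in-pipeline path is the reference behaviour;
* channel 4: raw p < α in ≥ 1 region with a consistent direction across
  all significant regions;
* channels 7–9 default to `FALSE` when no external file is supplied
  (logged), since they come from resources and experiments outside the
  pipeline's scope.

Ranking is by descending score, ties broken by descending discovery LBF
and then lexicographic gene id; exact (score, LBF) ties share a tie
group. Because the external channels default to false and channels 1, 5,
6 require multiple-testing-corrected significance, scores are
conservative: a gene with no genetic evidence cannot be rescued by a
single noisy expression result.

## The synthetic-data module

The generators are pure functions of their parameters and a seed
(`withr::with_seed`; the global RNG state is untouched), and every
fixture writes a planted-truth ledger alongside the data.

* `gen_gwas_eqtl()` plants the overlap structure the integrative score
  assumes: every gene gets eSNPs with strong eQTL z (|z| ~ N(7, 1) by
  default — instrument-grade, as brain eQTL used for this purpose are),
  and only the planted risk genes' eSNPs carry GWAS signal
  (|z| ~ N(5, 1); all other SNPs are N(0, 1)). SNPs are independent; no
  LD is simulated, because nothing in the implemented methods models
  LD. Setting the GWAS effect to 0 yields the exact null.
* `gen_expression_panel()` emulates a developmental brain atlas plus a
  case–control cohort in one panel: donors spanning ~8 post-conception
  weeks to ~40 years measured across brain regions (diagnosis `NA`),
  and adult cases/controls in three regions (hippocampus, prefrontal
  cortex, striatum; 19 vs 19 by default, matching the case–control
  cohort size the differential-expression layer is designed around).
  Planted structure: early-high genes decline multiplicatively by the
  `decay` factor (default 0.7) from the early to the late window,
  linear in log-age between; co-expression block genes share a
  per-sample latent factor (pairwise r ≈ loading²/(loading² +
  noise²)); differentially expressed genes are shifted by `de_shift`
  (default 2 expression units = 2 noise SDs, a realistic
  microarray-scale effect) in cases with a random recorded direction.
* `gen_network()` is a G(n, p) background (default edge probability
  0.02) with cross-set pairs between the planted candidate set and the
  reference set drawn at an elevated probability instead (each pair
  drawn exactly once, including pairs inside the overlap).
* `gen_study_fixture()` composes the three with coherent truth at desk
  scale: 100 genes × 5 eSNPs, 3 risk genes, a 60-gene reference set
  (standing in for a ~374-gene GWAS-significant list), 42 developmental
  donors across the 16 canonical regions, 19 + 19 cases/controls, and a
  replication eQTL panel against the same GWAS. In the fixture the risk
  genes are simultaneously early-high, differentially expressed,
  co-expressed with part of the reference set, and PPI-enriched — the
  fully convergent scenario. The block factor loading in this composed
  fixture is 6 rather than 1: risk genes also carry the developmental
  trajectory, whose variance would otherwise dilute their correlation
  with flat reference genes below the 0.8 edge threshold.

**What passing tests show — and don't.** The calibration suites show
the p-values are uniform and the rejection rates nominal *under the
generators' assumptions*: independent SNPs, Gaussian noise, homogeneous
variance, no batch or ancestry structure, exchangeable background
genes. Real GWAS/eQTL data violate several of these (LD above all), so
recovery rates on fixtures are upper bounds on real-data performance,
and the package makes no claim to reproduce any published per-gene
score, which would require the original external datasets and the
original tools' full models.

### Problem sizes in the test and acceptance suites

Simulation sizes were chosen as the smallest that make each check
statistically meaningful: 20 replicate studies for recovery rates;
200 replicate fixtures per Kolmogorov–Smirnov uniformity check
(against the 99% band); 100 000 draws for the SMR null rate (±0.1%
Monte-Carlo error); 10 000 permutations when comparing against exact
enumeration. Two calibration fixtures deviate from the headline study
shape for statistical reasons: the pattern-uniformity fixture uses 200
candidate genes (the early-high count statistic is integer-valued, and
a KS band is only meaningful when its largest null atom, ≈√(2/πm), is
small), and the co-expression-uniformity fixture uses 5 samples per
cluster so that null |r| > 0.8 edges occur at all. The planted
pattern-power fixture draws its 8 candidates against a 600-gene
background: the test draws permuted sets from the background *including*
the planted genes (as a genome-scale draw would), and the background
must be large enough that this contamination is negligible.

## Degenerate inputs and conventions

* Duplicate SNP ids, duplicate (SNP, gene) pairs, p outside (0, 1],
  inconsistent z/p pairs (relative tolerance 1e-6), and unknown
  cis/trans tokens are errors naming the offending record; an empty
  eQTL file is a warning plus an empty collection.
* Gene identifiers are opaque, case-sensitive strings; no symbol-alias
  resolution is attempted.
* eSNP lists sort by ascending p with lexicographic snp-id tie-break;
  instruments tie-break the same way; gene sums agree with their parts
  to 1e-12.
* A gene absent from the eQTL table has no eSNPs (empty result); a gene
  with eSNPs but no matching GWAS records is not testable (error at the
  single-gene level, logged skip in scans).
* A candidate set with no measurable genes yields observed 0 and p = 1
  in every permutation test; a cluster with fewer than 3 samples is an
  error.
* Result tables are tab-separated with '#' comment lines; doubles are
  serialized at 17 significant digits so write-then-read round-trips
  exactly. The run manifest records config, seed, per-stage seeds and
  input checksums, and contains no timestamps, so a rerun with the same
  seed and inputs is byte-identical.

## Known limitations

No LD modelling or multi-SNP instruments; no covariate adjustment or
expression normalization beyond what the input panel provides (values
are tested as given — whether to log-transform is the caller's
decision); Pearson correlation only; no within-degree network
permutation (the cross-set draw is the implemented null); external CFG
channels are inputs, not computations. These bounds are intentional:
each matches the scope of the analysis the package implements.
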