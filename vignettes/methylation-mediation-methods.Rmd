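---
title: "Methods: mapping meQTLs and testing methylation-mediated genetic risk"
author: "meQTLmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping meQTLs and testing methylation-mediated genetic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meQTLmediate)
```

# Overview

Most risk variants for immune-mediated diseases such as rheumatoid
arthritis are noncoding, and a prominent hypothesis is that they act by
altering CpG methylation in disease-relevant immune cells, which in turn
perturbs transcription of nearby genes. `meQTLmediate` implements the
full analysis chain needed to interrogate that hypothesis in isolated
cell subsets (for example CD4+ T cells and B cells):

1. SNP quality control and an additive linear **meQTL scan** of every
   SNP-CpG pair, with cis/trans classification and genome-wide
   Benjamini-Hochberg FDR;
2. **LD clumping** of associations into independent signals, and LD-block
   proxy lookup for intersecting GWAS risk loci with the meQTL landscape;
3. **Bayesian colocalization** of the disease and methylation signals via
   Wakefield approximate Bayes factors;
4. windowed Spearman **eQTM mapping** between CpG methylation and
   transcript abundance;
5. a four-component **causal inference test (CIT)** on (variant, CpG,
   transcript) triplets, run forward and in reverse, with
   permutation-based FDR;
6. **annotation enrichment** of risk CpGs (chromatin states, TFBS), a
   Storey-type cross-cell-type sharing estimate, opposing-effect
   detection and an allelic expression imbalance test.

Because individual-level patient data of this kind cannot be shipped,
the package carries a first-class synthetic-cohort generator with
planted causal structure; every stage is validated against it.

# The synthetic cohort

`simulateGenotypes()` draws two haplotypes per sample. SNPs are
organised in LD blocks; within a block each SNP copies the previous
SNP's allele with probability `ldRho` and otherwise draws a fresh
Bernoulli allele at the block's minor allele frequency. This makes
genotypes marginally Hardy-Weinberg while the dosage correlation between
adjacent SNPs is approximately `ldRho` (and decays geometrically with
lag), so clumping and proxy-lookup logic can be exercised at a tunable
r². Block MAFs are drawn from `mafRange`; blocks are physically compact
(5-25 kb SNP spacing) on one or more chromosomes.

`simulateCohort()` adds a diagnosis label (default 40% cases,
independent of genotype so that interaction effects are the only
phenotype-linked signal), age/sex covariates, and methylation and
expression matrices. Planted triplets follow the four regulatory models
used throughout:

* **causal**: `M = a*G + e`, `T = b*M + e'` (methylation mediates),
* **reactive**: `T = c*G + e`, `M = b*T + e'` (expression mediates),
* **independent**: `M = a*G + e`, `T = c*G + e'` with independent
  errors,
* **null**: noise only.

Methylation is generated on the M-value scale with beta-values derived
as `beta = 2^M / (2^M + 1)`. M-values are variance-stabilized and suit
linear modelling; a matching beta-scale matrix is emitted for workflows
that prefer it. Default residual SDs are 0.5 M-value/expression units,
a realistic noise floor for array data; the cohort default of 120
samples mirrors an early-arthritis cohort of ~100-140 genotyped
patients.

What the generator does **not** emulate: array probe biases, cell-type
composition artefacts, population structure, and realistic genome-wide
LD (blocks are exchangeable and block-local). Passing tests therefore
demonstrate correctness of the statistical machinery under its stated
assumptions, not robustness to every failure mode of real data.

# The meQTL scan

For each SNP-feature pair the scan fits ordinary least squares of the
trait on allele dosage plus an intercept and covariates, reporting the
slope per alt allele, its SE, t statistic and two-sided p with `n - k`
residual degrees of freedom. The implementation residualizes traits and
dosages on the covariate design once (Frisch-Waugh-Lovell), after which
every pair reduces to cross-products; this is algebraically exact OLS,
verified against `lm()` to 1e-8 in the tests.

Choices worth noting:

* **Additive dosage coding** (0/1/2 or imputed dosage), the standard for
  QTL scans.
* **Missing dosages are mean-imputed per SNP** rather than dropped
  pairwise, keeping one design per SNP; the observed count is recorded
  in `n`.
* **cis** means same chromosome and distance strictly below 1 Mb;
  everything else, including all cross-chromosome pairs, is **trans**.
* FDR is Benjamini-Hochberg **across all tests jointly** (cis and trans
  together).
* SNP QC removes call rate < 0.98, MAF < 0.01 and INFO < 0.8 (strict
  inequalities: a SNP exactly at a bound survives), and the scan
  requires 3+ individuals per genotype class, or 8+ heterozygotes when
  minor-allele homozygotes are absent.
* The Genotype x Diagnosis interaction scan additionally requires the
  class rule **within each diagnosis group**, preventing spurious
  interactions driven by group-specific monomorphism.

Confounder adjustment uses protected residual PCA
(`inferCovariates()`): the trait matrix is residualized on protected
covariates (e.g. diagnosis) and the top principal components of the
residuals are appended as covariates. This reproduces the role of
surrogate-variable-style adjustment with a deterministic construction;
it will capture strong structured confounding (batches, composition)
but, unlike iterative surrogate estimation, makes no attempt to
re-weight features by their association with the primary variable.

# Clumping, LD blocks and GWAS intersection

LD is measured as the squared Pearson correlation of dosages (composite
LD); phase is not needed and the measure is invariant to allele flips.
Clumping is greedy: the smallest-p unassigned association leads, and
every unassigned associated SNP within 1 Mb at r² >= 0.8 joins its
clump; ties in p break lexicographically by SNP id so output is
deterministic. Clumps partition the input, and raising the r² threshold
can only increase the number of clumps. The defaults (r² 0.8, 1 Mb) are
conventional for defining independent signals.

A GWAS risk locus is represented by the LD block of its index variant
(`ldBlock()`: every SNP within the window at r² >= threshold, the block
interval spanning the proxies). A locus is meQTL-positive when any
clump lead or member falls in the block, which lets a locus be
recovered even when its index variant itself was never tested.

# Colocalization

Per-SNP evidence is summarized by the Wakefield approximate Bayes
factor: with `V = se^2`, `W = priorSd^2`, `r = W/(V+W)`, `z = beta/se`,

$$\log \mathrm{ABF} = \tfrac12 \log(1 - r) + \tfrac12 z^2 r .$$

`colocPosteriors()` enumerates the standard five hypotheses (no
association; trait 1 only; trait 2 only; two distinct causal variants;
one shared variant) with per-SNP priors `p1 = p2 = 1e-4`,
`p12 = 1e-5`, evaluated in log space with log-sum-exp. The prior SD
defaults to 0.15 for quantitative traits (0.2 is conventional for
case-control log-odds). A locus "colocalizes" when `PP4 > 0.75` and
`PP4/PP3 > 5`; a PP3 of exactly zero passes the ratio by definition,
avoiding a 0/0 ambiguity. The enumeration is tested against a
brute-force oracle over explicit SNP configurations to 1e-12.

# eQTM mapping

For each CpG of interest, every transcript anchored within ±500 kb on
the same chromosome is tested with Spearman rank correlation (average
ranks for ties; exact p for n <= 10 without ties, t-approximation
otherwise), and BH FDR is computed across all tested pairs in the run,
not per CpG. The window is anchored at the CpG; the transcript anchor
is its map position (the TSS when the map provides it). Covariates are
*not* regressed out before ranking by default — the analysis models a
plain correlation — but a `covariates` argument enables rank
correlation on residuals. An inverse direction (rho < 0) is consistent
with the repressive role of promoter methylation, and on synthetic
cohorts with negative mediator-outcome effects the inverse fraction
among true positives approaches 100% as noise shrinks.

# The causal inference test

For a triplet (L = dosage, M = CpG methylation, T = transcript), the
forward CIT asks whether the data support the chain L -> M -> T. It is
an intersection-union test: the omnibus p is the **maximum** of four
component p-values, so every condition must hold.

1. `p1`: T associated with L (F-test of the genotype classes in
   `T ~ L`);
2. `p2`: M associated with L given T (F-test of L in `M ~ L + T`);
3. `p3`: T associated with M given L (F-test of M in `T ~ M + L`);
4. `p4`: an equivalence test that L is independent of T given M.

Genotype enters every component as a categorical factor with up to 2
degrees of freedom, which is robust to non-additive allelic effects.

Component 4 needs care: it must *accept* conditional independence. The
observed F statistic for L in `T ~ L + M` is compared against
surrogate datasets in which M is permuted **within the genotype classes
of L**. The surrogates preserve the marginal L-M association (class
means are untouched) while destroying the residual M-T coupling, so
they represent the "no mediation" world; `p4` is the proportion of
surrogate F values at or below the observed F. Under true mediation,
conditioning on the real M absorbs L's effect on T and the observed F
falls in the left tail (`p4` small); under the independent model the
real M explains nothing beyond its class means and `p4` is large. This
is one concrete, reproducible construction of the published test's
fourth condition; bit-compatibility with other implementations is not
claimed. The permutation loop is implemented in compiled code via a
Frisch-Waugh-Lovell decomposition, so only a rank-1 projection and a
2x2 solve remain per surrogate.

The reverse test swaps M and T (transcript as mediator), probing
reverse causation; swapping twice reproduces the forward result
exactly.

## Permutation FDR and classification

FDR follows the permutation scheme: sample labels of L are permuted
relative to (M, T) jointly per triplet, all omnibus p-values are
recomputed (1000 permutations by default), and for each observed
threshold p\* the estimated FDR is the permutation-average count of
permuted omnibus p <= p\* divided by the observed count, capped at 1
and made monotone non-decreasing in p\*. Component-4 permutations and
FDR permutations draw from separately seeded streams, both recorded in
the result.

One estimator property matters in small batches: null omnibus p-values
concentrate near 1 (they are maxima of four components), so a
moderately small — but not significant — observed omnibus p can
receive a small estimated FDR when few triplets are tested.
`classifyTriplets()` therefore requires both `perm_fdr < 0.05` *and* a
nominally significant omnibus p (< 0.05) before calling a triplet
`mediated` (or `reverse-mediated`); this mirrors reporting practice of
giving the raw omnibus p alongside the permutation FDR. Triplets
passing in both directions are `ambiguous`.

With the package's "moderate" planted effects (`a = b = c = 0.8` per
allele, unit noise, n = 200, MAF 0.3), 200 mixed triplets (50 per
model, 200 component and 200 FDR permutations) give sensitivity above
0.9 for causal triplets with zero observed false discoveries, and
reverse calls confined to reactive triplets. Weaker chains (e.g.
`a = b = 0.5` at n = 200) sit near the power boundary of the
intersection-union construction — with a 2-df genotype factor the
marginal L-T association is then often undetectable — which is a
property of the test, not of this implementation.

# Enrichment and cross-cell comparisons

CpGs are assigned to chromatin-state or TFBS intervals supplied as BED
tracks (0-based half-open). Containment uses `start <= pos < end` with
the reported CpG position compared directly in the track's frame, and
overlaps resolve by first-in-file precedence; uncovered CpGs are
`unassigned`. The shipped 15-state-to-5-group collapse
(promoter/TSS-flanking, enhancer, transcribed, bivalent,
repressed/quiescent) lives in an editable YAML config.

Enrichment of risk CpGs against the non-risk cis-CpG background is a
two-sided Fisher exact test per label; the odds ratio is the sample
cross-product ratio, Haldane-corrected (0.5 per cell, flagged) when a
cell is zero, so that identical proportions give OR exactly 1.

Cross-cell-type sharing is quantified as pi1 — one minus a Storey-type
pi0 estimated from the p-value density above a lambda grid, smoothed
with a cubic spline and read off at the largest lambda — applied to
cell-B p-values at cell-A discovery sites. This is a declared stand-in
for the empirical-Bayes sharing analyses used with real cohorts, chosen
because it is transparent, dependency-free and calibrated (0 on
uniform p-values, and recovering a 30% strong-alternative mixture to
within 0.05 in the tests).

Opposing allelic effects between cell types are features significant
in both result sets whose lead-SNP betas disagree in sign **after
aligning to the same effect allele**; a result reported on the flipped
allele is sign-corrected, and unalignable alleles skip the feature with
a warning.

Allelic expression imbalance is a paired one-sample test on
per-individual differences between the mRNA and genomic-DNA allele
fractions at a transcribed proxy SNP in heterozygotes. Because the
measurements are pyrosequencing allele proportions rather than read
counts, a nonparametric signed-rank test is used instead of a binomial
model; for n <= 25 the null distribution is computed exactly over all
sign assignments (average ranks, so ties are handled exactly), and the
normal approximation is used beyond.

# Pipeline and reporting

`runPipeline()` chains the stages per cell type and then applies pure
set algebra: per-cell cis/trans and clump counts, risk-locus overlap
between the first two cell types (both / A-only / B-only, the total,
and the percentage of the union of represented loci, rounded to the
nearest integer to match conventional reporting), eQTM counts with the
inverse fraction, CIT calls per locus, and Venn partitions of mediated
gene sets across traits. All thresholds (cis window 1 Mb, eQTM window
500 kb and FDR 0.01, CIT FDR 0.05, PP4 0.75 with ratio 5, clump r² 0.8)
live in the config with these defaults; a YAML provenance log (seed,
cells, full parameter snapshot) is written alongside every persisted
stage table, and identical config plus seeds give byte-identical
outputs.

# Numerical and degenerate-input policy

* Zero-variance dosage vectors error in LD computations; monomorphic
  index SNPs error in block construction; monomorphic L errors in the
  CIT.
* Constant trait vectors skip the eQTM pair with a warning.
* Rank-deficient covariate designs error before any scan runs.
* All-missing SNPs are "not testable" with a warning.
* Posterior enumeration uses log-sum-exp throughout; posteriors sum to
  1 within 1e-9.
* Ties: clumping breaks p-ties by SNP id; Spearman uses average ranks;
  the signed-rank null handles tied |differences| exactly.

# Problem sizes used in validation

The shipped validation uses cohorts of 100-200 samples, 100-500 SNPs,
up to 10,000 null SNP-trait pairs for calibration, 100 replicate loci
for colocalization recovery, 200 triplets with 200+200 permutations for
CIT operating characteristics, and 10,000 p-values for the sharing
estimator — sizes chosen so the complete suite runs on a laptop-class
single core in a few minutes while keeping Monte Carlo error well below
the asserted margins.

# Known limitations

* The component-4 surrogate scheme is one defensible construction of
  the equivalence condition; other CIT implementations will produce
  numerically different (if qualitatively consistent) p4 values.
* The permutation-FDR estimator is coarse for very small triplet sets;
  the nominal-p gate in `classifyTriplets()` mitigates but does not
  remove this.
* pi1 is a sharing *estimate* under the two-group mixture view; it is
  not an effect-size-aware replication analysis.
* The simulator's LD is block-local; long-range LD and population
  structure are out of scope, as are mixed models and kinship
  correction in the scan.
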