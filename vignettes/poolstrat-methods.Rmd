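---
title: "Methods: comparing pooled and individual genotyping strategies"
author: "poolstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing pooled and individual genotyping strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolstrat)
```

## The problem

A genebank accession is a seed lot managed as one unit but genetically a
small population: landraces of a predominantly selfing crop such as common
bean are usually mixtures of a few inbred lines with residual
heterozygosity, occasionally crossed. Three genotyping designs compete for
characterising such collections:

* **in-silico pool** — every plant genotyped individually, analysed jointly
  per accession (the reference standard, ~n-fold cost);
* **seq-pool** — equal tissue from all plants pooled before one DNA
  extraction; sequencing yields per-locus reference/alternate read counts,
  from which allele frequencies are estimated but individual genotypes are
  lost;
* **single plant** — one random plant per accession.

poolstrat implements the estimators and analyses needed to compare the
three on DArT-style one-row SNP reports and read-count reports, and a
generator that produces all of it synthetically with a truth ledger.

## Estimators and statistics

**Pooled frequency.** The naive read-ratio estimator
$q_{ij} = a_{ij}/(r_{ij}+a_{ij})$ per pool sample and locus; zero total
reads is a missing cell. Given the pool's true allele content $q_w$ and
depth $d$, $\hat q$ is Binomial$(d, q_w)/d$: unbiased with variance
$q_w(1-q_w)/d$. Model-based pool-seq callers that account for sequencing
error are deliberately out of scope; the read ratio is the estimator under
study.

**Genotype frequency.** Per accession, $p = f(AA) + f(AB)/2$ over
non-missing individuals, i.e. the allele-dose mean; its support (number of
non-missing calls) is recorded per cell.

**AFD.** For biallelic loci the half-sum of per-allele absolute differences
collapses to $|q_A - q_B|$ per locus; AFD is the mean over pairwise
non-missing loci, in $[0,1]$.

**Private and fixed alleles.** On loci non-missing in both versions of an
accession: an allele is private to A iff it occurs in A while B is
monomorphic for the other allele; a fixed difference is opposite fixation.
The two categories are disjoint here — a fixed difference is not also
counted as two private alleles — because they answer different questions
(detection vs contradiction). Counts are compared between strategies with a
log-link quasi-Poisson GLM (dispersion = Pearson $\chi^2$/df) and an
analysis-of-deviance F test, the standard practice for overdispersed counts.

**Heterozygosity.** $He_i = 2 p_i q_i$. H averages over polymorphic loci
only, H′ over all loci of the accession's no-missing subset, so
$H' = H \cdot n_{poly}/n_{all} \le H$; the package enforces this identity.
With no polymorphic loci H is reported as 0 with a locus count of 0.
Frequencies for H/H′ are computed on the no-missing-within-accession locus
subset so that both pooled designs are compared on equal footing.

**Modified Rogers distance.**
$\mathrm{MRD} = \sqrt{\tfrac{1}{2L}\sum_l\sum_{alleles}(\hat p_x-\hat p_y)^2}
= \sqrt{\mathrm{mean}_l\,(q_x-q_y)^2}$, in $[0,1]$, with 1 at complete
opposite fixation. Missing cells are handled by pairwise-complete loci and
the per-pair locus count is recorded (the source analyses do not state a
missing-data policy; pairwise deletion is the least destructive choice and
is reported, not hidden). For a single plant the "frequency" is the allele
dose divided by 2 ({0, ½, 1}), which makes all three strategies
commensurable in AFD/MRD space.

**Homogeneity.** An accession is classed homogeneous when the fraction of
fixed (homozygous) loci strictly exceeds 0.92, the empirical valley between
the two observed groups of accessions.

## Structure analyses

PCoA is classical scaling of the MRD matrix (negative eigenvalues are
reported and their axes dropped; explained variance is taken over the
positive spectrum). Clustering is complete linkage, with labels put in
lexicographic order first so distance ties break deterministically. Node
support resamples loci with replacement B times (default 1000), rebuilds
MRD and the dendrogram, and counts unrooted bipartition matches.

Admixture is estimated by a binomial cross-entropy NMF: scaled genotypes
$x \in [0,1]$ are modelled as $QG$ with ancestry rows of $Q$ on the
probability simplex and ancestral frequencies $G$ bounded to
$[g_{\min}, 1-g_{\min}]$, fitted by alternating projected gradient with
backtracking (the objective is non-increasing by construction; tests assert
the trace). The frequency floor $g_{\min} = 1/(2n+2)$ is a pseudo-count
prior: without it a single mispredicted held-out genotype contributes
$-\log(\epsilon)$ nats and swamps model selection. K is chosen by masked
cross-entropy — a fraction (default 5%) of observed entries is held out,
the model fitted on the rest and scored on the mask, averaged over 5
repetitions — with the argmin selected (ties to the smallest K) and a
plateau K reported alongside. This keeps the cross-entropy model-selection
contract of sparse-NMF admixture tools without re-implementing any specific
package; the sparse-NMF α regularisation has no exact analogue here and no
extra regularisation is applied beyond the frequency floor. Note that
masked selection is *not* invariant to duplicating samples — a duplicate
lets higher-K models predict a held-out entry from its twin — which is
consistent with highly redundant panels plateauing only at large K; at
fixed K the per-sample ancestry estimates are redundancy-stable, and that
is what the tests assert.

## The filter cascade

Filters run in a fixed order: all-missing removal → RepAvg ≥ 1 → average
depth in [5, 100] → locus call rate ≥ 0.75 → monomorphic removal. The order
matters only through the call-rate step, which is always recomputed on the
samples of the dataset being filtered, so filtering per subset matches the
per-subset protocol. All thresholds are inclusive; ties at a boundary (a
call rate of exactly 0.75) are retained, and each threshold can be disabled
with NA. Minor allele frequency is computed for review but never used as a
filter; no sample-level call-rate filter is applied; no imputation is ever
performed. Filtering never alters surviving genotype values and is
idempotent.

## The synthetic generator

`syntheticConfig()` defaults encode the study conditions: 44 accessions
drawn from 2 gene pools, 22–25 plants each, technical replicates for 8
pools (52 pool samples), read depth around 50×, 5% call dropout.

* **Gene pools** follow a Balding–Nichols model: ancestral frequency
  uniform on [0.1, 0.9], pool frequency Beta-distributed with divergence
  F = 0.4 — a single-knob standard model producing the strong two-pool
  structure observed in domesticated common bean.
* **Accessions** mix a configurable number of inbred lines (default
  alternating 1 and 3, i.e. half homogeneous, half seed mixtures). Lines
  are homozygous draws from the pool frequencies, heterozygous at rate
  0.005 per locus (residual heterozygosity). Individuals are selfed progeny
  of a uniformly chosen line — heterozygous line loci segregate 1:2:1 — or,
  with probability 0.02, F1s between two lines (a low outcrossing rate, as
  expected for a mostly autogamous species).
* **Pool sequencing**: plant DNA contributions are Dirichlet-weighted
  (concentration 10: slightly uneven, reflecting imperfect tissue
  normalisation); locus depth is gamma-Poisson, with the gamma
  "representation factor" (shape 5) shared by all samples, replicates and
  both report types of a panel, because locus depth is a property of the
  restriction fragment — marginally depth is negative-binomial with mean
  50. Both reports' AvgDepth metadata carry the marker-level mean depth.
  Technical replicates share the DNA pool (weights and locus factors) and
  differ only in sequencing draws. Alternate reads are binomial given
  depth; zero depth is missing.
* **Individual genotyping** applies per-call dropout (5%) and optional
  heterozygote-to-homozygote allelic dropout (off by default so truth
  recovery stays exact); RepAvg is 1 for 90% of loci with a tail in
  [0.95, 1).

The truth ledger records pool assignments, line genotypes, realised
accession frequencies (exactly the mean allele dose of the generated
plants) and pool-weighted frequencies, and is the oracle for the
recovery tests. What the generator does **not** emulate: sequencing error
(so no false rare alleles, the main caveat of the naive estimator on real
data), marker ascertainment and the reference-free calling pipeline,
linkage, selection, and non-random missingness. Passing tests therefore
demonstrate correctness of the estimators and the internal consistency of
the comparison, not robustness to those real-data artifacts.

## Numerical and interface choices

* Genotypes are stored as alternate-allele counts; the native DArT one-row
  coding (0 = reference homozygote, 1 = SNP homozygote, 2 = heterozygote,
  "−" = missing) and a plain 0/1/2 coding are explicit, tested dialect
  maps. Missingness is NA, never 0.
* The exact column layout of provider read-count files varies; the reader
  accepts a documented wide (two rows per locus) and long form, and the
  writer emits the wide form.
* Replicate pools are compared, never merged; accession-level pooled
  frequencies use the first replicate unless averaging is requested.
* Pool genotype calls (used where an analysis needs calls, e.g. admixture)
  are reference-free: only-ref → 0, only-alt → 2, both → 1, no reads → NA.
* Single-plant runs use per-run seed = base seed + run index, all recorded;
  the original study's seed is unknowable, so single-plant results are
  assessed distributionally across runs rather than by exact reproduction.
* Degenerate inputs: zero shared loci (AFD/MRD) and all-zero GLM groups are
  hard errors; all-missing loci in admixture are dropped with a warning;
  zero-locus datasets write header-only files that round-trip.
* Reported Results-text values of H and H′ in the source study conflict
  with the stated definitions (H′ includes monomorphic sites and cannot
  exceed H); this package implements the definitions and enforces
  H′ ≤ H.

## Problem sizes

The test suite and the acceptance script run synthetic panels of 44
accessions at 600–2,000 loci, 1,000 replicate pools for estimator recovery,
B = 1000 bootstrap replicates and K ∈ 1..5 with 5 masked repetitions —
sizes at which every Monte-Carlo margin asserted in the tests is stable
across seeds while a full run stays within a few minutes on one CPU.

## Limitations

Sequencing error and allele-dropout biases of real reduced-representation
data are not modelled; the naive estimator is known to inflate rare-allele
frequencies in their presence. Observed heterozygosity is intentionally
absent (it is only estimable from individual genotypes). The admixture
stand-in shares the model-selection contract, not the algorithm, of
sparse-NMF tools; on highly redundant panels its selected K grows with
redundancy, as such tools also exhibit.
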