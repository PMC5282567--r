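---
title: "cernet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cernet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

`cernet` reconstructs competing-endogenous-RNA (ceRNA) regulatory
networks from case--control transcriptome profiles and evaluates
circulating biomarkers derived from them. This vignette documents the
statistical machinery, the tunable parameters, the synthetic-data design
that stands in for patient data, and the numerical conventions the
implementation commits to.

## The analysis model

The pipeline follows the multistage design typical of ncRNA biomarker
studies in mitochondrial myopathy: a discovery screen on pooled
case/control profiles, a network-based nomination of candidate
regulators, and a per-subject validation/diagnostic phase.

**Differential expression.** Expression values are treated as continuous
positive quantities (microarray signal intensity for miRNA, FPKM for
lncRNA/mRNA) and modelled log-normally; all tests operate on the log2
scale. The default per-feature test is Welch's t when both groups have
at least three samples, otherwise the Mann--Whitney U test. The
Mann--Whitney p-value is computed by exact enumeration of all
$\binom{n_1+n_2}{n_1}$ group assignments when both groups have at most 8
samples, and by the tie-corrected normal approximation (without
continuity correction) otherwise; all-tie features give p = 1.
Multiple testing uses Benjamini--Hochberg step-up control (Bonferroni
available). Two nested screens are applied:

* *DE screen* (network substrate): |fold change| > 2 and q < 0.05, both
  strict;
* *candidate screen* (validation nominees): |log2FC| > 1.5, raw
  p < 0.01, p computable and nonzero, and abundant expression in either
  group -- mean signal >= 500 for the microarray class or >= 30 for the
  sequencing classes, in the matrix's native units.

Strictness follows the screens' "greater than" phrasing; the abundance
floor is inclusive ("at least"). Fold changes are guarded by a
pseudocount of half the smallest positive value in the matrix, keeping
FC finite and symmetric when a group mean is zero. Paired-channel
microarray data can be normalised with `lowess_normalize()`, which fits
a locally weighted regression of M on A and subtracts it, preserving
per-feature mean intensity.

**Target prediction.** In place of external target databases (whose
versions cannot be pinned), targets are predicted by canonical seed-site
scanning on the transcript's 5'->3' strand: with the seed defined as
miRNA positions 2--8, an 8mer site is the reverse complement of
positions 2--8 followed by A, 7mer-m8 the reverse complement of 2--8,
7mer-A1 the reverse complement of 2--7 followed by A, and 6mer the
reverse complement of 2--7. Each 6mer-core occurrence is reported once
at the strongest type it supports. G:U wobble pairs are not counted; T
is normalised to U. Only 7mer-m8/8mer sites count as edge evidence by
default (`min_type`), since weaker sites are dominated by chance
matches. Precomputed interaction tables can be ingested as an
alternative evidence source. lncRNA--mRNA partners come from two
additional routes: *cis* (same chromosome, interval gap <= 100 kb by
default; gap 0 for overlap, strand ignored, boundary inclusive) and
*trans* (expression correlation across all samples, |r| >= 0.9,
Pearson by default). Both windows/thresholds are exposed.

**Network assembly.** Because the discovery phase of the emulated design
profiles pooled RNA, per-sample correlation is not generally available
there; the operative "inverse correlation" criterion is therefore
*opposite DE direction* -- an up-regulated regulator may only be linked
to a down-regulated target and vice versa. An optional sample-level gate
(`require_r`) additionally demands correlation <= -r across samples
when per-sample matrices exist. The three pairwise networks
(miRNA--mRNA, miRNA--lncRNA, lncRNA--mRNA) integrate into two
tripartite views: the miRNA-centered network keeps every edge incident
to a miRNA with at least one mRNA target and one lncRNA partner, and
the lncRNA-centered network is built from the triads
$\{(l, m, g): m \to l \text{ and } m \to g\}$, in which the sign
constraint forces the lncRNA and mRNA to share a direction opposite the
miRNA's -- the ceRNA signature. "Network focus" for candidate
nomination, never formally defined in study descriptions of this
design, is operationalised as membership in at least one triad plus
degree rank (`hub_nodes()`, ties broken lexicographically). Venn
partitions compare mRNAs targeted by DE miRNAs vs mRNAs paired with DE
lncRNAs (miRNA-centered view) and miRNAs pairing with lncRNAs vs miRNAs
targeting mRNAs (lncRNA-centered view). Networks export to GraphML
(attributes preserved, read/write round-trip exact) and SIF
(`represses` relation) for Cytoscape.

**Enrichment.** Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ computed in log space, with BH correction applied within
each namespace (BP/MF/CC/pathway), mirroring the convention of
reporting GO divisions separately. The universe defaults to the genes
present in both the expression data and the collection; the rich factor
is $k/K$ over the intersected universe (the denominator choice is
documented here because tools differ). Terms below `min_term_size = 3`
are not tested.

**Biomarker evaluation.** Relative expression uses the 2^-ddCt model
with amplification efficiency fixed at 2 (efficiency-corrected models
are out of scope): replicate Ct values are averaged arithmetically
(replicate SD > 0.5 cycles is flagged), dCt is target minus reference,
ddCt subtracts the calibrator-group mean dCt, so the calibrator group's
mean rq is 1 by construction. The ROC AUC is the exact tie-corrected
pair-counting statistic, oriented so AUC >= 0.5 with the orientation
reported (`lower-in-case` for markers depleted in disease). Candidate
cutoffs are midpoints between consecutive sorted unique values; the
optimal cutoff maximises Youden's J with ties broken toward higher
sensitivity, and is reported on the original (rq) scale. Confidence
intervals and paired marker comparisons use the DeLong variance
estimator with a normal approximation, truncated to [0, 1]. Marker--
covariate association defaults to Spearman (lactate and severity scores
are typically skewed), with the exact n!-permutation p-value for
n <= 10 and the t approximation above.

## The synthetic-data generator

The generator is a first-class module: it defines the conditions under
which the pipeline's statistical behaviour is demonstrated, and its
defaults emulate the motivating study design rather than being tuned to
any test.

* **Cohort**: 20 cases vs 20 controls (the discovery-phase size);
  per-sample matrices are emitted, with `pool_samples()` available to
  emulate the equal-amount RNA pooling used in discovery profiling.
* **Expression**: log2 values are baseline + group effect + triad
  factor + noise. Baselines are N(10, 1.5) for miRNA signal (so the
  500-signal abundance floor is exercised) and N(6, 1.5) for FPKM
  classes (around the 30-copy floor). Planted DE features receive
  +/- `planted_log2fc` (default 2, matching the |FC| > 2 screen with
  headroom) in cases; `frac_de` (default 0.2) sets the planted
  fraction, and triad members are always planted. Residual noise is
  N(0, `noise_sd` = 0.5) on the log2 scale -- log-normal rather than
  negative binomial because both microarray signal and FPKM are
  continuous.
* **Triads**: `n_triads` (default 20) disjoint (lncRNA, miRNA, mRNA)
  triples; the miRNA direction is random and both partners take the
  opposite direction. A shared latent factor with loading -1 on the
  miRNA and +1 on the partners (scale `noise_sd`) induces the
  anticorrelated co-expression a ceRNA circuit implies (pairwise
  r of about -0.5 at the defaults).
* **Sequences**: mature miRNAs are 22 nt with mutually compatible
  seeds; every planted edge receives an exact 8mer site at a random
  position of its target, and all non-edge (miRNA, target) pairs are
  scrubbed of 7mer-m8/8mer sites by bounded iterative repair (an error
  is raised if the constraints cannot be met). 6mer/7mer-A1 sites may
  survive in negatives by design: weak sites are not used for truth
  evaluation.
* **Annotation**: a pseudo-genome of 10 chromosomes x 10 Mb;
  `cis_fraction` of triad lncRNA--mRNA pairs is placed within the cis
  window (default 100 kb) on one chromosome, the rest on distinct
  chromosomes.
* **qPCR**: triplicate Ct values with independent per-sample and
  per-replicate noise (`ct_noise_sd`, default 0.25 cycles, a typical
  SYBR replicate spread); an up-regulated feature's case Ct drops by
  its planted log2FC, and the three references (U6, GAPDH and spike-in
  analogues) are group-invariant, so 2^-ddCt recovers the planted fold
  change exactly as noise vanishes.
* **Serum biomarker**: binormal on the log2 scale with the case mean
  *below* the control mean and separation
  $\delta = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$, so the theoretical AUC
  equals `biomarker_auc` (default 0.879). Clinical covariates are
  generated within cases by a single-factor Gaussian copula on the
  marker's latent normal with
  $\rho = 2\sin(\pi r_s/6)$, targeting the configured Spearman
  correlations (defaults -0.43 lactate, -0.644 NMDAS, -0.709 mutation
  load); controls draw covariates from an independent healthy
  distribution, with mutation load undefined (NA) -- severity
  covariates are only meaningful within patients. The single-factor
  construction is positive semi-definite for any |r| < 1; infeasible
  matrices are rejected.

Everything derives from one root seed through fixed per-stage offsets,
so identical configurations give bit-identical outputs regardless of
which generators are invoked.

**What the generator does not emulate** -- and hence what passing
recovery tests do and do not show: no probe-level microarray artefacts
or read-level sequencing noise (so normalisation is only exercised on
synthetic MA bias); no correlation structure beyond the planted triad
factor (real transcriptomes have pervasive co-expression, which would
raise the trans-pairing false-positive rate); no mtDNA heteroplasmy
model (mutation load is a copula covariate, not a mechanistic
quantity); Gaussian noise without outliers (real qPCR failures are
ruled out by the Ct range check instead). Recovery results therefore
demonstrate correctness of the inference machinery under its stated
model, not performance on real muscle biopsies.

## Numerical conventions and edge cases

* Threshold comparisons are strict (`>`, `<`) except abundance floors
  (`>=`); boundary cases (|log2FC| = 1.5, q = 0.05, gap = window) are
  pinned by tests.
* BH can only raise p-values, so q >= p and q <= 1 are asserted as
  output invariants.
* Intervals are 0-based half-open everywhere (seed sites, BED);
  GRanges conversion happens at the boundary.
* Degenerate all-tie features are excluded from the candidate screen
  via the "p computable and nonzero" rule and counted in a message;
  features for which the t statistic is undefined fall back to the
  exact Mann--Whitney path.
* Node ordering, edge ordering and hub tie-breaks are lexicographic
  with radix (locale-independent) sorting, and all tables are written
  UTF-8/tab-separated/LF with mandatory headers, so identical runs are
  byte-identical; timestamps are confined to `run.log` and the
  report's `timestamps` field.
* The ROC orientation flip is applied before cutoff search, and the
  reported cutoff is mapped back to the original marker scale.
* The config hash covers every semantic parameter (not the output
  directory), computed as the MD5 of the canonical JSON serialisation.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise the pipeline at
sizes chosen to make the statistical claims sharp yet quick to verify:
2,000 features at 20 + 20 samples for DE recovery (sensitivity and
observed FDR of the planted 10% at |log2FC| = 2, noise 0.5); 50 planted
triads across 60/70/80 features for network recovery; 2,000 + 2,000
subjects for AUC convergence (+/- 0.02) and 1,000 cases for Spearman
recovery (+/- 0.05); exhaustive oracle grids elsewhere (all
hypergeometric arguments to N = 12, 1,000 random scanner pairs, 500
random BH vectors, 200 tied ROC datasets). The default end-to-end
configuration (60/150/300 features, 20 triads) runs in well under a
minute on one core.

## Known limitations

* Seed scanning is a stand-in for context-aware target predictors; it
  has no thermodynamic, conservation or accessibility model, and will
  over-call sites on real UTRs relative to curated databases.
* The opposite-direction filter is a sign test, not an estimate of
  regulatory strength; with small cohorts the direction calls
  themselves carry uncertainty that propagates to the network.
* The DeLong interval is asymptotic; for very small validation cohorts
  a bootstrap would be preferable.
* The 2^-ddCt model assumes perfect doubling per cycle; efficiency
  calibration (standard curves, Pfaffl correction) is deliberately out
  of scope.
* GMT ingestion keeps the term id as the display name (the description
  column is not retained by the underlying reader).
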