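---
title: "Methods: microbiome and gene-expression survival biomarkers in resected lung cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiome and gene-expression survival biomarkers in resected lung cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`lungmicsurv` implements a complete survival-biomarker analysis for cohorts
with paired tumor/normal lung tissue 16S profiles, peripheral blood gene
expression, clinical covariates, and post-surgical follow-up. The data
model has four parts: a samples-by-features count table with a seven-rank
Greengenes-style taxonomy (`feature_table`), per-sample metadata linking
samples to patients and tissue type, a per-patient covariate table, and
per-patient survival records holding elapsed times (months from surgery)
of recurrence, new primary cancer, death, and last follow-up.

Three composite endpoints are derived from the records following the
adjuvant-trial consensus definitions: recurrence-free survival (RFS:
recurrence or death), disease-free survival (DFS: recurrence, new primary,
or death), and overall survival (OS: death). The event time is the
earliest qualifying event; otherwise the patient is censored at last
follow-up, with an event winning a tie against the censoring time. A
patient known to have died without a recorded death date has the
recurrence date carried forward as the death date; such rows are flagged
(`death_imputed`) so sensitivity analyses can drop them. Times are stored
in months (1 year = 12 months).

Covariates are dummy-coded against the lexicographically first level, so
coefficients are reproducible without hidden factor-ordering state. The
covariate screen retains variables with Wald p < 0.10 for any endpoint in
either an unadjusted or the full multivariable Cox model; multi-level
variables are tested jointly, and a non-convergent model retains its
covariate conservatively.

# Compositional treatment

Counts are compositional: only relative information is meaningful, and
sequencing depth varies by orders of magnitude. The package therefore

* **agglomerates** ASVs to each taxonomic rank by summing counts over
  identical lineages down to that rank, optionally removing groups
  unclassified at the rank (the rule used before per-rank survival
  testing, which yields rank-specific feature families);
* applies the **centered log-ratio (clr) transform**,
  $\mathrm{clr}_j(x) = \log(x_j + c) - \frac{1}{p}\sum_k \log(x_k + c)$,
  with pseudocount $c = 0.5$ by default. The transform removes the
  unit-sum constraint; rows sum to zero by construction. $c$ is
  configurable; 0.5 is common compositional practice, and $c = 0$ is
  allowed for strictly positive data (where clr is exactly
  scale-invariant);
* computes **alpha diversity** (richness and base-2 Shannon index) as the
  average over 100 rarefaction draws at a fixed depth (default 2468
  reads, the study's minimum post-filter depth). Rarefaction is without
  replacement (multivariate hypergeometric); samples below the depth are
  excluded with a warning;
* computes **beta diversity** as the Jensen-Shannon divergence on
  relative abundances with base-2 logarithms, so values lie in [0, 1] and
  $\sqrt{\mathrm{JSD}}$ is a metric; and embeds distance matrices by
  **principal coordinate analysis** (classical MDS), reporting negative
  eigenvalues rather than dropping them and fixing axis signs (first
  nonzero loading positive) for determinism.

Samples with fewer than 6000 total reads are removed before analysis,
mirroring the quality-control rule that excludes specimens
indistinguishable from negative PCR controls in low-biomass lung tissue.

# Community tests

Three complementary comparisons of tumor versus normal lung:

* **PERMANOVA** (single factor) partitions squared JSD into between- and
  within-group components; the pseudo-F is tested by permuting labels,
  restricted to within-patient exchanges when patient strata are given.
  One factor at a time suffices for every use here (tissue contrasts and
  one-at-a-time covariate tests); multi-factor partitioning is out of
  scope.
* The **paired-distance permutation test** compares the mean within-pair
  JSD to the means of random tumor-to-normal bijections, reporting both
  an add-one permutation p-value and the 5th-percentile decision rule
  (observed mean below the 5th percentile of permuted means = pairs more
  alike than chance).
* **Per-feature paired Wilcoxon signed-rank tests** on clr differences,
  with the exact null for at most 25 non-zero pairs (no ties) and the
  continuity-corrected normal approximation otherwise; zero differences
  are dropped per convention. False-discovery-rate adjustment
  (Benjamini-Hochberg step-up, implemented and oracle-tested in-package)
  is applied within each taxonomic rank separately, never across ranks.

Permutation p-values use the add-one estimator
$(1 + \#\{stat_{perm} \ge stat_{obs}\})/(1 + B)$ and are therefore never
exactly zero; a 5000-permutation test bottoms out at $p \approx 2\times10^{-4}$,
matching the convention of reporting "p < 0.0001".

# Survival selection

Each biomarker family (one taxonomic rank of clr taxa, clr pathways, or
log2 genes) is screened in two coupled ways:

1. **Per-feature adjusted Cox models** (Efron ties) of each endpoint on
   the biomarker plus the screened covariates, with BH adjustment within
   the family. An optional cluster argument gives a sandwich variance for
   designs with several samples per patient. Monotone-likelihood fits are
   flagged with infinite confidence limits instead of erroring, so scans
   complete.
2. **Stability selection**: R repetitions (default 500) of K-fold
   (default 10) cross-validated elastic-net penalized Cox regression at
   mixing parameter alpha = 0.5 — chosen so correlated predictors can
   enter together — with the clinical covariates included *unpenalized*
   in every model. Folds are stratified by event status so no fold is
   event-free at small n. Each repetition selects the penalty minimizing
   cross-validated partial-likelihood deviance (configurable to the
   one-standard-error rule), refits on all data at that penalty, and
   counts features with nonzero coefficients. The penalized solver is
   `glmnet`; the repetition loop, fold construction, seeding
   (repetition r uses seed + r) and accounting are owned and tested here.

The selection rule keeps features chosen in at least 25% of repetitions
(125 of 500) *and* with q < 0.20 in the adjusted Cox scan of the same
family. Features are standardized inside the penalized fit only (penalty
fairness); reported effects are on the original clr/log2 scale.
Associations among selected biomarkers use Spearman correlation, with a
partial variant (rank-transform, residualize on the covariate design,
correlate residuals, t-approximate p on $n - 2 - p$ degrees of freedom)
for covariate-adjusted questions.

Because fold draws are tied to the repetition seed and sample order, the
selection *counts* are reproducible for a fixed seed and input order;
per-feature Cox scans are additionally invariant to permuting sample
order.

# Risk prediction

Nested Cox models — covariates only; plus microbiome; plus genes; plus
both — are compared by the cumulative/dynamic time-dependent AUC with
inverse-probability-of-censoring weights from the Kaplan-Meier estimate
of the censoring distribution (the default estimator of the standard
time-dependent ROC tooling). Cases at horizon t are patients with an
event by t (weight $1/\hat G(T_i^-)$), controls are patients event-free
past t (weight $1/\hat G(t)$); tied scores count one half. Without
censoring the estimator reduces exactly to the Mann-Whitney AUC, which is
how it is oracle-tested. The default horizons are annual, 12-60 months.

Uncertainty: percentile 95% intervals from bootstraps of patients
(default 1000), refitting the Cox model per resample (refit-per-resample
is the default; the alternative of fixed coefficients is a documented
configuration choice). Added discrimination of a biomarker block over the
covariate model is tested by permuting the rows of the tested block(s)
across patients — jointly within a block, independently across blocks —
while leaving outcomes and covariates linked, refitting the augmented
model, and recomputing the AUC difference; the add-one p-value and the
95th-percentile decision are both reported. AUC models are apparent
(in-sample), matching the small-cohort setting they mirror; optimism
correction is deliberately omitted.

# The synthetic cohort generator

Every stage is tested against a generator whose defaults emulate the
target study's structure: 46 patients; a nested taxonomy of 6 phyla, 10
classes, 19 orders, 27 families, 41 genera and 13 classified species over
an ASV pool; log-normal sequencing depths (median 20,000 reads);
paired tumor/normal samples; ~15%/11% missing tumor/normal tissue; and a
small fraction of death dates masked to exercise the imputation rule.

Compositions are logistic-normal rather than Dirichlet so that (a)
clade-level random effects induce a rank-tree correlation structure and
(b) the tumor and normal latent vectors of a patient can share a common
patient deviation with mixing weight `rho_pair` (default 0.9; at 0 the
pairing carries no signal). Counts are multinomial at the drawn depth, so
per-sample totals match depths exactly. Survival times are exponential
with hazard
$\lambda_0 \exp(\beta^\top \mathrm{clr}(\text{signal genera, normal-lung
latent composition}) + \beta_g^\top \log_2(\text{genes}) +
\gamma^\top z)$, with independent uniform administrative censoring
(24-146 months), a post-recurrence death process, and an independent
new-primary process — so RFS, DFS and OS genuinely differ. The
exponential baseline is a deliberate simplification: sampling is closed
form and Cox estimation is semiparametric anyway. Planted effect sizes
are chosen for test power (no real-data effect scale exists on the clr
scale); the default beta of 0.8 per clr unit at n = 150 gives high but
not saturated selection power. One integer seed drives documented
sub-streams (taxonomy, covariates, compositions, genes, survival at seed
+ 1..5), so any sub-draw can be regenerated in isolation.
`inject_contaminants()` adds depth-independent Poisson features whose
relative abundance is anticorrelated with depth — the frequency signature
of reagent contamination (contaminant *removal* algorithms are out of
scope; only the read-count filter is reproduced).

What the generator does not emulate: real taxon co-occurrence networks,
batch effects beyond depth variation, PCR/chimera artifacts, and
zero-inflation beyond what the logistic-normal-multinomial produces.
Passing tests therefore demonstrate correctness of the statistical
machinery under a controlled truth, not field performance on real lung
microbiome data.

# Numerical and design choices

* Pseudocount 0.5 (configurable); base-2 logs for Shannon and JSD;
  rarefaction without replacement. All three are conventions the source
  analyses leave unstated; they are fixed here and documented.
* JSD is computed on proportions of the filtered table (configurable in
  principle to rarefied counts; proportions are the default).
* Permutation p-values: add-one estimator everywhere; decision rules
  (5th/95th percentile) reported alongside.
* Wilcoxon: exact for <= 25 non-zero pairs without ties, else normal
  approximation with continuity correction; zeros dropped, mid-ranks for
  ties.
* Elastic-net penalty path: `lambda` chosen at minimum CV deviance by
  default (`lambda_rule = "1se"` available). The path resolution
  (`nlambda`) and lower end (`lambda_min_ratio`) are exposed; simulation
  studies use a coarser, truncated path (30 points down to 5% of the
  maximal penalty) after verifying selections match the default path on
  reference cohorts — the CV optimum never sits in the dense
  near-saturated tail when only a few features carry signal, and
  truncating it makes repeated-CV studies tractable on one CPU.
* Cox ties: Efron. Degenerate resamples/folds: bootstrap resamples
  without events are skipped and counted; event-free folds are redrawn
  with bounded retries.
* Deterministic outputs: PCoA axis signs fixed; run manifests echo seed
  and parameters; rerunning a config is byte-identical.

Problem sizes in the shipped tests and acceptance script (cohorts of
20-500 patients, 40-200 ASVs, repetitions of 100-500) were chosen as the
smallest sizes at which each statistical property is expected to hold
with comfortable margins, and are stated next to each test.

# Known limitations

* PERMANOVA is single-factor; no dispersion (PERMDISP) companion test.
* No phylogenetic (UniFrac) distances: no tree is modeled.
* Kernel survival association tests on distance matrices (e.g.
  MiRKAT-S) are not included.
* The stability-selection count depends on the fold RNG stream; only the
  seeded procedure, not every possible fold draw, is reproducible.
* Gene-expression preprocessing is limited to the log2 transform;
  platform normalization is assumed done upstream.

# Session

The pipeline is exercised end-to-end in `tests/testthat/` and by
`scripts/acceptance.R`; the README shows a worked example with the
numbers it prints.
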