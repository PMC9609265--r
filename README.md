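# lungmicsurv

Survival-biomarker analysis for the resected lung-cancer setting: does the
microbiome of tumor and adjacent normal lung tissue — or peripheral blood
gene expression — carry information about recurrence and death after
surgery, beyond standard clinical covariates?

The package is aimed at biostatisticians and microbiome analysts working
with paired tumor/normal 16S count tables, a normalized gene-expression
panel, clinical covariates, and post-surgical follow-up. It provides the
full analysis chain as tested, reusable functions:

* **Endpoints** — recurrence-free (RFS), disease-free (DFS) and overall
  survival (OS) derived from per-patient event histories under the
  adjuvant-trial consensus rules, including the carry-forward imputation
  of missing death dates and a p < 0.10 Cox screen for covariates.
* **Compositional tools** — taxonomic agglomeration, centered log-ratio
  transform (clr_j = log(x_j + c) − mean_k log(x_k + c)),
  rarefaction-averaged richness and Shannon diversity, Jensen-Shannon
  divergence (JSD, base 2), principal coordinate analysis.
* **Community tests** — single-factor PERMANOVA with strata (e.g. tissue
  within patient), a paired-distance permutation test of whether
  tumor/normal pairs are more alike than random pairings, per-feature
  paired Wilcoxon signed-rank tests with Benjamini-Hochberg FDR within
  each taxonomic rank.
* **Stability selection** — repeated (default 500×) 10-fold
  cross-validated elastic-net penalized Cox regression (α = 0.5,
  covariates unpenalized), counting how often each clr taxon / log2 gene
  is selected; the selection rule keeps features chosen ≥ 25% of
  repetitions with FDR q < 0.20 in the covariate-adjusted Cox scan.
* **Risk prediction** — cumulative/dynamic time-dependent AUC with IPCW
  censoring weights for nested Cox models, percentile bootstrap
  confidence intervals, and a permutation test of the AUC gain from
  biomarker blocks over covariates alone.
* **Synthetic cohorts** — a generator with planted clr-taxon, gene and
  covariate effects (paired logistic-normal compositions, multinomial
  counts, exponential-hazard survival, independent censoring) providing
  ground truth for every stage.

## Worked example

Simulate a 40-patient cohort with one harmful genus (log-HR 1.0 per clr
unit) planted in the normal-lung composition, then run the three core
questions:

```r
library(lungmicsurv)

co <- simulate_cohort(cohort_spec(
  n_patients = 40,
  n_taxa = c(phylum = 3, class = 4, order = 5, family = 6,
             genus = 15, species = 4, asv = 40),
  n_genes = 15, signal_taxa = c(g1 = 1.0),
  frac_unclassified_genus = 0, frac_unclassified_species = 0,
  p_missing_tumor = 0, p_missing_normal = 0, seed = 42))

## are tumor/normal pairs more alike than chance?
combined <- feature_table(rbind(co$tables$tumor$counts,
                                co$tables$normal$counts),
                          co$tables$tumor$taxonomy)
D <- jsd_matrix(combined)
paired_distance_test(D, sample_pairs(co$metadata), n_perm = 999, seed = 1)
#> Paired-distance test: observed mean = 0.0042 over 40 pairs; null mean = 0.2120;
#> p = 0.001 (999 permutations); pairs more alike: yes

## which genera predict recurrence-free survival?
ep  <- derive_endpoint(impute_missing_death(co$records), "RFS")
des <- build_covariate_design(co$covariates)
clr <- clr_transform(agglomerate(co$tables$normal, "genus",
                                 drop_unclassified = TRUE), 0.5)
ss  <- stability_select(ep$time, ep$event, clr[paste0(ep$patient_id, "_N"), ],
                        des, R = 100, K = 10, seed = 7)
head(ss[order(-ss$selection_fraction), c("feature_id", "selection_fraction",
                                         "hr", "q")], 3)
#>                                                       feature_id selection_fraction        hr         q
#> 2  k__Bacteria; p__Phy01; c__Cla02; o__Ord04; f__Fam03; g__Gen07               0.44 2.8446511 0.2314254
#> 8  k__Bacteria; p__Phy03; c__Cla04; o__Ord01; f__Fam01; g__Gen01               0.44 2.2405179 0.1427584
#> 14 k__Bacteria; p__Phy03; c__Cla04; o__Ord03; f__Fam04; g__Gen02               0.01 0.6096776 0.8615978
select_features(ss)   # >= 25% of repetitions and q < 0.20
#> [1] "k__Bacteria; p__Phy03; c__Cla04; o__Ord01; f__Fam01; g__Gen01"

## does the selected genus add risk discrimination over covariates?
blk <- clr[paste0(ep$patient_id, "_N"), select_features(ss), drop = FALSE]
auc_permutation_test(ep$time, ep$event, des, list(microbiome = blk),
                     t_grid = c(24, 48), n_perm = 500, seed = 3)
#>   time  auc_base  auc_full  delta_auc    p_value   null_q95 significant
#> 1   24 0.7150997 0.8062678 0.09116809 0.02195609 0.06267806        TRUE
#> 2   48 0.7700449 0.8147020 0.04465710 0.07784431 0.05413223       FALSE
```

Tumor/normal pairs are far more alike than random pairings (mean
within-pair JSD 0.004 versus a null mean of 0.21). The planted genus
(`g__Gen01`, the generator's `g1`) is the only feature passing the joint
selection rule (44% of repetitions, adjusted hazard ratio 2.2 per clr
unit, q = 0.14), and adding it raises the 24-month AUC for RFS from 0.72
(covariates only) to 0.81 — a gain the permutation test calls significant
at 24 months (add-one p = 0.022 with 500 permutations) but not at 48, as
expected for a moderate single-taxon effect at n = 40.

`run_pipeline(default_config(...))` chains all stages — filtering,
endpoints, diversity, community tests, selection, AUC — and writes tidy
TSVs plus a JSON manifest; `exec/lungmicsurv` exposes the same stages as
shell subcommands (`simulate`, `endpoints`, `diversity`,
`community-tests`, `select`, `predict-auc`, `run-all`) driven by a YAML
config.

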