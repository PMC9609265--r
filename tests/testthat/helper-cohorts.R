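# shared fixtures for the suite: a small rank tree and one mid-size cohort
# with planted effects, generated once per run

small_tax <- c(phylum = 3, class = 4, order = 5, family = 6, genus = 15,
               species = 4, asv = 40)

# a 40-patient cohort with one strong planted genus and one planted gene
demo_cohort <- simulate_cohort(cohort_spec(
  n_patients = 40, n_taxa = small_tax, n_genes = 15,
  signal_taxa = c(g1 = 1.0), signal_genes = c(gene2 = 0.6),
  frac_unclassified_genus = 0, frac_unclassified_species = 0,
  p_missing_tumor = 0, p_missing_normal = 0, seed = 42))

demo_endpoints <- derive_all_endpoints(impute_missing_death(demo_cohort$records))
demo_design <- build_covariate_design(demo_cohort$covariates)

# tiny deterministic feature table used across IO / compositional tests
tiny_counts <- matrix(c(5L, 0L, 12L,
                        3L, 7L, 2L), nrow = 2, byrow = TRUE,
                      dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
tiny_tax <- c(
  f1 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__; g__; s__",
  f2 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__Blautia; s__",
  f3 = "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__; g__; s__")
tiny_table <- feature_table(tiny_counts, tiny_tax)

# brute-force BH oracle: literal step-up definition, independent of bh_fdr
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# all-pairs Mann-Whitney AUC oracle for uncensored data at horizon t
mw_auc_oracle <- function(time, score, t) {
  case <- which(time <= t)
  ctrl <- which(time > t)
  s <- 0
  for (i in case) for (j in ctrl)
    s <- s + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  s / (length(case) * length(ctrl))
}
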