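test_that("time-dependent AUC matches the Mann-Whitney oracle without censoring", {
  set.seed(15)
  for (r in 1:5) {
    n <- 60
    tm <- rexp(n, 0.04)
    sc <- 0.5 * -log(tm) + rnorm(n)   # informative, imperfect marker
    t0 <- unname(quantile(tm, runif(1, 0.3, 0.7)))
    expect_equal(td_auc(tm, rep(1, n), sc, t0), mw_auc_oracle(tm, sc, t0),
                 tolerance = 1e-12)
  }
})

test_that("AUC is 1 for a perfect marker and invariant to monotone transforms", {
  set.seed(16)
  n <- 80
  tm <- rexp(n, 0.03)
  ev <- rbinom(n, 1, 0.8)
  sc <- -tm
  for (t0 in c(12, 24, 36)) {
    a <- td_auc(tm, ev, sc, t0)
    expect_equal(a, 1)
  }
  sc2 <- rnorm(n)
  a1 <- td_auc(tm, ev, sc2, 24)
  expect_equal(td_auc(tm, ev, exp(3 * sc2) - 5, 24), a1, tolerance = 1e-12)
  # ties contribute one half
  expect_equal(td_auc(c(1, 2, 10, 20), c(1, 1, 0, 0), c(1, 1, 1, 1), 5), 0.5)
  expect_warning(td_auc(tm, rep(0, n), sc2, 24), "no cases")
})

test_that("risk scores track the true linear predictor", {
  spec <- cohort_spec(n_patients = 300, n_taxa = small_tax, n_genes = 10,
                      signal_taxa = c(g1 = 1.0, g2 = -0.8),
                      p_missing_normal = 0, seed = 77)
  co <- simulate_cohort(spec)
  ep <- derive_endpoint(impute_missing_death(co$records), "RFS")
  X <- cbind(build_covariate_design(co$covariates),
             co$truth$clr_genus_latent[, c("g1", "g2")])
  sc <- cox_risk_score(ep$time, ep$event, X)
  expect_gt(cor(sc, co$truth$linear_predictor, method = "spearman"), 0.8)
  # a single binary covariate gives exactly two score values
  xb <- cbind(bin = rep(c(0, 1), length.out = nrow(ep)))
  sb <- cox_risk_score(ep$time, ep$event, xb)
  expect_equal(length(unique(round(sb, 10))), 2L)
})

test_that("stratified true-risk groups have ordered survival", {
  co <- simulate_cohort(cohort_spec(n_patients = 300, n_taxa = small_tax,
                                    n_genes = 5, signal_taxa = c(g1 = 1.5),
                                    seed = 31))
  ep <- derive_endpoint(impute_missing_death(co$records), "RFS")
  ter <- cut(co$truth$linear_predictor, breaks = quantile(
    co$truth$linear_predictor, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
    labels = c("low", "mid", "high"))
  sd <- survival::survdiff(survival::Surv(ep$time, ep$event) ~ ter)
  expect_lt(stats::pchisq(sd$chisq, 2, lower.tail = FALSE), 0.01)
  km <- summary(survival::survfit(survival::Surv(ep$time, ep$event) ~ ter),
                times = 36, extend = TRUE)
  expect_true(all(diff(km$surv) < 0))  # low risk survives best
})

test_that("bootstrap CIs are reproducible and collapse for a perfect marker", {
  ep <- demo_endpoints$RFS
  X <- cbind(demo_design, g1 = demo_cohort$truth$clr_genus_latent[, "g1"])
  ci1 <- bootstrap_auc_ci(ep$time, ep$event, X, t_grid = c(24, 48),
                          n_boot = 30, seed = 5)
  ci2 <- bootstrap_auc_ci(ep$time, ep$event, X, t_grid = c(24, 48),
                          n_boot = 30, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$ci_lower <= ci1$ci_upper))
  perfect <- cbind(score = -ep$time + 1e-9 * seq_len(nrow(ep)))
  cip <- suppressWarnings(bootstrap_auc_ci(ep$time, ep$event, perfect,
                                           t_grid = 24, n_boot = 30, seed = 1))
  expect_gt(cip$ci_upper, 0.99)
})

test_that("the permutation test never disturbs the base model and sees redundancy", {
  ep <- demo_endpoints$RFS
  # tested block duplicates a base covariate: no added discrimination
  dup <- demo_design[, "age", drop = FALSE]
  res <- auc_permutation_test(ep$time, ep$event, demo_design,
                              list(dup = dup), t_grid = c(24, 48),
                              n_perm = 60, seed = 2)
  expect_true(all(abs(res$delta_auc) < 0.02))
  expect_true(all(res$p_value > 0.1))
  # base AUC column is a constant of the permutation scheme by construction
  expect_equal(res$auc_base,
               td_auc_curve(ep$time, ep$event,
                            cox_risk_score(ep$time, ep$event, demo_design),
                            c(24, 48))$auc)
  expect_warning(
    auc_permutation_test(ep$time, ep$event, demo_design, list(dup = dup),
                         t_grid = 24, n_perm = 10, seed = 1), "n_perm")
})

test_that("a planted strong biomarker adds significant discrimination", {
  co <- simulate_cohort(cohort_spec(n_patients = 200, n_taxa = small_tax,
                                    n_genes = 5, signal_taxa = c(g1 = 1.0),
                                    p_missing_normal = 0, seed = 55))
  ep <- derive_endpoint(impute_missing_death(co$records), "RFS")
  des <- build_covariate_design(co$covariates)
  blk <- co$truth$clr_genus_latent[, "g1", drop = FALSE]
  res <- auc_permutation_test(ep$time, ep$event, des, list(mb = blk),
                              t_grid = c(24, 36), n_perm = 100, seed = 3)
  expect_true(all(res$p_value <= 0.05))
  expect_true(all(res$significant))
})
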