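rec <- function(recurrence = NA_real_, new_primary = NA_real_,
                death = NA_real_, fu, died = !is.na(death)) {
  data.frame(patient_id = "P1", recurrence_time = recurrence,
             new_primary_time = new_primary, death_time = death,
             last_followup_time = fu, died = died)
}

ep <- function(r, which) unlist(derive_endpoint(r, which)[, c("time", "event")],
                                use.names = FALSE)

test_that("endpoint composition follows the consensus definitions", {
  r <- rec(recurrence = 10, death = 20, fu = 20)
  expect_equal(ep(r, "RFS"), c(10, 1))
  expect_equal(ep(r, "DFS"), c(10, 1))
  expect_equal(ep(r, "OS"), c(20, 1))
  # new primaries count for DFS only
  r <- rec(new_primary = 12, fu = 50, died = FALSE)
  expect_equal(ep(r, "DFS"), c(12, 1))
  expect_equal(ep(r, "RFS"), c(50, 0))
  expect_equal(ep(r, "OS"), c(50, 0))
  # no events: censored at last follow-up
  r <- rec(fu = 60, died = FALSE)
  expect_equal(ep(r, "RFS"), c(60, 0))
  expect_equal(ep(r, "DFS"), c(60, 0))
  expect_equal(ep(r, "OS"), c(60, 0))
  # event at the censoring time wins
  r <- rec(recurrence = 60, fu = 60, died = FALSE)
  expect_equal(ep(r, "RFS"), c(60, 1))
})

test_that("missing death dates are imputed from recurrence and flagged", {
  r <- rec(recurrence = 8, fu = 8, died = TRUE)
  out <- impute_missing_death(r)
  expect_equal(out$death_time, 8)
  expect_true(out$death_imputed)
  r2 <- impute_missing_death(rec(recurrence = 5, death = 9, fu = 9))
  expect_equal(r2$death_time, 9)
  expect_false(r2$death_imputed)
  expect_error(impute_missing_death(rec(fu = 10, died = TRUE)),
               "neither death nor recurrence")
  # unimputed died-without-date records are refused downstream
  expect_error(derive_endpoint(rec(recurrence = 8, fu = 8, died = TRUE), "OS"),
               "impute_missing_death")
})

test_that("endpoint times are ordered DFS <= RFS <= OS on simulated records", {
  recs <- impute_missing_death(demo_cohort$records)
  eps <- derive_all_endpoints(recs)
  expect_true(all(eps$RFS$time <= eps$OS$time + 1e-12))
  expect_true(all(eps$DFS$time <= eps$RFS$time + 1e-12))
  # monotone: adding an earlier qualifying event never increases time
  base <- rec(recurrence = 30, fu = 40, died = FALSE)
  earlier <- rec(recurrence = 30, new_primary = 5, fu = 40, died = FALSE)
  expect_lte(derive_endpoint(earlier, "DFS")$time,
             derive_endpoint(base, "DFS")$time)
})

test_that("covariate screening retains signal at p<0.10 and all at 1.0", {
  covs <- demo_cohort$covariates
  screened <- screen_covariates(covs, demo_endpoints, p_threshold = 1.0)
  expect_setequal(screened, setdiff(colnames(covs), "patient_id"))
  set.seed(9)
  covs$planted <- demo_cohort$truth$linear_predictor + rnorm(nrow(covs), 0, 0.3)
  screened <- screen_covariates(covs, demo_endpoints, p_threshold = 0.10)
  expect_true("planted" %in% screened)
})

test_that("covariate design uses lexicographic reference dummy coding", {
  covs <- data.frame(patient_id = c("a", "b", "c"),
                     smoking = c("never", "former", "current"),
                     age = c(60, 70, 80))
  X <- build_covariate_design(covs)
  # reference level "current" (first alphabetically) is absorbed
  expect_setequal(colnames(X), c("smokingformer", "smokingnever", "age"))
  expect_equal(unname(X[, "smokingnever"]), c(1, 0, 0))
  Xr <- build_covariate_design(
    data.frame(patient_id = c("a", "b"), race = c("Hispanic", "white")),
    collapse_race = TRUE)
  expect_equal(colnames(Xr), "racewhite")
})
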