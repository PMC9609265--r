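test_that("adjusted Cox fits are reparameterization-consistent and improve on the null", {
  ep <- demo_endpoints$RFS
  x <- demo_cohort$truth$clr_genus_latent[, "g1"]
  f <- fit_cox_adjusted(ep$time, ep$event, x, demo_design)
  fneg <- fit_cox_adjusted(ep$time, ep$event, -x, demo_design)
  expect_equal(fneg$hr, 1 / f$hr, tolerance = 1e-8)
  expect_equal(fneg$p, f$p, tolerance = 1e-8)
  expect_gte(f$loglik[2], f$loglik[1])
  expect_true(f$ci_lower <= f$hr && f$hr <= f$ci_upper)
  expect_gt(f$hr, 1)  # planted harmful taxon
  expect_error(fit_cox_adjusted(c(1, 2), c(0, 0), c(1, 2)), "events")
})

test_that("cox_feature_scan is invariant to sample order and adjusts within family", {
  ep <- demo_endpoints$RFS
  X <- demo_cohort$truth$clr_genus_latent[, 1:6]
  scan <- cox_feature_scan(ep$time, ep$event, X, demo_design)
  expect_equal(scan$q, bh_fdr(scan$p))
  perm <- sample(nrow(X))
  scan2 <- cox_feature_scan(ep$time[perm], ep$event[perm],
                            X[perm, , drop = FALSE],
                            demo_design[perm, , drop = FALSE])
  expect_equal(scan2$p, scan$p, tolerance = 1e-8)
  expect_equal(scan2$hr, scan$hr, tolerance = 1e-8)
})

test_that("noise features stay near zero effect", {
  ep <- demo_endpoints$RFS
  set.seed(13)
  ok <- 0L
  for (r in 1:20) {
    f <- fit_cox_adjusted(ep$time, ep$event, rnorm(nrow(ep)), demo_design)
    if (abs(f$coef) <= 3 * f$se) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("stability selection is deterministic and ranks the planted taxon first", {
  ep <- demo_endpoints$RFS
  ag <- agglomerate(demo_cohort$tables$normal, "genus",
                    drop_unclassified = TRUE)
  clr <- clr_transform(ag, 0.5)[paste0(ep$patient_id, "_N"), ]
  s1 <- stability_select(ep$time, ep$event, clr, demo_design, R = 3, K = 5,
                         seed = 21, nlambda = 30)
  s2 <- stability_select(ep$time, ep$event, clr, demo_design, R = 3, K = 5,
                         seed = 21, nlambda = 30)
  expect_identical(s1$selection_count, s2$selection_count)
  planted <- demo_cohort$truth$genus_feature_ids["g1"]
  expect_equal(s1$selection_fraction[s1$feature_id == planted],
               max(s1$selection_fraction))
  expect_true(all(s1$selection_count >= 0 & s1$selection_count <= 3))
})

test_that("the selection rule combines the count threshold and the q threshold", {
  st <- data.frame(feature_id = c("a", "b", "c"),
                   selection_count = c(400, 100, 300), R = 500,
                   selection_fraction = c(0.8, 0.2, 0.6),
                   q = c(0.01, 0.01, 0.5))
  class(st) <- c("stability_result", class(st))
  expect_equal(select_features(st), "a")
  expect_equal(select_features(st, min_fraction = 1.01), character(0))
  expect_setequal(select_features(st, q_threshold = 1), c("a", "c"))
})

test_that("partial Spearman reduces to Spearman and removes confounding", {
  set.seed(14)
  x <- rnorm(50); y <- x^3 + rnorm(50, 0, 0.1)
  ps <- partial_spearman(x, y)
  expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(partial_spearman(x, x)$rho, 1)
  # x and y both driven by a shared covariate: adjustment removes the link
  n <- 200
  z <- rnorm(n)
  x2 <- 2 * z + rnorm(n); y2 <- -1.5 * z + rnorm(n)
  marg <- partial_spearman(x2, y2)
  part <- partial_spearman(x2, y2, covariates = cbind(z))
  expect_lt(abs(part$rho), abs(marg$rho))
  expect_gt(part$p, 0.001)
  expect_error(partial_spearman(rep(1, 10), rnorm(10)), "constant")
})

test_that("gene matrices are log2-transformed with exact inverses", {
  m <- matrix(c(8, 1, 2, 16), 2, dimnames = list(c("p1", "p2"), c("g1", "g2")))
  lg <- log2_gene_matrix(m)
  expect_equal(lg["p1", "g1"], 3)
  expect_equal(lg["p2", "g1"], 0)
  expect_equal(2^lg, m, tolerance = 1e-12)
  expect_error(log2_gene_matrix(matrix(c(0, 1), 1)), "pseudocount")
  expect_equal(log2_gene_matrix(matrix(c(0, 3), 1), pseudocount = 1),
               matrix(c(0, 2), 1))
})
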