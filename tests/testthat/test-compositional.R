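test_that("clr transform matches hand values and is centered", {
  m <- matrix(c(1, 2, 4), 1, dimnames = list("s1", c("a", "b", "c")))
  z <- clr_transform(m, pseudocount = 0)
  expect_equal(unclass(z)[1, ], c(a = -log(2), b = 0, c = log(2)),
               tolerance = 1e-3)
  u <- clr_transform(matrix(5, 2, 4, dimnames = list(c("x", "y"), letters[1:4])),
                     pseudocount = 0)
  expect_true(all(abs(u) < 1e-12))
  set.seed(1)
  big <- matrix(rpois(200, 30) + 1, 10,
                dimnames = list(paste0("s", 1:10), paste0("f", 1:20)))
  expect_true(all(abs(rowSums(clr_transform(big, 0.5))) < 1e-9))
  # scale invariance at pseudocount 0
  expect_equal(unclass(clr_transform(big, 0)), unclass(clr_transform(big * 7, 0)),
               tolerance = 1e-12)
  expect_error(clr_transform(big[, 0, drop = FALSE]), "empty")
})

test_that("agglomeration sums lineage groups and applies the drop rule", {
  ag <- agglomerate(tiny_table, "order")
  # f1 and f2 share the lineage down to Clostridiales
  clo <- grep("o__Clostridiales", feature_ids(ag), value = TRUE)
  expect_length(clo, 1L)
  expect_equal(unname(ag$counts[, clo]),
               unname(tiny_table$counts[, "f1"] + tiny_table$counts[, "f2"]))
  # identity at ASV level; unknown rank errors
  expect_identical(agglomerate(tiny_table, "ASV"), tiny_table)
  expect_error(agglomerate(tiny_table, "subspecies"), "unknown rank")
  # conservation without the drop rule
  expect_equal(sum(agglomerate(tiny_table, "genus")$counts),
               sum(tiny_table$counts))
  # drop rule removes genus-unclassified features (f1 and f3)
  dropped <- agglomerate(tiny_table, "genus", drop_unclassified = TRUE)
  expect_equal(sum(dropped$counts), sum(tiny_table$counts[, "f2"]))
  expect_match(feature_ids(dropped), "g__Blautia")
})

test_that("rarefaction-averaged alpha diversity behaves at the boundaries", {
  m <- matrix(c(10, 20, 0, 30, 0, 0), 2, byrow = TRUE,
              dimnames = list(c("mix", "mono"), c("a", "b", "c")))
  ft <- feature_table(m)
  # depth equal to the sample total: zero subsampling variance
  a <- rarefied_alpha(subset_table(ft, samples = "mix"), depth = 30,
                      iterations = 5, seed = 1)
  expect_equal(a$richness, 2)
  p <- c(10, 20) / 30
  expect_equal(a$shannon, -sum(p * log2(p)))
  a2 <- rarefied_alpha(subset_table(ft, samples = "mono"), depth = 30,
                       iterations = 5, seed = 1)
  expect_equal(a2$richness, 1)
  expect_equal(a2$shannon, 0)
  expect_error(rarefied_alpha(ft, depth = 0), "depth")
  # samples below depth are excluded with a warning, deeper ones retained
  m3 <- rbind(m, tiny = c(3, 2, 0))
  expect_warning(a3 <- rarefied_alpha(feature_table(m3), depth = 20,
                                      iterations = 2, seed = 1), "excluded")
  expect_setequal(a3$sample_id, c("mix", "mono"))
})

test_that("even two-feature sample rarefies to ~1 bit of entropy", {
  ft <- feature_table(matrix(c(5000, 5000), 1,
                             dimnames = list("s", c("a", "b"))))
  a <- rarefied_alpha(ft, depth = 2468, iterations = 100, seed = 7)
  expect_lt(abs(a$shannon - 1), 0.02)
})

test_that("rarefied means agree with an independent subsampling oracle", {
  set.seed(11)
  m <- matrix(rpois(15, 20), 5, dimnames = list(paste0("s", 1:5),
                                                c("a", "b", "c")))
  m[m == 0] <- 1
  ft <- feature_table(m)
  a <- rarefied_alpha(ft, depth = 20, iterations = 400, seed = 3)
  for (i in 1:5) {
    # oracle: explicit multiset subsample via sample() on the read vector
    x <- m[i, ]
    reads <- rep(seq_along(x), x)
    rich <- sh <- numeric(2000)
    for (b in seq_len(2000)) {
      cnt <- tabulate(sample(reads, 20), nbins = 3)
      p <- cnt[cnt > 0] / 20
      rich[b] <- length(p); sh[b] <- -sum(p * log2(p))
    }
    tol_r <- 3 * (sd(rich) / sqrt(2000) + sd(rich) / sqrt(400))
    tol_s <- 3 * (sd(sh) / sqrt(2000) + sd(sh) / sqrt(400))
    expect_lt(abs(a$richness[i] - mean(rich)), max(tol_r, 1e-8))
    expect_lt(abs(a$shannon[i] - mean(sh)), max(tol_s, 1e-8))
  }
})

test_that("JSD matches its definition and is a bounded squared metric", {
  P <- matrix(c(1, 0, 0.5, 0.5, 0, 1), 3, byrow = TRUE,
              dimnames = list(c("p", "m", "q"), c("x", "y")))
  D <- jsd_matrix(P)
  expect_equal(D["p", "p"], 0)
  expect_equal(D["p", "q"], 1)               # disjoint supports
  expect_equal(D["p", "m"], 0.3113, tolerance = 1e-4)
  expect_true(isSymmetric(D))
  # sqrt(JSD) triangle inequality on random triples
  set.seed(5)
  for (r in 1:50) {
    Q <- matrix(rexp(12), 3)
    Q <- Q / rowSums(Q)
    rownames(Q) <- c("a", "b", "c"); colnames(Q) <- paste0("f", 1:4)
    d <- sqrt(jsd_matrix(Q))
    expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"] + 1e-10)
  }
})

test_that("PCoA recovers Euclidean configurations", {
  # points on a line: a single positive eigenvalue
  x <- c(0, 1, 3, 6)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  fit <- pcoa(D, k = 3)
  expect_equal(sum(fit$eig > 1e-8), 1L)
  expect_equal(as.matrix(dist(fit$points[, 1])), unname(D), tolerance = 1e-8,
               ignore_attr = TRUE)
  # random 2-D configuration recovered exactly with k = 2
  set.seed(2)
  pts <- matrix(rnorm(20), 10)
  D2 <- as.matrix(dist(pts))
  dimnames(D2) <- list(paste0("s", 1:10), paste0("s", 1:10))
  fit2 <- pcoa(D2, k = 2)
  expect_equal(as.matrix(dist(fit2$points)), unname(D2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign convention
  expect_gt(fit2$points[which(abs(fit2$points[, 1]) > 1e-12)[1], 1], 0)
  expect_error(pcoa(D2, k = 10), "k must be")
})

test_that("distance matrices round-trip through TSV", {
  set.seed(3)
  pts <- matrix(rnorm(10), 5)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:5), paste0("s", 1:5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(D, path)
  expect_equal(read_distance_matrix(path), D, tolerance = 1e-12)
})
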