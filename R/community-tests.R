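#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1, returned in the
#' original order. Adjustment is applied within one feature family (one
#' taxonomic rank, the ASVs, the pathways, or the genes) at a time.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return vector of q-values, same length and order as `p`
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / (m:1)))[ro]
  q
}

#' Single-factor PERMANOVA with optional strata
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components for one grouping factor and tests the pseudo-F
#' statistic by permuting group labels. When `strata` is given, labels are
#' only exchanged within strata (e.g. tissue labels within patients for
#' paired tumor/normal designs). The permutation p-value uses the add-one
#' estimator `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)` and so is never
#' exactly zero.
#'
#' @param D symmetric dissimilarity matrix
#' @param labels grouping factor aligned with rows of `D` (>= 2 levels)
#' @param strata optional blocking factor restricting permutations
#' @param n_perm number of permutations (> 0)
#' @param seed optional integer seed
#' @return object of class `permanova_result`: list with `pseudo_f`, `r2`,
#'   `p_value`, `n_perm`, `df`, `strata_used`
#' @export
permanova <- function(D, labels, strata = NULL, n_perm = 999, seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- as.factor(labels)
  if (length(labels) != n) stop("labels must align with D")
  if (nlevels(droplevels(labels)) < 2L) stop("labels need >= 2 levels")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(strata)) {
    strata <- as.factor(strata)
    if (length(strata) != n) stop("strata must align with D")
  }
  if (!is.null(seed)) set.seed(seed)
  D2 <- D^2
  stat <- function(lab) {
    ssw <- 0
    for (lv in levels(lab)) {
      ix <- which(lab == lv)
      if (length(ix) > 1L)
        ssw <- ssw + sum(D2[ix, ix]) / (2 * length(ix))
    }
    ssw
  }
  sst <- sum(D2) / (2 * n)
  a <- nlevels(droplevels(labels))
  ssw_obs <- stat(labels)
  ssa_obs <- sst - ssw_obs
  f_obs <- (ssa_obs / (a - 1)) / (ssw_obs / (n - a))
  perm_labels <- function() {
    if (is.null(strata)) return(sample(labels))
    out <- labels
    for (lv in levels(strata)) {
      ix <- which(strata == lv)
      out[ix] <- labels[ix][sample.int(length(ix))]
    }
    out
  }
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    lp <- perm_labels()
    ssw_p <- stat(lp)
    f_p <- ((sst - ssw_p) / (a - 1)) / (ssw_p / (n - a))
    if (f_p >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  structure(list(pseudo_f = f_obs, r2 = ssa_obs / sst,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, df = c(a - 1L, n - a),
                 strata_used = !is.null(strata)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), R2 = %.4f, p = %.4g (%d permutations%s)\n",
              x$pseudo_f, x$df[1L], x$df[2L], x$r2, x$p_value, x$n_perm,
              if (x$strata_used) ", stratified" else ""))
  invisible(x)
}

#' Paired-distance permutation test
#'
#' Tests whether paired tumor/normal samples from the same patient are more
#' alike than random tumor-normal pairings: the observed statistic is the
#' mean dissimilarity over true pairs; the null distribution is the mean
#' over random bijections of tumor samples to normal samples. Reports the
#' add-one permutation p-value for the null mean falling at or below the
#' observed mean, the percentile of the observed mean in the null
#' distribution, and the decision under the 5th-percentile rule
#' (observed mean below the 5th percentile of permuted means).
#'
#' @param D symmetric dissimilarity matrix containing all paired samples
#' @param pairs data frame with columns `tumor` and `normal` (sample ids),
#'   disjoint across rows; >= 3 pairs required
#' @param n_perm number of random pairings (study setting: 5000)
#' @param seed optional integer seed
#' @return object of class `paired_distance_test`: list with `observed`,
#'   `null_mean`, `null_q05`, `percentile`, `p_value`, `more_alike`,
#'   `n_pairs`, `n_perm`
#' @export
paired_distance_test <- function(D, pairs, n_perm = 5000, seed = NULL) {
  stopifnot(all(c("tumor", "normal") %in% colnames(pairs)))
  if (nrow(pairs) < 3L) stop("need >= 3 pairs")
  ids <- c(pairs$tumor, pairs$normal)
  if (anyDuplicated(ids)) stop("pairs must be disjoint")
  missing <- setdiff(ids, rownames(D))
  if (length(missing)) stop("samples absent from D: ",
                            paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  tum <- pairs$tumor; nor <- pairs$normal
  observed <- mean(D[cbind(tum, nor)])
  null_means <- vapply(seq_len(n_perm), function(b)
    mean(D[cbind(tum, sample(nor))]), numeric(1))
  at_or_below <- sum(null_means <= observed + 1e-15)
  structure(list(observed = observed,
                 null_mean = mean(null_means),
                 null_q05 = stats::quantile(null_means, 0.05, names = FALSE),
                 percentile = 100 * mean(null_means < observed - 1e-15),
                 p_value = (1 + at_or_below) / (1 + n_perm),
                 more_alike = observed < stats::quantile(null_means, 0.05,
                                                         names = FALSE),
                 n_pairs = nrow(pairs), n_perm = n_perm),
            class = "paired_distance_test")
}

#' @export
print.paired_distance_test <- function(x, ...) {
  cat(sprintf(paste0("Paired-distance test: observed mean = %.4f over %d pairs; ",
                     "null mean = %.4f; p = %.4g (%d permutations); ",
                     "pairs more alike: %s\n"),
              x$observed, x$n_pairs, x$null_mean, x$p_value, x$n_perm,
              if (x$more_alike) "yes" else "no"))
  invisible(x)
}

#' Per-feature paired Wilcoxon signed-rank tests
#'
#' Tests each feature for a tumor-vs-normal shift in clr-transformed
#' abundance with the Wilcoxon signed-rank test on paired differences
#' (exact distribution when at most 25 non-zero pairs and no ties, normal
#' approximation with continuity correction otherwise; zero differences are
#' dropped per the Wilcoxon convention). p-values are BH-adjusted within the
#' call, i.e. within one taxonomic rank.
#'
#' @param clr_tumor,clr_normal clr matrices with identical feature columns;
#'   rows aligned via `pairs`
#' @param pairs data frame with `tumor` and `normal` sample-id columns
#' @param rank optional rank label recorded in the result
#' @return data frame, one row per feature: `feature_id`, `statistic`,
#'   `direction` (+1 higher in tumor, -1 lower, 0 no signal), `p`, `q`
#' @export
paired_feature_tests <- function(clr_tumor, clr_normal, pairs, rank = NULL) {
  stopifnot(identical(colnames(clr_tumor), colnames(clr_normal)))
  xt <- clr_tumor[pairs$tumor, , drop = FALSE]
  xn <- clr_normal[pairs$normal, , drop = FALSE]
  nfeat <- ncol(xt)
  stat <- p <- dirn <- numeric(nfeat)
  zero_var <- character(0)
  for (j in seq_len(nfeat)) {
    d <- xt[, j] - xn[, j]
    dz <- d[d != 0]
    if (!length(dz)) {
      stat[j] <- NA_real_; p[j] <- 1; dirn[j] <- 0
      zero_var <- c(zero_var, colnames(xt)[j])
      next
    }
    use_exact <- length(dz) <= 25 && !anyDuplicated(abs(dz))
    wt <- suppressWarnings(
      stats::wilcox.test(xt[, j], xn[, j], paired = TRUE,
                         exact = use_exact, correct = TRUE))
    stat[j] <- unname(wt$statistic)
    p[j] <- wt$p.value
    r <- rank(abs(dz))
    dirn[j] <- sign(sum(r[dz > 0]) - sum(r[dz < 0]))
  }
  if (length(zero_var))
    warning("zero-variance paired differences (p set to 1): ",
            paste(zero_var, collapse = ", "))
  out <- data.frame(feature_id = colnames(xt), statistic = stat,
                    direction = dirn, p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE)
  if (!is.null(rank)) out$rank <- rank
  out
}
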