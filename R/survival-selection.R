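#' Covariate-adjusted Cox model for a single feature
#'
#' Fits a Cox proportional hazards model (Efron ties) of the endpoint on one
#' biomarker (a clr-transformed taxon or a log2 gene) plus an unpenalized
#' covariate design. With `cluster`, a sandwich (robust) variance is used to
#' account for within-patient clustering of samples, as needed when several
#' samples per patient enter the model. Monotone-likelihood or
#' non-convergent fits are returned flagged with infinite confidence limits
#' rather than raising an error, so feature scans can proceed.
#'
#' @param time,event numeric survival time (months) and 0/1 event indicator
#' @param feature numeric biomarker vector
#' @param covariates optional numeric design matrix (adjustment columns)
#' @param cluster optional cluster ids for robust variance
#' @return object of class `cox_fit`: `coef`, `hr`, `ci_lower`, `ci_upper`,
#'   `se`, `p`, `converged`, `n`, `n_events`, `loglik` (null, fitted)
#' @export
fit_cox_adjusted <- function(time, event, feature, covariates = NULL,
                             cluster = NULL) {
  if (sum(event) < 2L) stop("need >= 2 events")
  df <- data.frame(time = time, event = event, feature = feature)
  covnames <- NULL
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    # drop rank-deficient columns with a warning
    qrX <- qr(cbind(1, covariates))
    if (qrX$rank < ncol(covariates) + 1L) {
      keep <- qrX$pivot[seq_len(qrX$rank)] - 1L
      keep <- keep[keep > 0L]
      warning("covariate design not full rank; dropping: ",
              paste(setdiff(colnames(covariates), colnames(covariates)[keep]),
                    collapse = ", "))
      covariates <- covariates[, keep, drop = FALSE]
    }
    covnames <- paste0("z", seq_len(ncol(covariates)))  # syntactic aliases
    cv <- as.data.frame(covariates)
    colnames(cv) <- covnames
    df <- cbind(df, cv)
  }
  fm <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(c("feature", covnames), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fm, data = df, ties = "efron",
                    cluster = if (!is.null(cluster)) cluster),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  b <- unname(stats::coef(fit)["feature"])
  se_col <- if ("robust se" %in% colnames(sm$coefficients)) "robust se" else "se(coef)"
  se <- sm$coefficients["feature", se_col]
  p <- sm$coefficients["feature", ncol(sm$coefficients)]
  if (!converged || !is.finite(se) || se > 1e3) {
    ci <- c(0, Inf)
    if (!is.finite(se) || se > 1e3) converged <- FALSE
  } else {
    ci <- exp(b + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  structure(list(coef = b, hr = exp(b), ci_lower = ci[1L], ci_upper = ci[2L],
                 se = se, p = p, converged = converged,
                 n = nrow(df), n_events = sum(event),
                 loglik = fit$loglik), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit: HR = %.3f (95%% CI %.3f-%.3f), p = %.3g, %d events / %d%s\n",
              x$hr, x$ci_lower, x$ci_upper, x$p, x$n_events, x$n,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Adjusted Cox scan over a feature matrix
#'
#' Runs [fit_cox_adjusted()] for each column of `features` and BH-adjusts the
#' Wald p-values within the scan (one feature family, e.g. one taxonomic
#' rank).
#'
#' @inheritParams fit_cox_adjusted
#' @param features numeric matrix, patients x features
#' @return data frame: `feature_id`, `coef`, `hr`, `ci_lower`, `ci_upper`,
#'   `p`, `q`, `converged`
#' @export
cox_feature_scan <- function(time, event, features, covariates = NULL,
                             cluster = NULL) {
  features <- as.matrix(features)
  fits <- lapply(seq_len(ncol(features)), function(j)
    fit_cox_adjusted(time, event, features[, j], covariates, cluster))
  out <- data.frame(
    feature_id = colnames(features),
    coef = vapply(fits, `[[`, numeric(1), "coef"),
    hr = vapply(fits, `[[`, numeric(1), "hr"),
    ci_lower = vapply(fits, `[[`, numeric(1), "ci_lower"),
    ci_upper = vapply(fits, `[[`, numeric(1), "ci_upper"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  out
}

# event-stratified fold assignment: events and censored spread evenly
stratified_folds <- function(event, K) {
  fold <- integer(length(event))
  for (g in c(0L, 1L)) {
    ix <- which(event == g)
    fold[ix] <- sample(rep_len(seq_len(K), length(ix)))
  }
  fold
}

#' Repeated cross-validated elastic-net Cox stability selection
#'
#' Repeats, `R` times, a K-fold cross-validated elastic-net penalized Cox
#' regression (mixing parameter `alpha`; study settings R = 500, K = 10,
#' alpha = 0.5) of the endpoint on the biomarker matrix, with the clinical
#' covariates included unpenalized in every model. Folds are stratified by
#' event status so no fold is event-free at small n. Each repetition picks
#' the penalty minimizing the cross-validated partial-likelihood deviance
#' (or the one-standard-error penalty with `lambda_rule = "1se"`), refits on
#' all data at that penalty, and records which features have nonzero
#' coefficients. The per-feature selection count out of R, together with the
#' covariate-adjusted Cox fit and its BH q-value from [cox_feature_scan()],
#' forms the selection surface: the study rule keeps features selected in at
#' least 25% of repetitions with q < 0.20.
#'
#' @param time,event survival endpoint (months, 0/1)
#' @param features numeric matrix, patients x features (clr taxa, clr
#'   pathways, or log2 genes); standardized internally by the penalized fit
#' @param covariates optional numeric design matrix, never penalized
#' @param R number of repetitions
#' @param K number of cross-validation folds (2..n)
#' @param alpha elastic-net mixing parameter in (0, 1]
#' @param seed integer seed; repetition r uses stream `seed + r`
#' @param lambda_rule `"min"` (default) or `"1se"`
#' @param nlambda length of the penalty path handed to the solver
#' @param lambda_min_ratio smallest penalty on the path as a fraction of the
#'   largest (passed to the solver); the default lets the solver decide.
#'   Raising it truncates the dense small-penalty tail of the path that the
#'   cross-validated optimum never visits when only a few features carry
#'   signal, at a large computational saving
#' @return object of class `stability_result`: data frame with
#'   `feature_id`, `selection_count`, `R`, `selection_fraction`, plus the
#'   adjusted Cox columns of [cox_feature_scan()]; attributes `K`, `alpha`,
#'   `lambda_rule`
#' @export
stability_select <- function(time, event, features, covariates = NULL,
                             R = 500, K = 10, alpha = 0.5, seed = NULL,
                             lambda_rule = c("min", "1se"), nlambda = 100,
                             lambda_min_ratio = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(R >= 1, K >= 2, K <= n)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max / 2, 1L)
  ncov <- if (is.null(covariates)) 0L else ncol(covariates)
  x <- if (ncov) cbind(as.matrix(covariates), features) else features
  pf <- c(rep(0, ncov), rep(1, ncol(features)))
  y <- survival::Surv(time, event)
  counts <- stats::setNames(integer(ncol(features)), colnames(features))
  feat_cols <- ncov + seq_len(ncol(features))
  for (r in seq_len(R)) {
    set.seed(seed + r)
    cf <- NULL
    for (try in 1:10) {
      foldid <- stratified_folds(event, K)
      # path-truncation warnings (numerical error at small lambda) are
      # harmless: the cross-validated optimum lies on the returned path
      cf <- tryCatch(
        suppressWarnings(
          if (is.null(lambda_min_ratio))
            glmnet::cv.glmnet(x, y, family = "cox", alpha = alpha,
                              foldid = foldid, penalty.factor = pf,
                              standardize = TRUE, nlambda = nlambda)
          else
            glmnet::cv.glmnet(x, y, family = "cox", alpha = alpha,
                              foldid = foldid, penalty.factor = pf,
                              standardize = TRUE, nlambda = nlambda,
                              lambda.min.ratio = lambda_min_ratio)),
        error = function(e) NULL)
      if (!is.null(cf)) break
    }
    if (is.null(cf)) stop("cross-validated fit failed after 10 fold redraws (repetition ", r, ")")
    s <- if (lambda_rule == "min") cf$lambda.min else cf$lambda.1se
    beta <- as.numeric(stats::coef(cf, s = s))
    counts <- counts + (abs(beta[feat_cols]) > 0)
  }
  scan <- cox_feature_scan(time, event, features, covariates)
  out <- cbind(data.frame(feature_id = names(counts),
                          selection_count = as.integer(counts), R = R,
                          selection_fraction = as.numeric(counts) / R,
                          stringsAsFactors = FALSE),
               scan[match(names(counts), scan$feature_id),
                    c("coef", "hr", "ci_lower", "ci_upper", "p", "q",
                      "converged")])
  rownames(out) <- NULL
  attr(out, "K") <- K
  attr(out, "alpha") <- alpha
  attr(out, "lambda_rule") <- lambda_rule
  class(out) <- c("stability_result", class(out))
  out
}

#' Apply the selection rule to a stability result
#'
#' Keeps features selected in at least `min_fraction` of repetitions and
#' with BH q below `q_threshold` (study rule: >= 25% of 500 repetitions,
#' i.e. 125 times or more, and q < 0.20).
#'
#' @param stability a `stability_result`
#' @param min_fraction minimum selection fraction (default 0.25)
#' @param q_threshold FDR threshold (default 0.20)
#' @return character vector of selected feature ids
#' @export
select_features <- function(stability, min_fraction = 0.25,
                            q_threshold = 0.20) {
  sel <- stability$selection_fraction >= min_fraction &
    stability$q < q_threshold
  stability$feature_id[sel]
}

#' (Partial) Spearman correlation
#'
#' Rank-transforms `x` and `y`, residualizes each on the covariate design,
#' and reports the Pearson correlation of the residuals with a t-based
#' p-value on `n - 2 - ncol(covariates)` degrees of freedom. With no
#' covariates this is the ordinary Spearman correlation.
#'
#' @param x,y numeric vectors
#' @param covariates optional numeric design matrix to adjust for
#' @return list with `rho`, `p`, `df`
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= ncov + 2L) stop("need n > ncol(covariates) + 2")
  rx <- rank(x); ry <- rank(y)
  if (ncov) {
    Z <- cbind(1, as.matrix(covariates))
    rx <- stats::lm.fit(Z, rx)$residuals
    ry <- stats::lm.fit(Z, ry)$residuals
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - ncov
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df), df = df)
}

#' Log2-transform a gene-expression matrix
#'
#' @param m numeric matrix of normalized expression values (> 0, or supply a
#'   pseudocount)
#' @param pseudocount optional constant added before the log
#' @return matrix of log2 values
#' @export
log2_gene_matrix <- function(m, pseudocount = NULL) {
  m <- as.matrix(m)
  if (is.null(pseudocount)) {
    if (any(m <= 0)) stop("non-positive expression values; supply a pseudocount")
    pseudocount <- 0
  }
  log2(m + pseudocount)
}
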