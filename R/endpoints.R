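#' Survival endpoint derivation
#'
#' Survival records store per-patient elapsed event times in months from
#' surgery: `recurrence_time`, `new_primary_time`, `death_time` (each may be
#' `NA`), `last_followup_time` (required), and a logical `died`. From these,
#' three composite endpoints are derived following the consensus definitions
#' for adjuvant lung-cancer trials:
#'
#' * RFS (recurrence-free survival): recurrence or death from any cause,
#'   ignoring new primaries.
#' * DFS (disease-free survival): recurrence, new primary (same or other
#'   cancer), or death from any cause.
#' * OS (overall survival): death from any cause.
#'
#' Event time is the earliest qualifying event; patients without a qualifying
#' event are censored at last follow-up. When an event and the censoring time
#' coincide, the event wins.
#'
#' @param records data frame with columns `patient_id`, `recurrence_time`,
#'   `new_primary_time`, `death_time`, `last_followup_time`, `died`
#' @param endpoint one of `"RFS"`, `"DFS"`, `"OS"`
#' @return data frame with columns `patient_id`, `endpoint`, `time`, `event`
#' @export
derive_endpoint <- function(records, endpoint = c("RFS", "DFS", "OS")) {
  endpoint <- match.arg(endpoint)
  validate_records(records)
  if (any(records$died & is.na(records$death_time)))
    stop("records with died=TRUE but missing death_time: ",
         "apply impute_missing_death() first")
  qualifying <- switch(endpoint,
    RFS = cbind(records$recurrence_time, records$death_time),
    DFS = cbind(records$recurrence_time, records$new_primary_time,
                records$death_time),
    OS  = cbind(records$death_time))
  ev_time <- suppressWarnings(apply(qualifying, 1L, min, na.rm = TRUE))
  has_event <- is.finite(ev_time)
  time <- ifelse(has_event, ev_time, records$last_followup_time)
  if (any(!is.finite(time) | time <= 0))
    stop("no usable positive time for patient(s): ",
         paste(records$patient_id[!is.finite(time) | time <= 0], collapse = ", "))
  data.frame(patient_id = records$patient_id, endpoint = endpoint,
             time = time, event = as.integer(has_event),
             stringsAsFactors = FALSE)
}

validate_records <- function(records) {
  req <- c("patient_id", "recurrence_time", "new_primary_time", "death_time",
           "last_followup_time", "died")
  missing_cols <- setdiff(req, colnames(records))
  if (length(missing_cols))
    stop("survival records missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyNA(records$last_followup_time))
    stop("last_followup_time is required for every record")
  tm <- c(records$recurrence_time, records$new_primary_time,
          records$death_time, records$last_followup_time)
  if (any(tm < 0, na.rm = TRUE)) stop("event times must be >= 0")
  invisible(records)
}

#' Impute a missing death date from the recurrence date
#'
#' For patients known to have died but missing a death time, the recurrence
#' time is carried forward as the death time. Imputed rows are flagged in a
#' `death_imputed` column so sensitivity analyses can exclude them.
#'
#' @param records survival records data frame (see [derive_endpoint()])
#' @return the records with `death_time` filled and `death_imputed` added
#' @export
impute_missing_death <- function(records) {
  validate_records(records)
  needs <- records$died & is.na(records$death_time)
  bad <- needs & is.na(records$recurrence_time)
  if (any(bad))
    stop("died with neither death nor recurrence time: ",
         paste(records$patient_id[bad], collapse = ", "))
  records$death_imputed <- needs
  records$death_time[needs] <- records$recurrence_time[needs]
  records
}

#' Derive all three endpoints as a named list
#' @param records survival records data frame
#' @return list with elements `RFS`, `DFS`, `OS`
#' @export
derive_all_endpoints <- function(records) {
  stats::setNames(lapply(c("RFS", "DFS", "OS"), derive_endpoint,
                         records = records), c("RFS", "DFS", "OS"))
}

#' Encode patient covariates as a design matrix
#'
#' Categorical covariates are dummy-coded with the lexicographically first
#' level as reference, so Cox coefficients are reproducible across runs and
#' platforms. Continuous covariates are passed through unchanged. Race may be
#' collapsed to white/non-white via `collapse_race`.
#'
#' @param covariates data frame, one row per patient, with a `patient_id`
#'   column; remaining columns are covariates (character/factor treated as
#'   categorical, numeric as continuous)
#' @param columns which covariate columns to encode (default: all but
#'   `patient_id`)
#' @param collapse_race collapse the `race` column to `white`/`non-white`
#' @return numeric design matrix (no intercept) with `patient_id` rownames
#' @export
build_covariate_design <- function(covariates, columns = NULL,
                                   collapse_race = FALSE) {
  stopifnot("patient_id" %in% colnames(covariates))
  if (is.null(columns))
    columns <- setdiff(colnames(covariates), "patient_id")
  df <- covariates[, columns, drop = FALSE]
  if (collapse_race && "race" %in% columns)
    df$race <- ifelse(tolower(as.character(df$race)) == "white",
                      "white", "non-white")
  for (cn in colnames(df)) {
    if (is.character(df[[cn]]) || is.factor(df[[cn]]) || is.logical(df[[cn]]))
      df[[cn]] <- factor(as.character(df[[cn]]),
                         levels = sort(unique(as.character(df[[cn]]))))
  }
  single <- vapply(df, function(v) is.factor(v) && nlevels(v) < 2L, logical(1))
  if (any(single)) df <- df[, !single, drop = FALSE]  # no contrast possible
  if (!ncol(df)) stop("no usable covariates (all single-level)")
  mm_full <- stats::model.matrix(~ ., data = df)
  assign <- attr(mm_full, "assign")[-1L]
  mm <- mm_full[, -1L, drop = FALSE]  # drop intercept
  rownames(mm) <- covariates$patient_id
  attr(mm, "assign_cols") <- split(colnames(mm), colnames(df)[assign])
  mm
}

#' Screen covariates for association with survival
#'
#' Retains covariates whose Wald test reaches `p < p_threshold` for any of
#' the supplied endpoints, in either an unadjusted Cox model (the covariate
#' alone) or the full multivariable model (all covariates jointly).
#' Multi-level covariates are tested jointly across their dummy columns.
#' A covariate whose model fails to converge is retained with a warning
#' (conservative).
#'
#' @param covariates patient covariate data frame (with `patient_id`)
#' @param endpoints a single endpoint data frame from [derive_endpoint()] or
#'   a list of them (e.g. [derive_all_endpoints()])
#' @param p_threshold retention threshold on the Wald p-value (default 0.10)
#' @param collapse_race passed to [build_covariate_design()]
#' @return character vector of retained covariate names, with a
#'   `p_values` attribute holding the per-covariate minimum p
#' @export
screen_covariates <- function(covariates, endpoints, p_threshold = 0.10,
                              collapse_race = FALSE) {
  if (is.data.frame(endpoints)) endpoints <- list(endpoints)
  covnames <- setdiff(colnames(covariates), "patient_id")
  if (!length(covnames)) stop("no covariates to screen")
  design <- build_covariate_design(covariates, collapse_race = collapse_race)
  groups <- attr(design, "assign_cols")
  pmin_by_cov <- stats::setNames(rep(Inf, length(covnames)), covnames)
  keep_warn <- character(0)
  for (ep in endpoints) {
    if (length(unique(ep$event)) < 2L)
      stop("endpoint needs both censored and event records")
    idx <- match(ep$patient_id, rownames(design))
    X <- design[idx, , drop = FALSE]
    y <- survival::Surv(ep$time, ep$event)
    full <- tryCatch(
      survival::coxph(y ~ X, ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL)
    for (cn in covnames) {
      cols <- groups[[cn]]
      ps <- c()
      # unadjusted
      Xu <- X[, cols, drop = FALSE]
      fu <- tryCatch(survival::coxph(y ~ Xu, ties = "efron"),
                     error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fu)) {
        keep_warn <- union(keep_warn, cn)
      } else {
        ps <- c(ps, wald_joint_p(stats::coef(fu), stats::vcov(fu)))
      }
      # full model
      if (is.null(full)) {
        keep_warn <- union(keep_warn, cn)
      } else {
        sel <- match(paste0("X", cols), names(stats::coef(full)))
        sel <- sel[!is.na(sel)]
        if (length(sel))
          ps <- c(ps, wald_joint_p(stats::coef(full)[sel],
                                   stats::vcov(full)[sel, sel, drop = FALSE]))
      }
      if (length(ps))
        pmin_by_cov[cn] <- min(pmin_by_cov[cn], ps, na.rm = TRUE)
    }
  }
  retained <- covnames[pmin_by_cov < p_threshold | covnames %in% keep_warn]
  if (length(intersect(keep_warn, retained)))
    warning("Cox model did not converge for: ",
            paste(intersect(keep_warn, retained), collapse = ", "),
            "; retained conservatively")
  attr(retained, "p_values") <- pmin_by_cov
  retained
}

wald_joint_p <- function(beta, V) {
  ok <- is.finite(beta) & is.finite(diag(as.matrix(V)))
  if (!any(ok)) return(NA_real_)
  beta <- beta[ok]
  V <- as.matrix(V)[ok, ok, drop = FALSE]
  stat <- tryCatch(drop(t(beta) %*% solve(V, beta)), error = function(e) NA_real_)
  if (!is.finite(stat)) return(NA_real_)
  stats::pchisq(stat, df = length(beta), lower.tail = FALSE)
}

#' Read/write survival records and metadata TSVs
#'
#' Tab-delimited, UTF-8, `NA` for missing. Columns follow the documented
#' contracts: survival records (`patient_id`, `recurrence_time`,
#' `new_primary_time`, `death_time`, `last_followup_time`, `died`), sample
#' metadata (`sample_id`, `patient_id`, `tissue`, optional `batch`),
#' covariates (`patient_id` plus covariate columns).
#'
#' @param path file path
#' @param x data frame to write
#' @return data frame (readers) or `path` invisibly (writer)
#' @export
read_survival_records <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  df$died <- as.logical(df$died)
  validate_records(df)
  df
}

#' @rdname read_survival_records
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_survival_records
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}
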