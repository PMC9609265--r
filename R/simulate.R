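#' Specification for a synthetic tumor/normal lung cohort
#'
#' Collects every parameter of the cohort generator. Defaults mirror the
#' structure of a resected stage-II NSCLC cohort with paired tumor and
#' normal lung tissue microbiome profiles and a peripheral blood
#' gene-expression panel: 46 patients; a seven-rank taxonomy with 6 phyla,
#' 10 classes, 19 orders, 27 families, 41 genera and 13 classified species
#' over the ASV pool; log-normal sequencing depths; paired tumor/normal
#' compositions that are more similar within than between patients
#' (`rho_pair`); survival times from an exponential-baseline Cox model with
#' planted clr-taxon, log2-gene and covariate effects; and independent
#' uniform administrative censoring.
#'
#' @param n_patients number of patients
#' @param n_taxa named integer vector of taxa per rank (phylum..species)
#'   plus `asv`; scaled-down trees are fine for tests
#' @param depth_meanlog,depth_sdlog log-normal sequencing depth parameters
#' @param rho_pair within-patient tumor/normal composition mixing weight in
#'   \[0, 1\]: sample latent composition = base + `rho_pair` * patient
#'   deviation + `(1 - rho_pair)` * sample-specific noise
#' @param sigma_rank sd of clade-level (phylum..genus) log-abundance
#'   effects shared cohort-wide (rank-tree correlation structure)
#' @param sigma_patient sd of the patient-level and sample-level latent
#'   deviations
#' @param frac_unclassified_genus,frac_unclassified_species probability an
#'   ASV lacks a genus / species label
#' @param signal_taxa named numeric vector: planted log-hazard-ratio per
#'   clr unit for genus-level taxa (names like `"g3"` index genera), or
#'   `NULL`
#' @param n_genes gene panel size
#' @param signal_genes named numeric vector of log-HR per log2 unit for
#'   gene columns (names like `"gene5"`), or `NULL`
#' @param gamma named numeric vector of covariate log-HRs on the dummy
#'   design scale (names must match design columns; see
#'   [build_covariate_design()])
#' @param lambda0 baseline hazard per month of the recurrence/death process
#' @param censor_window `c(min, max)` months of the uniform administrative
#'   censoring time
#' @param p_death_first probability the composite first event is a death
#'   rather than a recurrence
#' @param post_recurrence_death_rate hazard per month of death after
#'   recurrence
#' @param new_primary_rate hazard per month of an independent new primary
#' @param p_missing_tumor,p_missing_normal probability a patient lacks that
#'   tissue sample
#' @param p_missing_death_date probability a death date is masked for a
#'   patient who died after recurrence (exercises the imputation rule)
#' @param seed integer seed; the generator derives fixed sub-stream seeds
#'   from it (see Details)
#' @details Reproducibility uses a documented stream-splitting scheme:
#'   taxonomy is drawn at `seed + 1`, covariates at `seed + 2`, latent
#'   compositions and counts at `seed + 3`, gene expression at `seed + 4`,
#'   and survival/censoring at `seed + 5`, so any sub-draw can be
#'   regenerated in isolation.
#' @return object of class `cohort_spec` (a validated list)
#' @export
cohort_spec <- function(n_patients = 46,
                        n_taxa = c(phylum = 6, class = 10, order = 19,
                                   family = 27, genus = 41, species = 13,
                                   asv = 200),
                        depth_meanlog = log(20000), depth_sdlog = 0.6,
                        rho_pair = 0.9,
                        sigma_rank = 0.8, sigma_patient = 1.0,
                        frac_unclassified_genus = 0.15,
                        frac_unclassified_species = 0.6,
                        signal_taxa = NULL,
                        n_genes = 100, signal_genes = NULL,
                        gamma = c(age = 0.02, sexmale = 0.2,
                                  racewhite = -0.1, smokingformer = -0.2,
                                  smokingnever = -0.4,
                                  histologysquamous = 0.15,
                                  chemotherapyyes = -0.2),
                        lambda0 = 0.012,
                        censor_window = c(24, 146),
                        p_death_first = 0.3,
                        post_recurrence_death_rate = 0.03,
                        new_primary_rate = 0.002,
                        p_missing_tumor = 0.15, p_missing_normal = 0.11,
                        p_missing_death_date = 0.04,
                        seed = 1L) {
  spec <- as.list(environment())
  stopifnot(n_patients >= 2, all(n_taxa >= 1),
            depth_sdlog > 0, exp(depth_meanlog) > 0,
            rho_pair >= 0, rho_pair <= 1,
            sigma_rank > 0, sigma_patient > 0,
            lambda0 > 0, censor_window[1] > 0,
            censor_window[2] > censor_window[1],
            n_genes >= 1)
  if (!is.null(spec$signal_taxa) && is.null(names(spec$signal_taxa)))
    stop("signal_taxa must be named (e.g. c(g1 = 0.8))")
  if (!is.null(spec$signal_genes) && is.null(names(spec$signal_genes)))
    stop("signal_genes must be named (e.g. c(gene1 = 0.5))")
  structure(spec, class = "cohort_spec")
}

# build a nested rank tree: each node at a rank gets a parent one rank up,
# every parent has at least one child
build_taxonomy <- function(n_taxa, frac_unclassified_genus,
                           frac_unclassified_species) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  parent <- list()
  for (i in seq_along(ranks)[-1L]) {
    np <- n_taxa[[ranks[i - 1L]]]
    nc <- n_taxa[[ranks[i]]]
    if (nc < np) stop("rank tree needs n(", ranks[i], ") >= n(", ranks[i - 1L], ")")
    parent[[ranks[i]]] <- sample(c(seq_len(np),
                                   sample.int(np, nc - np, replace = TRUE)))
  }
  n_asv <- n_taxa[["asv"]]
  ng <- n_taxa[["genus"]]
  asv_genus <- c(seq_len(ng), sample.int(ng, max(0L, n_asv - ng),
                                         replace = TRUE))[seq_len(n_asv)]
  # classified species live under specific genera; ASVs in those genera may
  # carry the species label
  ns <- n_taxa[["species"]]
  species_genus <- sample.int(ng, ns, replace = TRUE)
  asv_species <- rep(NA_integer_, n_asv)
  for (s in seq_len(ns)) {
    cand <- which(asv_genus == species_genus[s])
    if (length(cand))
      asv_species[sample(cand, 1L)] <- s
  }
  unl_g <- stats::runif(n_asv) < frac_unclassified_genus
  unl_s <- is.na(asv_species) | stats::runif(n_asv) < frac_unclassified_species
  lab <- function(rank, id) sprintf("%s%02d", c(phylum = "Phy", class = "Cla",
                                                order = "Ord", family = "Fam",
                                                genus = "Gen")[rank], id)
  # full lineage segments down to genus, for each genus id
  genus_segs <- lapply(seq_len(ng), function(g) {
    path <- c(genus = g)
    id <- g
    for (i in rev(seq_along(ranks))[-length(ranks)]) {
      id <- parent[[ranks[i]]][id]
      path[ranks[i - 1L]] <- id
    }
    path <- path[ranks]
    c("k__Bacteria",
      paste0(RANK_PREFIXES[ranks],
             vapply(ranks, function(r) lab(r, path[[r]]), character(1))))
  })
  genus_lineage <- vapply(genus_segs, paste, character(1), collapse = "; ")
  names(genus_lineage) <- paste0("g", seq_len(ng))
  lineage <- character(n_asv)
  for (a in seq_len(n_asv)) {
    segs <- genus_segs[[asv_genus[a]]]
    if (unl_g[a]) segs[6L] <- "g__"
    segs <- c(segs, if (unl_s[a] || unl_g[a]) "s__"
              else sprintf("s__Species%02d", asv_species[a]))
    lineage[a] <- paste(segs, collapse = "; ")
  }
  names(lineage) <- sprintf("ASV%04d", seq_len(n_asv))
  list(lineage = lineage, asv_genus = asv_genus, parent = parent,
       genus_lineage = genus_lineage)
}

# patient covariates with frequencies typical of a stage-II NSCLC cohort
draw_covariates <- function(n) {
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = round(stats::rnorm(n, 70, 9), 1),
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.5, 0.5)),
    race = sample(c("non-white", "white"), n, TRUE, prob = c(0.13, 0.87)),
    smoking = sample(c("current", "former", "never"), n, TRUE,
                     prob = c(0.22, 0.63, 0.15)),
    histology = sample(c("adenocarcinoma", "squamous"), n, TRUE),
    chemotherapy = sample(c("no", "yes"), n, TRUE, prob = c(0.67, 0.33)),
    stringsAsFactors = FALSE)
}

#' Simulate a paired tumor/normal cohort with planted survival effects
#'
#' Generates, from a [cohort_spec()]:
#' * tumor and normal lung `feature_table`s at the ASV level with a nested
#'   taxonomy, counts multinomial at log-normal depths over logistic-normal
#'   latent compositions; the tumor and normal latent compositions of a
#'   patient share a common patient deviation with weight `rho_pair`;
#' * sample metadata and patient covariates;
#' * a gene-expression matrix (log-normal, positive scale);
#' * survival records whose recurrence/death composite hazard is
#'   `lambda0 * exp(beta . clr(signal genera, normal-lung latent
#'   composition) + beta_g . centered log2(genes) + gamma . covariates)`,
#'   with independent uniform censoring, an independent new-primary
#'   process, and optional masking of tissue samples and death dates;
#' * the ground truth: planted effect ids/sizes, per-patient true linear
#'   predictor, and pre-masking event/censoring times.
#'
#' @param spec a `cohort_spec`
#' @return object of class `synthetic_cohort`: list with elements `tables`
#'   (list `tumor`, `normal` of `feature_table`), `metadata`, `covariates`,
#'   `records`, `genes` (patients x genes, positive scale), `truth`, `spec`
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  pid <- sprintf("P%03d", seq_len(n))

  set.seed(spec$seed + 1L)                       # -- taxonomy stream
  tax <- build_taxonomy(spec$n_taxa, spec$frac_unclassified_genus,
                        spec$frac_unclassified_species)
  n_asv <- length(tax$lineage)
  base_mu <- stats::rnorm(n_asv, 0, 1.2)
  clade_eff <- stats::rnorm(spec$n_taxa[["genus"]], 0, spec$sigma_rank) +
    stats::rnorm(spec$n_taxa[["family"]], 0,
                 spec$sigma_rank)[tax$parent$genus][seq_len(spec$n_taxa[["genus"]])]
  base_mu <- base_mu + clade_eff[tax$asv_genus]

  set.seed(spec$seed + 2L)                       # -- covariate stream
  covariates <- draw_covariates(n)
  design <- build_covariate_design(covariates)

  set.seed(spec$seed + 3L)                       # -- composition stream
  delta_pat <- matrix(stats::rnorm(n * n_asv, 0, spec$sigma_patient), n, n_asv)
  z_normal <- z_tumor <- matrix(0, n, n_asv)
  for (i in seq_len(n)) {
    eps_t <- stats::rnorm(n_asv, 0, spec$sigma_patient)
    eps_n <- stats::rnorm(n_asv, 0, spec$sigma_patient)
    z_tumor[i, ] <- base_mu + spec$rho_pair * delta_pat[i, ] +
      (1 - spec$rho_pair) * eps_t
    z_normal[i, ] <- base_mu + spec$rho_pair * delta_pat[i, ] +
      (1 - spec$rho_pair) * eps_n
  }
  softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  draw_counts <- function(z, ids) {
    depth <- pmax(1, round(stats::rlnorm(n, spec$depth_meanlog,
                                         spec$depth_sdlog)))
    m <- t(vapply(seq_len(n), function(i)
      drop(stats::rmultinom(1L, depth[i], softmax(z[i, ]))), numeric(n_asv)))
    dimnames(m) <- list(ids, names(tax$lineage))
    m
  }
  counts_tumor <- draw_counts(z_tumor, paste0(pid, "_T"))
  counts_normal <- draw_counts(z_normal, paste0(pid, "_N"))
  has_tumor <- stats::runif(n) >= spec$p_missing_tumor
  has_normal <- stats::runif(n) >= spec$p_missing_normal

  set.seed(spec$seed + 4L)                       # -- gene stream
  gene_ids <- sprintf("gene%d", seq_len(spec$n_genes))
  log2_genes <- matrix(stats::rnorm(n * spec$n_genes, 8, 1.5), n,
                       dimnames = list(pid, gene_ids))
  genes <- 2^log2_genes

  # true linear predictor: clr of signal genera in the NORMAL-lung latent
  # composition (pre-count, so truth exists even for unsampled tissue)
  lp <- drop(design %*% ifelse(is.na(spec$gamma[colnames(design)]), 0,
                               spec$gamma[colnames(design)]))
  genus_comp <- t(vapply(seq_len(n), function(i) {
    p <- softmax(z_normal[i, ])
    vapply(split(p, tax$asv_genus), sum, numeric(1))
  }, numeric(spec$n_taxa[["genus"]])))
  colnames(genus_comp) <- paste0("g", sort(unique(tax$asv_genus)))
  clr_genus <- log(genus_comp) - rowMeans(log(genus_comp))
  if (!is.null(spec$signal_taxa)) {
    miss <- setdiff(names(spec$signal_taxa), colnames(clr_genus))
    if (length(miss)) stop("unknown signal taxa: ", paste(miss, collapse = ", "))
    lp <- lp + drop(clr_genus[, names(spec$signal_taxa), drop = FALSE] %*%
                      spec$signal_taxa)
  }
  if (!is.null(spec$signal_genes)) {
    miss <- setdiff(names(spec$signal_genes), gene_ids)
    if (length(miss)) stop("unknown signal genes: ", paste(miss, collapse = ", "))
    lg <- scale(log2_genes[, names(spec$signal_genes), drop = FALSE],
                scale = FALSE)
    lp <- lp + drop(lg %*% spec$signal_genes)
  }

  set.seed(spec$seed + 5L)                       # -- survival stream
  e_time <- stats::rexp(n, rate = spec$lambda0 * exp(lp - mean(lp)))
  death_first <- stats::runif(n) < spec$p_death_first
  recur <- ifelse(death_first, NA_real_, e_time)
  death <- ifelse(death_first, e_time,
                  e_time + stats::rexp(n, spec$post_recurrence_death_rate))
  new_primary <- stats::rexp(n, spec$new_primary_rate)
  cens <- stats::runif(n, spec$censor_window[1], spec$censor_window[2])
  died <- death <= cens
  records <- data.frame(
    patient_id = pid,
    recurrence_time = ifelse(!is.na(recur) & recur <= cens, recur, NA_real_),
    new_primary_time = ifelse(new_primary <= pmin(cens, death),
                              new_primary, NA_real_),
    death_time = ifelse(died, death, NA_real_),
    last_followup_time = ifelse(died, death, cens),
    died = died, stringsAsFactors = FALSE)
  mask_death <- died & !is.na(records$recurrence_time) &
    stats::runif(n) < spec$p_missing_death_date
  records$death_time[mask_death] <- NA_real_

  md <- rbind(
    data.frame(sample_id = paste0(pid, "_T")[has_tumor],
               patient_id = pid[has_tumor], tissue = "tumor",
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(pid, "_N")[has_normal],
               patient_id = pid[has_normal], tissue = "normal",
               stringsAsFactors = FALSE))
  tables <- list(
    tumor = feature_table(counts_tumor[has_tumor, , drop = FALSE],
                          tax$lineage),
    normal = feature_table(counts_normal[has_normal, , drop = FALSE],
                           tax$lineage))
  truth <- list(signal_taxa = spec$signal_taxa,
                signal_genes = spec$signal_genes,
                gamma = spec$gamma,
                genus_feature_ids = tax$genus_lineage,
                linear_predictor = stats::setNames(lp - mean(lp), pid),
                clr_genus_latent = clr_genus,
                event_time = e_time, censor_time = cens,
                death_date_masked = mask_death,
                contaminants = character(0))
  structure(list(tables = tables, metadata = md, covariates = covariates,
                 records = records, genes = genes, truth = truth,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d patients (%d tumor, %d normal ",
                     "samples), %d ASVs, %d genes, %d events\n"),
              x$spec$n_patients, nrow(x$tables$tumor$counts),
              nrow(x$tables$normal$counts), length(x$tables$tumor$taxonomy),
              ncol(x$genes), sum(x$records$died |
                                   !is.na(x$records$recurrence_time))))
  invisible(x)
}

#' Inject frequency-style contaminant features
#'
#' Adds features whose absolute input is roughly constant per sample
#' (Poisson counts independent of depth), so their relative abundance is
#' anticorrelated with sequencing depth — the signature of reagent
#' contamination in low-biomass specimens. Injected ids are recorded in the
#' `contaminants` attribute (and should be merged into the cohort's ground
#' truth by the caller).
#'
#' @param table a `feature_table`
#' @param n_contaminants number of contaminant features to add
#' @param mean_count mean per-sample contaminant count (log-normal across
#'   features)
#' @param seed optional integer seed
#' @return a `feature_table` with `n_contaminants` extra features and a
#'   `contaminants` attribute of their ids
#' @export
inject_contaminants <- function(table, n_contaminants, mean_count = 50,
                                seed = NULL) {
  stopifnot(n_contaminants >= 0)
  if (n_contaminants == 0L) {
    attr(table, "contaminants") <- character(0)
    return(table)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table$counts)
  ids <- sprintf("CONTAM%03d", seq_len(n_contaminants))
  mu <- stats::rlnorm(n_contaminants, log(mean_count), 1)
  extra <- vapply(mu, function(m) stats::rpois(n, m), numeric(n))
  extra <- matrix(extra, nrow = n, dimnames = list(sample_ids(table), ids))
  tax <- table$taxonomy
  if (!is.null(tax))
    tax <- c(tax, stats::setNames(
      rep("k__Bacteria; p__; c__; o__; f__; g__; s__", n_contaminants), ids))
  out <- feature_table(cbind(table$counts, extra), tax)
  attr(out, "contaminants") <- ids
  out
}
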