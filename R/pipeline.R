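#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with defaults
#' reproducing the study settings: <6000-read sample filter, rarefaction at
#' depth 2468 with 100 iterations, clr pseudocount 0.5, 500 x 10-fold
#' elastic-net Cox (alpha 0.5) with the 25%-of-repetitions / q < 0.20
#' selection rule, annual AUC horizons 12-60 months, 1000 bootstraps and
#' 5000 permutations. Any entry can be overridden via `...` or a YAML file
#' ([read_pipeline_config()]). Smaller values of `R`, `n_boot` and `n_perm`
#' are appropriate for demonstrations.
#'
#' @param ... named overrides of the defaults
#' @return named list of class `pipeline_config`
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # simulate-or-load: when all input paths are NULL, a synthetic cohort
    # is generated from `cohort` (passed to cohort_spec())
    input = list(tumor_table = NULL, normal_table = NULL, metadata = NULL,
                 covariates = NULL, records = NULL, genes = NULL),
    cohort = list(),
    min_reads = 6000,
    rarefaction = list(depth = 2468, iterations = 100),
    pseudocount = 0.5,
    ranks = c("phylum", "class", "order", "family", "genus"),
    drop_unclassified = TRUE,
    endpoints = c("RFS", "DFS", "OS"),
    screen_p = 0.10,
    community = list(n_perm = 5000),
    selection = list(R = 500, K = 10, alpha = 0.5, min_fraction = 0.25,
                     q_threshold = 0.20, lambda_rule = "min"),
    tdroc = list(t_grid = seq(12, 60, by = 12), n_boot = 1000, n_perm = 5000,
                 endpoint = "RFS", max_block = 4),
    output_dir = "lungmicsurv-output")
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys override [default_config()]
#' @return a `pipeline_config` list
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  if (!is.null(user$tdroc$t_grid)) cfg$tdroc$t_grid <- unlist(user$tdroc$t_grid)
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate-or-load, depth filtering, endpoint derivation,
#' covariate screening, rarefaction-averaged alpha diversity, clr
#' transforms per rank, community tests (PERMANOVA on tissue with patient
#' strata, the paired-distance permutation test, per-rank paired Wilcoxon
#' tests), stability selection per endpoint and rank in the normal lung plus
#' the gene panel, and time-dependent AUC models with bootstrap CIs and the
#' added-discrimination permutation test. All results are written as tidy
#' TSVs plus a JSON run manifest (seeds, parameters, file list) sufficient
#' to reproduce every output.
#'
#' @param config a `pipeline_config` list (see [default_config()])
#' @return invisibly, a list of in-memory results (`cohort`, `endpoints`,
#'   `alpha`, `community`, `selection`, `tdroc`, `manifest`)
#' @export
run_pipeline <- function(config = default_config()) {
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv(df, path)
    outputs <<- c(outputs, path)
  }

  ## ---- load or simulate -------------------------------------------------
  cohort <- run_stage("input", {
    if (is.null(config$input$tumor_table)) {
      stage_log("simulate", "generating synthetic cohort, seed ", config$seed)
      spec <- do.call(cohort_spec, utils::modifyList(
        list(seed = config$seed), config$cohort))
      simulate_cohort(spec)
    } else {
      stage_log("load", "reading input tables")
      list(tables = list(
             tumor = read_feature_table(config$input$tumor_table),
             normal = read_feature_table(config$input$normal_table)),
           metadata = read_tsv(config$input$metadata),
           covariates = read_tsv(config$input$covariates),
           records = read_survival_records(config$input$records),
           genes = {
             g <- read_tsv(config$input$genes)
             m <- as.matrix(g[, -1L, drop = FALSE]); rownames(m) <- g[[1L]]; m
           },
           truth = NULL)
    }
  })

  ## ---- depth filter -----------------------------------------------------
  tables <- run_stage("filter", {
    lapply(cohort$tables, filter_low_depth, min_reads = config$min_reads)
  })
  stage_log("filter", sprintf("tumor %d, normal %d samples at >= %d reads",
                              nrow(tables$tumor$counts),
                              nrow(tables$normal$counts), config$min_reads))
  md <- rbind(validate_metadata(tables$tumor, cohort$metadata),
              validate_metadata(tables$normal, cohort$metadata))

  ## ---- endpoints --------------------------------------------------------
  endpoints <- run_stage("endpoints", {
    recs <- impute_missing_death(cohort$records)
    derive_all_endpoints(recs)
  })
  for (ep in names(endpoints)) emit(endpoints[[ep]], paste0("endpoint_", ep))

  ## ---- covariate screening ---------------------------------------------
  retained <- run_stage("screen", {
    screen_covariates(cohort$covariates, endpoints,
                      p_threshold = config$screen_p)
  })
  stage_log("screen", "retained covariates: ", paste(retained, collapse = ", "))
  design <- build_covariate_design(cohort$covariates,
                                   columns = if (length(retained)) retained)
  emit(data.frame(covariate = names(attr(retained, "p_values")),
                  min_p = as.numeric(attr(retained, "p_values")),
                  retained = names(attr(retained, "p_values")) %in% retained),
       "covariate_screen")

  ## ---- alpha diversity --------------------------------------------------
  alpha <- run_stage("diversity", {
    combined <- feature_table(rbind(tables$tumor$counts,
                                    tables$normal$counts),
                              tables$tumor$taxonomy)
    depth <- min(config$rarefaction$depth, min(sample_depths(combined)))
    a <- rarefied_alpha(combined, depth = depth,
                        iterations = config$rarefaction$iterations,
                        seed = config$seed + 101L)
    a$tissue <- md$tissue[match(a$sample_id, md$sample_id)]
    a
  })
  emit(alpha, "alpha_diversity")

  ## ---- community tests --------------------------------------------------
  community <- run_stage("community", {
    combined <- feature_table(rbind(tables$tumor$counts,
                                    tables$normal$counts),
                              tables$tumor$taxonomy)
    D <- jsd_matrix(combined)
    write_distance_matrix(D, file.path(out_dir, "jsd_asv.tsv"))
    outputs <<- c(outputs, file.path(out_dir, "jsd_asv.tsv"))
    pairs <- sample_pairs(md)
    perm <- permanova(D, labels = md$tissue, strata = md$patient_id,
                      n_perm = config$community$n_perm,
                      seed = config$seed + 201L)
    pdt <- paired_distance_test(D, pairs, n_perm = config$community$n_perm,
                                seed = config$seed + 202L)
    ord <- pcoa(D, k = 2)
    feat <- do.call(rbind, lapply(config$ranks, function(rk) {
      agt <- agglomerate(tables$tumor, rk, drop_unclassified = FALSE)
      agn <- agglomerate(tables$normal, rk, drop_unclassified = FALSE)
      common <- intersect(feature_ids(agt), feature_ids(agn))
      paired_feature_tests(
        clr_transform(subset_table(agt, features = common),
                      config$pseudocount),
        clr_transform(subset_table(agn, features = common),
                      config$pseudocount),
        pairs, rank = rk)
    }))
    list(jsd = D, permanova = perm, paired_distance = pdt, pcoa = ord,
         feature_tests = feat, pairs = pairs)
  })
  emit(community$feature_tests, "paired_feature_tests")
  emit(data.frame(test = c("permanova_tissue", "paired_distance"),
                  statistic = c(community$permanova$pseudo_f,
                                community$paired_distance$observed),
                  p_value = c(community$permanova$p_value,
                              community$paired_distance$p_value)),
       "community_tests")
  emit(data.frame(sample_id = rownames(community$pcoa$points),
                  community$pcoa$points), "pcoa_coordinates")

  ## ---- stability selection ---------------------------------------------
  selection <- run_stage("selection", {
    nl_md <- md[md$tissue == "normal", ]
    res <- list()
    for (ep_name in config$endpoints) {
      ep <- endpoints[[ep_name]]
      keep <- nl_md$patient_id[nl_md$patient_id %in% ep$patient_id]
      ep_i <- ep[match(keep, ep$patient_id), ]
      Xcov <- design[keep, , drop = FALSE]
      for (rk in config$ranks) {
        ag <- agglomerate(tables$normal, rk,
                          drop_unclassified = config$drop_unclassified)
        clr <- clr_transform(ag, config$pseudocount)
        rows <- nl_md$sample_id[match(keep, nl_md$patient_id)]
        st <- stability_select(ep_i$time, ep_i$event,
                               clr[rows, , drop = FALSE], Xcov,
                               R = config$selection$R,
                               K = min(config$selection$K, nrow(ep_i)),
                               alpha = config$selection$alpha,
                               seed = config$seed + 301L,
                               lambda_rule = config$selection$lambda_rule)
        st$endpoint <- ep_name; st$rank <- rk
        st$selected <- st$feature_id %in%
          select_features(st, config$selection$min_fraction,
                          config$selection$q_threshold)
        res[[paste(ep_name, rk, sep = "_")]] <- st
      }
      # gene panel
      gep <- ep[match(rownames(cohort$genes), ep$patient_id), ]
      gok <- !is.na(gep$patient_id)
      lg <- log2_gene_matrix(cohort$genes[gok, , drop = FALSE])
      stg <- stability_select(gep$time[gok], gep$event[gok], lg,
                              design[gep$patient_id[gok], , drop = FALSE],
                              R = config$selection$R,
                              K = min(config$selection$K, sum(gok)),
                              alpha = config$selection$alpha,
                              seed = config$seed + 302L,
                              lambda_rule = config$selection$lambda_rule)
      stg$endpoint <- ep_name; stg$rank <- "gene"
      stg$selected <- stg$feature_id %in%
        select_features(stg, config$selection$min_fraction,
                        config$selection$q_threshold)
      res[[paste(ep_name, "gene", sep = "_")]] <- stg
    }
    res
  })
  sel_all <- do.call(rbind, lapply(selection, as.data.frame))
  emit(sel_all, "stability_selection")

  ## ---- time-dependent AUC ----------------------------------------------
  tdres <- run_stage("tdroc", {
    ep_name <- config$tdroc$endpoint
    ep <- endpoints[[ep_name]]
    nl_md <- md[md$tissue == "normal", ]
    keep <- nl_md$patient_id[nl_md$patient_id %in% ep$patient_id]
    ep_i <- ep[match(keep, ep$patient_id), ]
    rows <- nl_md$sample_id[match(keep, nl_md$patient_id)]
    Xcov <- design[keep, , drop = FALSE]
    # biomarker blocks: top selected taxa (any rank) and genes, capped
    pick_block <- function(rks) {
      tabs <- sel_all[sel_all$endpoint == ep_name & sel_all$selected &
                        sel_all$rank %in% rks, ]
      if (!nrow(tabs)) return(NULL)
      tabs <- tabs[order(-tabs$selection_fraction, tabs$q), ]
      utils::head(tabs, config$tdroc$max_block)
    }
    taxa_top <- pick_block(config$ranks)
    gene_top <- pick_block("gene")
    blocks <- list()
    if (!is.null(taxa_top)) {
      cols <- lapply(seq_len(nrow(taxa_top)), function(i) {
        ag <- agglomerate(tables$normal, taxa_top$rank[i],
                          drop_unclassified = config$drop_unclassified)
        clr_transform(ag, config$pseudocount)[rows, taxa_top$feature_id[i]]
      })
      blocks$microbiome <- do.call(cbind, cols)
      colnames(blocks$microbiome) <- taxa_top$feature_id
    }
    if (!is.null(gene_top)) {
      lg <- log2_gene_matrix(cohort$genes[keep, , drop = FALSE])
      blocks$genes <- lg[, gene_top$feature_id, drop = FALSE]
    }
    t_grid <- config$tdroc$t_grid
    models <- list(covariates = Xcov)
    if (!is.null(blocks$microbiome))
      models$microbiome <- cbind(Xcov, blocks$microbiome)
    if (!is.null(blocks$genes))
      models$genes <- cbind(Xcov, blocks$genes)
    if (length(blocks) == 2L)
      models$both <- cbind(Xcov, blocks$microbiome, blocks$genes)
    aucs <- lapply(names(models), function(nm) {
      ci <- bootstrap_auc_ci(ep_i$time, ep_i$event, models[[nm]], t_grid,
                             n_boot = config$tdroc$n_boot,
                             seed = config$seed + 401L)
      ci$model <- nm
      ci
    })
    perm <- if (length(blocks))
      auc_permutation_test(ep_i$time, ep_i$event, Xcov, blocks, t_grid,
                           n_perm = config$tdroc$n_perm,
                           seed = config$seed + 402L)
    list(auc = do.call(rbind, aucs), permutation = perm, blocks = blocks)
  })
  emit(tdres$auc, "td_auc")
  if (!is.null(tdres$permutation)) emit(tdres$permutation, "td_auc_permutation")

  ## ---- manifest ---------------------------------------------------------
  manifest <- list(
    package = "lungmicsurv",
    version = as.character(utils::packageVersion("lungmicsurv")),
    timestamp_format = "omitted for byte-identical reruns",
    seed = config$seed,
    config = config[setdiff(names(config), c("input", "output_dir"))],
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  stage_log("done", length(outputs), " output files in ", out_dir)
  invisible(list(cohort = cohort, tables = tables, endpoints = endpoints,
                 covariates_retained = retained, alpha = alpha,
                 community = community, selection = selection,
                 tdroc = tdres, manifest = manifest))
}
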