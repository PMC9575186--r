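# Configuration-driven orchestration: simulate -> preprocess -> cluster ->
# classify -> robustness -> composition -> survival, with a manifest and a
# machine-readable summary. Re-running the same configuration reproduces
# all outputs.

pipeline_stages <- c("cluster", "classify", "robustness", "composition",
                     "survival")

validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$reps)) config$reps <- 100L
  if (is.null(config$stages)) config$stages <- pipeline_stages
  bad <- setdiff(config$stages, pipeline_stages)
  if (length(bad))
    stop("config error at /stages: unknown stage(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(config$simulate))
    stop("config error at /simulate: a simulation block is required",
         call. = FALSE)
  sim <- config$simulate
  if (!is.null(sim$scenario)) {
    if (!sim$scenario %in% c("signal", "confounded"))
      stop("config error at /simulate/scenario: unknown scenario '",
           sim$scenario, "'", call. = FALSE)
  }
  config
}

sim_config_from_block <- function(sim, seed) {
  if (!is.null(sim$scenario)) {
    args <- sim[setdiff(names(sim), "scenario")]
    do.call(scenario_config, c(list(name = sim$scenario, seed = seed), args))
  } else {
    do.call(simulation_config, c(sim, list(seed = seed)))
  }
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full signature-robustness evaluation
#'
#' Orchestrates the pipeline on a simulated multi-cohort dataset: data
#' generation, preprocessing (z-scoring; cross-cohort intersection and
#' batch correction when more than one cohort), signature-restricted
#' clustering with RI/ARI against truth, cross-validated classification,
#' the random-signature/shuffled-label null batteries with their SSMD
#' summary, enrichment + deconvolution follow-up, and pairwise survival
#' separation. All stage outputs are written as TSV/JSON under `out_dir`
#' together with a manifest recording the configuration, seeds and package
#' version; a run with the same configuration reproduces them exactly.
#'
#' @param config a list or a YAML file path with fields `seed`, `reps`,
#'   `stages` (subset of cluster/classify/robustness/composition/survival)
#'   and `simulate` (either `scenario: signal|confounded` plus overrides,
#'   or [simulation_config()] fields).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("sigrobust_run_")) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  reps <- as.integer(config$reps)
  sim_cfg <- sim_config_from_block(config$simulate, seed)
  sim <- simulate_cohorts(sim_cfg)
  summary <- list(seed = seed, reps = reps, n_cohorts = sim_cfg$n_cohorts,
                  k = sim_cfg$k)

  for (nm in names(sim$cohorts)) {
    co <- sim$cohorts[[nm]]
    write_expression(co$expression, file.path(out_dir, paste0(nm, "_expression.tsv")))
    write_labels(co$labels, file.path(out_dir, paste0(nm, "_labels.tsv")))
    write_survival(co$survival, file.path(out_dir, paste0(nm, "_survival.tsv")))
  }

  # preprocessing: z-score per cohort; shared-universe batch correction when
  # several cohorts are present
  if (length(sim$cohorts) > 1) {
    pp <- preprocess_cohorts(lapply(sim$cohorts, `[[`, "expression"))
  } else {
    pp <- list(zscore_genes(sim$cohorts[[1]]$expression))
  }
  names(pp) <- names(sim$cohorts)
  first <- names(sim$cohorts)[1]
  m1 <- pp[[first]]
  labels1 <- sim$cohorts[[first]]$labels

  if ("cluster" %in% config$stages) {
    cl <- hcluster(m1, sim$signature)
    write_labels(cl$assignments, file.path(out_dir, "cluster_assignments.tsv"))
    metrics <- list(ri = rand_index(cl$assignments, labels1),
                    ari = adjusted_rand_index(cl$assignments, labels1),
                    overlap = cl$overlap)
    p_adj <- gene_association(m1, cl$assignments, sim$signature)
    utils::write.table(data.frame(gene = names(p_adj), p_adjusted = p_adj,
                                  neglog10 = attr(p_adj, "neglog10")),
                       file.path(out_dir, "cluster_gene_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_out(metrics, file.path(out_dir, "cluster_metrics.json"))
    summary$cluster <- metrics
  }

  if ("classify" %in% config$stages) {
    grid <- build_model_grid(list(planted = sim$signature),
                             lapply(names(pp), function(nm)
                               list(expression = pp[[nm]],
                                    labels = sim$cohorts[[nm]]$labels)) |>
                               stats::setNames(names(pp)),
                             seed = seed)
    accs <- lapply(grid$models, function(mo)
      list(signature = mo$signature, cohort = mo$cohort,
           cv_accuracy = mo$cv_accuracy))
    write_json_out(accs, file.path(out_dir, "classify_cv_accuracy.json"))
    if (length(pp) > 1) {
      pred <- predict_external(grid$models[[1]], pp[[2]])
      write_labels(pred, file.path(out_dir, "classify_predicted_cohort2.tsv"))
    }
    summary$classify <- list(n_models = length(grid$models),
                             n_failures = nrow(grid$failures),
                             cv_accuracy = vapply(grid$models, `[[`,
                                                  numeric(1), "cv_accuracy"))
  }

  if ("robustness" %in% config$stages) {
    cn <- classification_null(m1, labels1, sim$signature, n_reps = reps,
                              seed = seed)
    utils::write.table(
      data.frame(real = cn$real$values,
                 random_signature = cn$random_signature$values,
                 shuffled_labels = cn$shuffled_labels$values),
      file.path(out_dir, "robustness_accuracy_distributions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    cl_null <- clustering_null(m1, sim$signature, n_reps = reps, seed = seed)
    write_json_out(list(classification_summary = cn$summary,
                        clustering_ssmd = cl_null$ssmd,
                        clustering_ssmd_abs = cl_null$ssmd_abs),
                   file.path(out_dir, "robustness_summary.json"))
    summary$robustness <- list(
      median_real = stats::median(cn$real$values),
      median_random = stats::median(cn$random_signature$values),
      median_shuffled = stats::median(cn$shuffled_labels$values),
      clustering_ssmd_abs = cl_null$ssmd_abs)
  }

  if ("composition" %in% config$stages) {
    # enrichment of the planted per-class gene sets against the truth labels
    dir_map <- sim$signature$direction
    sets <- split(names(dir_map), unname(dir_map))
    prof <- ssgsea_matrix(m1, sets)
    assoc <- enrichment_association(prof, labels1)
    utils::write.table(assoc, file.path(out_dir, "composition_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # deconvolution demonstration on basis-generated mixtures
    basis <- cell_type_basis(seed = seed)
    mix <- simulate_mixtures(basis, n_samples = 100, seed = seed)
    est <- nnls_deconvolve(mix$expression, basis)
    utils::write.table(data.frame(cell_type = rownames(est), est,
                                  check.names = FALSE),
                       file.path(out_dir, "composition_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$composition <- list(
      n_significant_terms = sum(assoc$significant),
      deconvolution_rmse = sqrt(mean((est - mix$fractions)^2)))
  }

  if ("survival" %in% config$stages) {
    surv <- sim$cohorts[[first]]$survival
    mat <- pairwise_logrank(labels1, surv)
    utils::write.table(data.frame(class = rownames(mat), mat,
                                  check.names = FALSE),
                       file.path(out_dir, "survival_pairwise_neglog10p.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$survival <- list(max_neglog10_p = max(mat, na.rm = TRUE))
  }

  manifest <- list(package = "sigrobust",
                   version = as.character(utils::packageVersion("sigrobust")),
                   seed = seed, reps = reps, stages = config$stages,
                   simulation = unclass(sim_cfg),
                   rf_defaults = rf_defaults)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  write_json_out(summary, file.path(out_dir, "summary.json"))
  invisible(summary)
}
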