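# Multi-cohort synthetic expression generator. Emulates the confounding
# structure under study: a planted subtype signature, per-cohort additive
# batch shifts, per-sample contamination by a shared "normal tissue"
# profile, and subtype-dependent exponential survival with censoring.

#' Simulation configuration
#'
#' Defines one multi-cohort simulation. Expression is generated on a
#' z-score-like Gaussian scale (the evaluation pipeline z-scores everything
#' anyway, so no count model is used). Gene `i` in class `c`'s signature
#' block has mean `effect_size * noise_sd` in class-`c` samples and 0
#' elsewhere, before batch shifts and contamination are applied. Each
#' sample's profile is then mixed as `(1 - phi) * tumor + phi * normal`
#' where `phi ~ Uniform(contamination_range)` and the normal-tissue profile
#' is a fixed N(0,1) gene-wise offset drawn once per simulation (an
#' acinar-contamination-like, purity-correlated global signal). Survival
#' times are exponential with hazard `survival_base_hazard *
#' class_hazard_ratios[class]` per month, independently exponentially
#' censored at the requested marginal censoring rate.
#'
#' @param n_cohorts number of cohorts.
#' @param samples_per_cohort samples per cohort.
#' @param k number of latent subtypes.
#' @param class_proportions probability vector of length `k` (sums to 1).
#' @param n_signature_genes_per_class planted signature genes per class.
#' @param n_background_genes additional noise genes.
#' @param effect_size mean shift of a class's signature genes, in SD units.
#' @param noise_sd residual SD of every gene.
#' @param batch_shift_sd SD of the per-cohort per-gene additive shift.
#' @param contamination_range `c(lo, hi)` in `[0,1]`: per-sample fraction of
#'   the normal-tissue profile mixed in.
#' @param survival_base_hazard baseline hazard per month.
#' @param class_hazard_ratios hazard ratio per class, length `k`.
#' @param censor_rate marginal probability that a sample is censored.
#' @param labels_from_contamination if `TRUE`, class labels are assigned by
#'   contamination quantile bins (sized by `class_proportions`) instead of
#'   independently at random — the purity-confounded regime in which
#'   "subtypes" merely track tissue composition.
#' @param seed integer seed; identical configurations reproduce identical
#'   outputs bitwise.
#' @return An object of class `SimulationConfig`.
#' @export
simulation_config <- function(n_cohorts = 2,
                              samples_per_cohort = 100,
                              k = 2,
                              class_proportions = rep(1 / k, k),
                              n_signature_genes_per_class = 25,
                              n_background_genes = 500,
                              effect_size = 3,
                              noise_sd = 1,
                              batch_shift_sd = 0.5,
                              contamination_range = c(0, 0.3),
                              survival_base_hazard = 0.03,
                              class_hazard_ratios = seq(1, 2, length.out = k),
                              censor_rate = 0.3,
                              labels_from_contamination = FALSE,
                              seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = as.integer(samples_per_cohort),
              k = as.integer(k),
              class_proportions = as.numeric(class_proportions),
              n_signature_genes_per_class = as.integer(n_signature_genes_per_class),
              n_background_genes = as.integer(n_background_genes),
              effect_size = effect_size, noise_sd = noise_sd,
              batch_shift_sd = batch_shift_sd,
              contamination_range = as.numeric(contamination_range),
              survival_base_hazard = survival_base_hazard,
              class_hazard_ratios = as.numeric(class_hazard_ratios),
              censor_rate = censor_rate,
              labels_from_contamination = isTRUE(labels_from_contamination),
              seed = as.integer(seed))
  if (length(cfg$class_proportions) != cfg$k)
    stop("class_proportions must have length k", call. = FALSE)
  if (abs(sum(cfg$class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1 (tolerance 1e-8)", call. = FALSE)
  cr <- cfg$contamination_range
  if (length(cr) != 2 || cr[1] < 0 || cr[2] > 1 || cr[1] > cr[2])
    stop("contamination_range must satisfy 0 <= lo <= hi <= 1", call. = FALSE)
  if (any(c(cfg$n_cohorts, cfg$samples_per_cohort, cfg$k,
            cfg$n_signature_genes_per_class, cfg$n_background_genes) < 1))
    stop("all counts must be >= 1", call. = FALSE)
  if (length(cfg$class_hazard_ratios) != cfg$k)
    stop("class_hazard_ratios must have length k", call. = FALSE)
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  structure(cfg, class = "SimulationConfig")
}

sim_class_names <- function(k) paste0("class", seq_len(k))

assign_classes <- function(cfg, phi) {
  n <- cfg$samples_per_cohort
  classes <- sim_class_names(cfg$k)
  if (cfg$labels_from_contamination) {
    # quantile bins of the contamination fraction, sized by the proportions
    sizes <- diff(round(cumsum(c(0, cfg$class_proportions)) * n))
    cls <- character(n)
    cls[order(phi)] <- rep(classes, times = sizes)
    cls
  } else {
    sample(classes, n, replace = TRUE, prob = cfg$class_proportions)
  }
}

simulate_one_cohort <- function(cfg, cohort_id, gene_names, sig_rows,
                                normal_profile) {
  n <- cfg$samples_per_cohort
  n_genes <- length(gene_names)
  classes <- sim_class_names(cfg$k)
  phi <- stats::runif(n, cfg$contamination_range[1], cfg$contamination_range[2])
  cls <- assign_classes(cfg, phi)
  tumor <- matrix(stats::rnorm(n_genes * n, sd = cfg$noise_sd), n_genes, n)
  for (c_idx in seq_len(cfg$k))
    tumor[sig_rows[[c_idx]], cls == classes[c_idx]] <-
      tumor[sig_rows[[c_idx]], cls == classes[c_idx]] +
      cfg$effect_size * cfg$noise_sd
  vals <- sweep(tumor, 2, 1 - phi, `*`) + outer(normal_profile, phi)
  if (cfg$batch_shift_sd > 0)
    vals <- vals + stats::rnorm(n_genes, sd = cfg$batch_shift_sd)
  sample_ids <- sprintf("%s_s%03d", cohort_id, seq_len(n))
  dimnames(vals) <- list(gene_names, sample_ids)
  # subtype-dependent exponential survival with independent exponential
  # censoring calibrated so P(censored) = censor_rate
  rate <- cfg$survival_base_hazard *
    cfg$class_hazard_ratios[match(cls, classes)]
  t_event <- stats::rexp(n, rate)
  if (cfg$censor_rate > 0) {
    c_rate <- cfg$censor_rate * rate / (1 - cfg$censor_rate)
    t_cens <- stats::rexp(n, c_rate)
  } else t_cens <- rep(Inf, n)
  surv <- survival_table(sample_ids, pmin(t_event, t_cens),
                         as.numeric(t_event <= t_cens), cls)
  list(expression = expression_matrix(vals, cohort_id, "synthetic"),
       labels = subtype_labels(stats::setNames(cls, sample_ids),
                               subtype_scheme(classes), "truth"),
       survival = surv,
       contamination = stats::setNames(phi, sample_ids))
}

#' Simulate a multi-cohort dataset with planted subtype structure
#'
#' @param config a [simulation_config()].
#' @return A list with elements `cohorts` (per cohort: `expression`,
#'   `labels`, `survival`, `contamination` — the true per-sample mixing
#'   fraction), `signature` (the planted `GeneSignature` with its
#'   gene -> class direction map), and `config`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(config$seed, {
    m <- config$n_signature_genes_per_class
    n_sig <- config$k * m
    gene_names <- sprintf("G%05d", seq_len(n_sig + config$n_background_genes))
    sig_rows <- split(seq_len(n_sig), rep(seq_len(config$k), each = m))
    normal_profile <- stats::rnorm(length(gene_names))
    cohorts <- lapply(seq_len(config$n_cohorts), function(i)
      simulate_one_cohort(config, sprintf("cohort%d", i), gene_names,
                          sig_rows, normal_profile))
    names(cohorts) <- vapply(cohorts, function(co) co$expression$cohort_id,
                             character(1))
    classes <- sim_class_names(config$k)
    direction <- stats::setNames(rep(classes, each = m),
                                 gene_names[seq_len(n_sig)])
    sig <- gene_signature("planted", gene_names[seq_len(n_sig)],
                          subtype_scheme(classes), direction)
    list(cohorts = cohorts, signature = sig, config = config)
  })
}

#' Simulate a battery of cohorts with different subtype schemes
#'
#' Builds a shared gene universe in which each configuration owns a disjoint
#' block of planted signature genes, and simulates one cohort per
#' configuration over the full universe. Every cohort therefore contains all
#' schemes' signature genes — the other schemes' blocks behave as background
#' for it — mirroring a collection of real cohorts that each carry labels of
#' one subtyping system. Intended input for [build_model_grid()].
#'
#' @param configs list of [simulation_config()]s (one cohort is drawn per
#'   config; `n_cohorts` within each config is ignored).
#' @param seed master seed for the battery.
#' @return A list with `cohorts` (per config: `expression`, `labels`,
#'   `survival`, `contamination`) and `signatures` (one planted signature
#'   per config, named `sig1`, `sig2`, ...).
#' @export
simulate_battery <- function(configs, seed = 1L) {
  stopifnot(length(configs) >= 1,
            all(vapply(configs, inherits, logical(1), "SimulationConfig")))
  withr::with_seed(as.integer(seed), {
    m_per <- vapply(configs, function(c) c$k * c$n_signature_genes_per_class,
                    integer(1))
    n_bg <- max(vapply(configs, `[[`, integer(1), "n_background_genes"))
    total <- sum(m_per) + n_bg
    gene_names <- sprintf("G%05d", seq_len(total))
    offsets <- cumsum(c(0, m_per))
    normal_profile <- stats::rnorm(total)
    sigs <- vector("list", length(configs))
    cohorts <- vector("list", length(configs))
    for (i in seq_along(configs)) {
      cfg <- configs[[i]]
      block <- offsets[i] + seq_len(m_per[i])
      sig_rows <- split(block, rep(seq_len(cfg$k),
                                   each = cfg$n_signature_genes_per_class))
      cohorts[[i]] <- simulate_one_cohort(cfg, sprintf("cohort%d", i),
                                          gene_names, sig_rows, normal_profile)
      classes <- sim_class_names(cfg$k)
      direction <- stats::setNames(
        rep(classes, each = cfg$n_signature_genes_per_class),
        gene_names[block])
      sigs[[i]] <- gene_signature(sprintf("sig%d", i), gene_names[block],
                                  subtype_scheme(classes), direction)
    }
    names(cohorts) <- sprintf("cohort%d", seq_along(configs))
    names(sigs) <- sprintf("sig%d", seq_along(configs))
    list(cohorts = cohorts, signatures = sigs)
  })
}

#' Build a synthetic cell-type reference basis
#'
#' Non-negative reference profiles for a small pancreas-like panel of cell
#' types (ductal, acinar, macrophage, fibroblast by default). Each type gets
#' a block of strongly expressed marker genes on top of a shared low
#' baseline, which keeps the basis well-conditioned for deconvolution.
#'
#' @param n_genes number of genes in the basis.
#' @param cell_types character vector of cell-type names.
#' @param marker_level expression level of a type's marker block.
#' @param seed integer seed.
#' @return An object of class `CellTypeBasis`: list with `basis` (genes x
#'   cell types, non-negative) and `cell_types`.
#' @export
cell_type_basis <- function(n_genes = 200,
                            cell_types = c("ductal", "acinar", "macrophage",
                                           "fibroblast"),
                            marker_level = 5, seed = 42L) {
  n_types <- length(cell_types)
  stopifnot(n_genes >= n_types)
  withr::with_seed(as.integer(seed), {
    B <- matrix(stats::rgamma(n_genes * n_types, shape = 2, rate = 4),
                n_genes, n_types,
                dimnames = list(sprintf("G%05d", seq_len(n_genes)), cell_types))
    per <- n_genes %/% n_types
    for (j in seq_len(n_types)) {
      rows <- ((j - 1) * per + 1):(j * per)
      B[rows, j] <- B[rows, j] + marker_level
    }
    structure(list(basis = B, cell_types = cell_types), class = "CellTypeBasis")
  })
}

#' Simulate bulk mixtures of cell-type profiles
#'
#' Each sample is `basis %*% f + N(0, noise_sd^2)` with mixture fractions
#' `f ~ Dirichlet(dirichlet_alpha)` (or fixed fractions if supplied).
#'
#' @param basis a [cell_type_basis()].
#' @param n_samples number of samples.
#' @param dirichlet_alpha positive Dirichlet concentration vector, one per
#'   cell type.
#' @param noise_sd additive Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @param fractions optional cell types x samples matrix of fixed mixture
#'   fractions (columns summing to 1) overriding the Dirichlet draw.
#' @return List with `expression` (an `ExpressionMatrix`) and `fractions`
#'   (cell types x samples, the ground truth).
#' @export
simulate_mixtures <- function(basis, n_samples,
                              dirichlet_alpha = rep(1, length(basis$cell_types)),
                              noise_sd = 0.05, seed = 1L, fractions = NULL) {
  stopifnot(inherits(basis, "CellTypeBasis"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n_types <- length(basis$cell_types)
  withr::with_seed(as.integer(seed), {
    if (is.null(fractions)) {
      if (length(dirichlet_alpha) != n_types || any(dirichlet_alpha <= 0))
        stop("dirichlet_alpha must be positive, one entry per cell type",
             call. = FALSE)
      g <- matrix(stats::rgamma(n_types * n_samples, shape = dirichlet_alpha),
                  n_types, n_samples)
      fractions <- sweep(g, 2, colSums(g), `/`)
    } else {
      stopifnot(nrow(fractions) == n_types, ncol(fractions) == n_samples)
    }
    rownames(fractions) <- basis$cell_types
    colnames(fractions) <- sprintf("mix_s%03d", seq_len(n_samples))
    vals <- basis$basis %*% fractions
    if (noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), sd = noise_sd),
                            nrow(vals), ncol(vals))
    colnames(vals) <- colnames(fractions)
    list(expression = expression_matrix(vals, "mixture", "synthetic"),
         fractions = fractions)
  })
}

#' Ready-made study scenarios
#'
#' Two reference regimes used throughout the tests and the worked analyses:
#'
#' The two regimes share the same realistic backdrop — a gene universe large
#' enough (5000 background genes) that a size-matched random signature
#' rarely contains planted genes, and tumor purity varying widely
#' (`contamination ~ U[0, 0.8]` on all genes) — and differ only in where
#' the labels come from:
#'
#' * `"signal"` — the subtype signal lives exclusively on the planted
#'   signature genes (`effect_size = 3`); labels are the true subtypes,
#'   independent of purity. Real signatures should beat random ones at
#'   classification, and signature-derived clusters should differ sharply
#'   from random-signature clusters (which all track the shared purity
#'   gradient instead).
#' * `"confounded"` — no subtype signal at all (`effect_size = 0`); labels
#'   are quantile bins of the contamination fraction, which affects every
#'   gene. Any gene set can "predict" these labels, so real and random
#'   signatures perform indistinguishably.
#'
#' @param name `"signal"` or `"confounded"`.
#' @param seed integer seed.
#' @param samples_per_cohort samples per cohort (single cohort).
#' @return A [simulation_config()].
#' @export
scenario_config <- function(name = c("signal", "confounded"), seed = 1L,
                            samples_per_cohort = 150) {
  name <- match.arg(name)
  common <- list(n_cohorts = 1L, samples_per_cohort = samples_per_cohort,
                 k = 2, n_signature_genes_per_class = 25,
                 n_background_genes = 5000, noise_sd = 1, batch_shift_sd = 0,
                 contamination_range = c(0, 0.8),
                 class_hazard_ratios = c(1, 2.5), seed = seed)
  extra <- if (name == "signal") {
    list(effect_size = 3, labels_from_contamination = FALSE)
  } else {
    list(effect_size = 0, labels_from_contamination = TRUE)
  }
  do.call(simulation_config, c(common, extra))
}
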