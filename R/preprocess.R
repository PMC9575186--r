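# Preprocessing contracts: per-gene z-scoring, cross-cohort gene
# intersection and additive batch correction. For cross-cohort
# classification the canonical order is intersect -> merge -> batch-correct
# -> z-score, so that the z-scores are computed on batch-clean values.

#' z-score every gene across samples
#'
#' Each gene row is centred to mean 0 and scaled to sample SD 1 (n - 1
#' denominator). Constant genes have no defined z-score and are dropped;
#' the dropped count is messaged and recorded in the `"n_dropped_constant"`
#' attribute.
#'
#' @param m an `ExpressionMatrix` with >= 2 samples.
#' @return A z-scored `ExpressionMatrix`.
#' @export
zscore_genes <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 2)
    stop("z-scoring needs >= 2 samples", call. = FALSE)
  sds <- apply(m$values, 1, stats::sd)
  constant <- sds == 0
  if (any(constant))
    message(sprintf("zscore_genes: dropped %d constant gene(s)", sum(constant)))
  vals <- m$values[!constant, , drop = FALSE]
  vals <- (vals - rowMeans(vals)) / sds[!constant]
  out <- expression_matrix(vals, m$cohort_id, m$platform)
  attr(out, "n_dropped_constant") <- sum(constant)
  out
}

#' Restrict several cohorts to their common genes
#'
#' All returned matrices share an identical gene vector: the intersection of
#' the inputs, in the first matrix's row order.
#'
#' @param ms list of >= 2 `ExpressionMatrix` objects.
#' @return List of `ExpressionMatrix` objects over the shared genes.
#' @export
intersect_genes <- function(ms) {
  stopifnot(is.list(ms), length(ms) >= 2,
            all(vapply(ms, inherits, logical(1), "ExpressionMatrix")))
  common <- Reduce(intersect, lapply(ms, genes))
  if (length(common) == 0)
    stop("empty gene intersection across cohorts", call. = FALSE)
  common <- genes(ms[[1]])[genes(ms[[1]]) %in% common]
  lapply(ms, function(m)
    expression_matrix(m$values[common, , drop = FALSE], m$cohort_id, m$platform))
}

#' Merge cohorts into one matrix with a batch map
#'
#' Inputs must already share an identical gene vector (see
#' [intersect_genes()]); sample IDs must be globally unique.
#'
#' @param ms list of `ExpressionMatrix` objects over identical genes.
#' @return List with `expression` (merged `ExpressionMatrix`) and `batch`
#'   (named character vector sample -> cohort_id).
#' @export
merge_cohorts <- function(ms) {
  stopifnot(length(ms) >= 2)
  g <- genes(ms[[1]])
  for (m in ms[-1])
    if (!identical(genes(m), g))
      stop("cohorts must share an identical gene vector; run intersect_genes()",
           call. = FALSE)
  vals <- do.call(cbind, unname(lapply(ms, `[[`, "values")))
  batch <- unlist(unname(lapply(ms, function(m)
    stats::setNames(rep(m$cohort_id, ncol(m$values)), samples(m)))))
  list(expression = expression_matrix(vals, "merged", ms[[1]]$platform),
       batch = batch)
}

#' Remove additive per-cohort batch effects
#'
#' Per gene, fits `value = grand effect + batch effect` by least squares
#' with sum-to-zero batch encoding and subtracts the fitted batch terms
#' (via `limma::removeBatchEffect`). For balanced designs the corrected
#' per-gene batch means coincide across batches; the operation is
#' idempotent.
#'
#' @param m merged `ExpressionMatrix`.
#' @param batch named character vector sample -> cohort/batch ID, covering
#'   all samples; >= 2 batches, each with >= 2 samples.
#' @return Batch-corrected `ExpressionMatrix`.
#' @export
remove_batch_effect <- function(m, batch) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!all(samples(m) %in% names(batch)))
    stop("`batch` must label every sample", call. = FALSE)
  b <- factor(batch[samples(m)])
  if (nlevels(b) < 2)
    stop("batch correction needs >= 2 batches", call. = FALSE)
  if (any(table(b) < 2))
    stop("every batch needs >= 2 samples", call. = FALSE)
  corrected <- limma::removeBatchEffect(m$values, batch = b)
  expression_matrix(corrected, m$cohort_id, m$platform)
}

#' Standard cross-cohort preprocessing for classification
#'
#' Applies the canonical order intersect -> merge -> batch-correct ->
#' z-score and splits the merged matrix back into per-cohort matrices.
#'
#' @param ms list of >= 2 `ExpressionMatrix` objects.
#' @return List of preprocessed `ExpressionMatrix` objects, one per input
#'   cohort, over the shared batch-clean z-scored gene universe.
#' @export
preprocess_cohorts <- function(ms) {
  ms <- intersect_genes(ms)
  merged <- merge_cohorts(ms)
  corrected <- remove_batch_effect(merged$expression, merged$batch)
  z <- zscore_genes(corrected)
  lapply(ms, function(m)
    expression_matrix(z$values[, samples(m), drop = FALSE],
                      m$cohort_id, m$platform))
}
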