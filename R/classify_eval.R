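# The 16-model framework: one random-forest subtype classifier per
# (signature x labeled training cohort), evaluated by stratified 5-fold
# cross-validation and applied to external cohorts.

rf_defaults <- list(ntree = 100, criterion = "gini", mtry = "sqrt",
                    bootstrap = TRUE)

feature_matrix <- function(m, feature_genes) {
  missing <- setdiff(feature_genes, genes(m))
  if (length(missing))
    stop("cohort is missing feature gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  t(m$values[feature_genes, , drop = FALSE])
}

#' Train a random-forest subtype classifier
#'
#' Frozen reference defaults: 100 trees, Gini impurity splits, floor(sqrt(p))
#' candidate features per split, bootstrap resampling. Seeded for exact
#' reproducibility.
#'
#' @param features samples x genes numeric matrix.
#' @param labels a `SubtypeLabelSet` (or named character vector) covering
#'   the feature rows; >= 2 classes must be present.
#' @param seed integer seed.
#' @return A fitted `randomForest` classifier.
#' @export
train_classifier <- function(features, labels, seed = 1L) {
  y <- if (inherits(labels, "SubtypeLabelSet")) labels$labels[rownames(features)]
       else labels[rownames(features)]
  if (anyNA(y)) stop("labels must cover every sample in `features`", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) < 2) stop("training labels contain a single class", call. = FALSE)
  withr::with_seed(as.integer(seed),
    randomForest::randomForest(x = features, y = y,
                               ntree = rf_defaults$ntree,
                               mtry = max(1, floor(sqrt(ncol(features))))))
}

#' Mean accuracy from stratified k-fold cross-validation
#'
#' Fold membership is assigned per class (stratified) under the given seed;
#' the reported value is the mean over folds of the held-out accuracy.
#'
#' @inheritParams train_classifier
#' @param folds number of folds (default 5); every class must have at least
#'   `folds` members.
#' @return Mean held-out accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(features, labels, folds = 5, seed = 1L) {
  y <- if (inherits(labels, "SubtypeLabelSet")) labels$labels[rownames(features)]
       else labels[rownames(features)]
  if (anyNA(y)) stop("labels must cover every sample in `features`", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) < 2) stop("labels contain a single class", call. = FALSE)
  if (any(table(y) < folds))
    stop("every class needs >= ", folds, " samples for ", folds,
         "-fold CV", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    fold_id <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    acc <- vapply(seq_len(folds), function(f) {
      train <- fold_id != f
      fit <- randomForest::randomForest(
        x = features[train, , drop = FALSE], y = droplevels(y[train]),
        ntree = rf_defaults$ntree,
        mtry = max(1, floor(sqrt(ncol(features)))))
      pred <- predict(fit, features[!train, , drop = FALSE])
      mean(as.character(pred) == as.character(y[!train]))
    }, numeric(1))
    mean(acc)
  })
}

#' Build the signature x training-cohort model grid
#'
#' One model per (signature, labeled training cohort) pair: features are the
#' signature genes present in the shared preprocessed gene universe, the
#' target is the cohort's subtype labels. With four signatures and four
#' discovery cohorts this is the sixteen-model framework. Pairs whose
#' signature has zero overlap with the cohort's genes are reported as
#' failures rather than aborting the grid.
#'
#' @param signatures named list of `GeneSignature`s.
#' @param training_cohorts named list, one element per cohort, each a list
#'   with `expression` (preprocessed `ExpressionMatrix`) and `labels`
#'   (truth `SubtypeLabelSet`).
#' @param folds CV folds.
#' @param seed master seed; per-model seeds are derived from it via a
#'   counter.
#' @return A list of class `ModelGrid`: `models` (list of `ModelSpec`s,
#'   each with `signature`, `cohort`, `scheme`, `feature_genes`, `fit`,
#'   `cv_accuracy`, `seed`) and `failures` (data.frame of skipped pairs).
#' @export
build_model_grid <- function(signatures, training_cohorts, folds = 5,
                             seed = 1L) {
  stopifnot(length(signatures) >= 1, length(training_cohorts) >= 1)
  for (co in training_cohorts)
    if (is.null(co$labels) || !inherits(co$labels, "SubtypeLabelSet"))
      stop("every training cohort needs truth labels", call. = FALSE)
  models <- list()
  failures <- data.frame(signature = character(), cohort = character(),
                         reason = character(), stringsAsFactors = FALSE)
  counter <- 0L
  for (sn in names(signatures)) {
    for (cn in names(training_cohorts)) {
      counter <- counter + 1L
      sig <- signatures[[sn]]
      co <- training_cohorts[[cn]]
      feats <- intersect(sig$genes, genes(co$expression))
      model_seed <- as.integer(seed) + counter
      if (length(feats) == 0) {
        failures <- rbind(failures, data.frame(
          signature = sn, cohort = cn,
          reason = "no overlap with shared gene universe"))
        next
      }
      X <- feature_matrix(co$expression, feats)
      fit <- train_classifier(X, co$labels, seed = model_seed)
      acc <- cv_accuracy(X, co$labels, folds = folds, seed = model_seed)
      models[[paste(sn, cn, sep = ".")]] <- structure(
        list(signature = sn, cohort = cn, scheme = co$labels$scheme,
             feature_genes = feats, fit = fit, cv_accuracy = acc,
             seed = model_seed),
        class = "ModelSpec")
    }
  }
  structure(list(models = models, failures = failures), class = "ModelGrid")
}

#' @export
print.ModelGrid <- function(x, ...) {
  cat(sprintf("ModelGrid: %d models, %d failures\n", length(x$models),
              nrow(x$failures)))
  for (m in x$models)
    cat(sprintf("  %s on %s: %d features, CV accuracy %.3f\n",
                m$signature, m$cohort, length(m$feature_genes), m$cv_accuracy))
  invisible(x)
}

#' Predict subtype labels on an external cohort
#'
#' @param model a `ModelSpec` from [build_model_grid()].
#' @param cohort an `ExpressionMatrix` containing all of the model's feature
#'   genes.
#' @return A `SubtypeLabelSet` with origin `"predicted"` in the model's
#'   scheme.
#' @export
predict_external <- function(model, cohort) {
  stopifnot(inherits(model, "ModelSpec"), inherits(cohort, "ExpressionMatrix"))
  X <- feature_matrix(cohort, model$feature_genes)
  pred <- as.character(predict(model$fit, X))
  subtype_labels(stats::setNames(pred, rownames(X)), model$scheme, "predicted")
}

#' Contingency table of two label sets over the same samples
#'
#' Counts co-assignments of two labelings (possibly under different subtype
#' schemes); rows are the first scheme's classes, columns the second's, and
#' the total equals the number of samples.
#'
#' @param a,b `SubtypeLabelSet`s over the same samples.
#' @return A contingency `table`.
#' @export
cross_scheme_confusion <- function(a, b) {
  stopifnot(inherits(a, "SubtypeLabelSet"), inherits(b, "SubtypeLabelSet"))
  if (!setequal(names(a$labels), names(b$labels)))
    stop("label sets cover different samples", call. = FALSE)
  ids <- names(a$labels)
  table(factor(a$labels[ids], levels = a$scheme$classes),
        factor(b$labels[ids], levels = b$scheme$classes),
        dnn = c("a", "b"))
}
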