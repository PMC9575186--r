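#' Construct an expression matrix
#'
#' The universal container of the pipeline: a numeric genes x samples matrix
#' of normalized expression values with cohort and platform metadata. Gene
#' symbols and sample identifiers must be unique; missing values are not
#' allowed (readers drop incomplete gene rows at ingestion, see
#' [read_expression()]).
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs).
#' @param cohort_id cohort identifier string.
#' @param platform one of `"array"`, `"rnaseq"`, `"synthetic"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, cohort_id = "cohort",
                              platform = c("synthetic", "array", "rnaseq")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  rownames(values) <- trimws(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in expression matrix", call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)
  structure(list(values = values, cohort_id = cohort_id, platform = platform),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s' [%s]: %d genes x %d samples\n",
              x$cohort_id, x$platform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene symbols of an expression matrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of gene symbols (row order).
#' @export
genes <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of sample IDs (column order).
#' @export
samples <- function(x) colnames(x$values)

#' Restrict an expression matrix to a gene subset
#'
#' Keeps the matrix row order for the genes present; genes absent from the
#' matrix are silently dropped (the overlap size is recorded in the
#' `"overlap"` attribute, mirroring how signatures are filtered per dataset).
#'
#' @param x an `ExpressionMatrix`.
#' @param gene_set character vector of gene symbols.
#' @return An `ExpressionMatrix` over `intersect(genes(x), gene_set)`.
#' @export
restrict_genes <- function(x, gene_set) {
  keep <- genes(x) %in% gene_set
  if (!any(keep)) stop("no overlap between gene set and matrix genes", call. = FALSE)
  out <- expression_matrix(x$values[keep, , drop = FALSE], x$cohort_id, x$platform)
  attr(out, "overlap") <- sum(keep)
  out
}

#' Describe a subtype scheme
#'
#' A scheme is the set of class names of one subtyping system (e.g. the
#' basal-like/classical dichotomy, k = 2, or a five-class scheme, k = 5).
#'
#' @param classes character vector of distinct class names, length >= 2.
#' @return An object of class `SubtypeScheme` with fields `classes` and `k`.
#' @export
subtype_scheme <- function(classes) {
  classes <- as.character(classes)
  if (anyDuplicated(classes) || length(classes) < 2)
    stop("a subtype scheme needs >= 2 distinct class names", call. = FALSE)
  structure(list(classes = classes, k = length(classes)), class = "SubtypeScheme")
}

#' Construct a gene signature
#'
#' A published (or planted, or random) gene list used to assign samples to
#' the classes of one subtype scheme. The optional `direction` map records,
#' per gene, the class in which the gene is up-regulated.
#'
#' @param name signature name.
#' @param genes character vector of gene symbols; duplicates are dropped
#'   (first occurrence kept) with a message.
#' @param scheme a `SubtypeScheme`, or `NULL` for plain gene sets
#'   (e.g. pathway terms used for enrichment scoring).
#' @param direction optional named character vector gene -> class name.
#' @return An object of class `GeneSignature`.
#' @export
gene_signature <- function(name, genes, scheme = NULL, direction = NULL) {
  genes <- trimws(as.character(genes))
  if (length(genes) == 0) stop("signature '", name, "' has an empty gene list",
                               call. = FALSE)
  if (anyDuplicated(genes)) {
    message(sprintf("signature '%s': dropped %d duplicate gene entries",
                    name, sum(duplicated(genes))))
    genes <- genes[!duplicated(genes)]
  }
  if (!is.null(scheme) && !inherits(scheme, "SubtypeScheme"))
    stop("`scheme` must be a SubtypeScheme", call. = FALSE)
  if (!is.null(direction)) {
    if (is.null(scheme) || !all(direction %in% scheme$classes))
      stop("`direction` values must be classes of `scheme`", call. = FALSE)
    direction <- direction[names(direction) %in% genes]
  }
  structure(list(name = name, genes = genes, scheme = scheme,
                 direction = direction), class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  k <- if (is.null(x$scheme)) NA_integer_ else x$scheme$k
  cat(sprintf("GeneSignature '%s': %d genes, k = %s\n", x$name,
              length(x$genes), k))
  invisible(x)
}

#' Construct a subtype label set
#'
#' Per-sample class assignments for one scheme, tagged with their origin:
#' `"truth"` (given labels), `"cluster"` (unsupervised), or `"predicted"`
#' (classifier output).
#'
#' @param labels named character vector, names = sample IDs, values = class
#'   names belonging to `scheme`.
#' @param scheme a `SubtypeScheme`.
#' @param origin one of `"truth"`, `"cluster"`, `"predicted"`.
#' @return An object of class `SubtypeLabelSet`.
#' @export
subtype_labels <- function(labels, scheme, origin = c("truth", "cluster", "predicted")) {
  origin <- match.arg(origin)
  if (is.null(names(labels))) stop("`labels` must be named by sample ID", call. = FALSE)
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!all(labels %in% scheme$classes))
    stop("labels outside the scheme's classes: ",
         paste(unique(setdiff(labels, scheme$classes)), collapse = ", "),
         call. = FALSE)
  structure(list(labels = labels, scheme = scheme, origin = origin),
            class = "SubtypeLabelSet")
}

#' @export
print.SubtypeLabelSet <- function(x, ...) {
  cat(sprintf("SubtypeLabelSet (%s): %d samples, k = %d\n", x$origin,
              length(x$labels), x$scheme$k))
  print(table(x$labels))
  invisible(x)
}

#' Construct a survival table
#'
#' @param sample sample IDs.
#' @param time follow-up time in months, non-negative.
#' @param event event indicator, 1 = death observed, 0 = censored.
#' @param group optional class name per sample.
#' @return A `data.frame` of class `SurvivalTable` with columns
#'   `sample`, `time`, `event`, `group`.
#' @export
survival_table <- function(sample, time, event, group = NA_character_) {
  time <- as.numeric(time); event <- as.numeric(event)
  if (any(time < 0)) stop("survival times must be >= 0", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  group <- rep(as.character(group), length.out = length(sample))
  out <- data.frame(sample = as.character(sample), time = time, event = event,
                    group = group, stringsAsFactors = FALSE)
  class(out) <- c("SurvivalTable", "data.frame")
  out
}

#' Construct a null distribution of replicate statistics
#'
#' @param setting one of `"real"`, `"random_signature"`, `"shuffled_labels"`,
#'   or for clustering nulls `"real_vs_random"`, `"random_vs_random"`.
#' @param statistic one of `"cv_accuracy"`, `"ari"`.
#' @param values numeric vector of replicate statistics.
#' @param seed the seed the battery was run under.
#' @return An object of class `NullDistribution`.
#' @export
null_distribution <- function(setting, statistic = c("cv_accuracy", "ari"),
                              values, seed = NA_integer_) {
  statistic <- match.arg(statistic)
  values <- as.numeric(values)
  if (statistic == "cv_accuracy" && any(values < 0 | values > 1))
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  if (any(values > 1 + 1e-12)) stop("ARI values cannot exceed 1", call. = FALSE)
  structure(list(setting = setting, statistic = statistic, values = values,
                 n_reps = length(values), seed = seed),
            class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat(sprintf("NullDistribution [%s, %s]: %d reps, median %.3f, max %.3f\n",
              x$setting, x$statistic, x$n_reps, stats::median(x$values),
              max(x$values)))
  invisible(x)
}
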