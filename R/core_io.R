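# Readers/writers for the plain-text formats the pipeline exchanges:
# expression TSV/GCT, signature GMT/TSV, label and survival TSV.

#' Collapse duplicate gene rows to their element-wise median
#'
#' When several probes (rows) map to the same gene symbol, the ingested
#' expression value is the per-sample median across those rows.
#'
#' @param rows numeric matrix (>= 1 row) of the value vectors sharing one
#'   symbol, or a single numeric vector.
#' @return A numeric vector, the element-wise median across rows.
#' @export
collapse_duplicates <- function(rows) {
  if (is.vector(rows)) return(as.numeric(rows))
  if (!is.matrix(rows) || nrow(rows) < 1)
    stop("`rows` must be a matrix with >= 1 row", call. = FALSE)
  if (nrow(rows) == 1) return(as.numeric(rows[1, ]))
  apply(rows, 2, stats::median)
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV dialect: header row, first column the gene symbol, remaining columns
#' one per sample. GCT dialect: v1.2 (`#1.2` line, dimensions line, header
#' `Name`/`Description`/samples). Rows with any missing value are dropped
#' (count recorded in the `"n_dropped_missing"` attribute and messaged);
#' rows sharing a gene symbol are collapsed to their element-wise median
#' via [collapse_duplicates()].
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @param cohort_id cohort identifier attached to the result.
#' @param platform platform tag attached to the result.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "gct"),
                            cohort_id = basename(path),
                            platform = c("synthetic", "array", "rnaseq")) {
  format <- match.arg(format)
  platform <- match.arg(platform)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "gct") {
    header <- readLines(path, n = 2)
    if (length(header) < 2 || !grepl("^#1\\.2", header[1]))
      stop("malformed GCT header (expected '#1.2'): ", path, call. = FALSE)
    raw <- utils::read.delim(path, skip = 2, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 3 || names(raw)[1] != "Name")
      stop("malformed GCT column header (expected Name/Description/...)",
           call. = FALSE)
    gene_col <- raw[[1]]
    value_df <- raw[, -(1:2), drop = FALSE]
  } else {
    raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 2)
      stop("malformed TSV header: need a gene column plus >= 1 sample", call. = FALSE)
    gene_col <- raw[[1]]
    value_df <- raw[, -1, drop = FALSE]
  }
  values <- matrix(NA_real_, nrow(value_df), ncol(value_df),
                   dimnames = list(NULL, names(value_df)))
  for (j in seq_len(ncol(value_df))) {
    col <- value_df[[j]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & col != "NA" & col != "" & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                     bad[1], names(value_df)[j], col[bad[1]]), call. = FALSE)
      col <- num
    }
    values[, j] <- as.numeric(col)
  }
  incomplete <- rowSums(is.na(values)) > 0
  if (any(incomplete))
    message(sprintf("read_expression: dropped %d gene row(s) with missing values",
                    sum(incomplete)))
  n_dropped <- sum(incomplete)
  values <- values[!incomplete, , drop = FALSE]
  gene_col <- trimws(gene_col[!incomplete])
  # collapse duplicate symbols to the element-wise median, preserving first-
  # occurrence order
  if (anyDuplicated(gene_col)) {
    keep_order <- unique(gene_col)
    values <- t(vapply(keep_order, function(g) {
      collapse_duplicates(values[gene_col == g, , drop = FALSE])
    }, numeric(ncol(values))))
    gene_col <- keep_order
  }
  rownames(values) <- gene_col
  out <- expression_matrix(values, cohort_id = cohort_id, platform = platform)
  attr(out, "n_dropped_missing") <- n_dropped
  out
}

#' Write an expression matrix as TSV
#'
#' Full-precision round-trip companion of [read_expression()].
#'
#' @param m an `ExpressionMatrix`.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = genes(m), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene signatures from GMT or two-column TSV
#'
#' GMT: one gene set per line (`name<TAB>description<TAB>gene1<TAB>...`);
#' each line becomes a scheme-less signature (schemes are attached by the
#' registry or by the caller). TSV: columns `gene` and `class`; the scheme is
#' inferred from the distinct class values and the class map becomes the
#' signature's `direction`. A gene listed under two classes is ambiguous and
#' raises an error.
#'
#' @param path file path.
#' @param format `"gmt"` or `"tsv"`.
#' @param name signature name for the TSV dialect (default: file stem).
#' @return For GMT a named list of `GeneSignature`s, for TSV a single
#'   `GeneSignature`.
#' @export
read_signature <- function(path, format = c("gmt", "tsv"),
                           name = sub("\\.[^.]*$", "", basename(path))) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sigs <- lapply(lines, function(l) {
      fields <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 3)
        stop("GMT line with empty gene list: ", fields[1], call. = FALSE)
      gene_signature(fields[1], fields[-(1:2)])
    })
    names(sigs) <- vapply(sigs, `[[`, character(1), "name")
    return(sigs)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "class") %in% names(df)))
    stop("signature TSV needs columns 'gene' and 'class'", call. = FALSE)
  df$gene <- trimws(df$gene)
  amb <- tapply(df$class, df$gene, function(x) length(unique(x)) > 1)
  if (any(amb))
    stop("gene(s) assigned to more than one class: ",
         paste(utils::head(names(amb)[amb], 5), collapse = ", "), call. = FALSE)
  df <- df[!duplicated(df$gene), , drop = FALSE]
  scheme <- subtype_scheme(unique(df$class))
  gene_signature(name, df$gene, scheme,
                 direction = stats::setNames(df$class, df$gene))
}

#' Read subtype labels from TSV
#'
#' Expects columns `sample` and `label`.
#'
#' @param path file path.
#' @param scheme optional `SubtypeScheme`; inferred from the distinct labels
#'   when `NULL`.
#' @param origin label origin tag.
#' @return A `SubtypeLabelSet`.
#' @export
read_labels <- function(path, scheme = NULL, origin = "truth") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "label") %in% names(df)))
    stop("label TSV needs columns 'sample' and 'label'", call. = FALSE)
  if (is.null(scheme)) scheme <- subtype_scheme(unique(df$label))
  subtype_labels(stats::setNames(df$label, df$sample), scheme, origin)
}

#' Write subtype labels as TSV
#' @param labels a `SubtypeLabelSet`.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample = names(labels$labels),
                                label = unname(labels$labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' Expects columns `sample`, `time`, `event` and optionally `group`.
#'
#' @param path file path.
#' @return A `SurvivalTable`.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(df)))
    stop("survival TSV needs columns 'sample', 'time', 'event'", call. = FALSE)
  survival_table(df$sample, df$time, df$event,
                 if ("group" %in% names(df)) df$group else NA_character_)
}

#' Write a survival table as TSV
#' @param tab a `SurvivalTable`.
#' @param path output path.
#' @export
write_survival <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

registry_dir <- function() {
  system.file("extdata", "signatures", package = "sigrobust", mustWork = TRUE)
}

#' Names of the registered subtype signatures
#' @return character vector of registry keys.
#' @export
registry_names <- function() {
  reg <- utils::read.delim(file.path(registry_dir(), "registry.tsv"),
                           stringsAsFactors = FALSE)
  reg$name
}

#' Fetch a registered subtype signature
#'
#' The registry carries five packaged signatures with the published sizes
#' and schemes of the four PDAC subtyping systems: `moffitt_tumor` (50
#' genes, basal-like/classical), `moffitt_stroma` (48 genes,
#' activated/normal stroma), `collisson` (62 genes, 3 classes), `bailey`
#' (613 genes, 4 classes) and `puleo` (403 genes, 5 classes). The packaged
#' gene lists are synthetic stand-ins (the published supplementary lists are
#' not redistributed here); sizes, schemes and class maps follow the
#' published systems and a checksum file guards the fixtures against drift.
#'
#' @param name one of [registry_names()].
#' @return A `GeneSignature` with the published size and scheme.
#' @export
registry_get <- function(name) {
  dir <- registry_dir()
  reg <- utils::read.delim(file.path(dir, "registry.tsv"),
                           stringsAsFactors = FALSE)
  row <- reg[reg$name == name, ]
  if (nrow(row) != 1)
    stop("unknown signature '", name, "'; registered: ",
         paste(reg$name, collapse = ", "), call. = FALSE)
  sig <- read_signature(file.path(dir, row$file), format = "tsv", name = name)
  if (length(sig$genes) != row$size)
    stop("registry fixture for '", name, "' has drifted: expected ",
         row$size, " genes, found ", length(sig$genes), call. = FALSE)
  expected_classes <- strsplit(row$classes, ",", fixed = TRUE)[[1]]
  sig$scheme <- subtype_scheme(expected_classes)
  sig
}

#' Verify the registry fixtures against their checksums
#'
#' @return invisibly `TRUE`; errors if any fixture file's md5 differs from
#'   the packaged checksum.
#' @export
registry_verify <- function() {
  dir <- registry_dir()
  sums <- utils::read.delim(file.path(dir, "checksums.tsv"),
                            stringsAsFactors = FALSE)
  actual <- tools::md5sum(file.path(dir, sums$file))
  bad <- sums$file[unname(actual) != sums$md5]
  if (length(bad))
    stop("registry fixture(s) changed since packaging: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
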