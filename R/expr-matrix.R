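#' Expression matrix container
#'
#' A light matrix-backed container for a genes x samples expression table on
#' the log2 scale, together with a per-sample group label (e.g. `"LN"` vs
#' `"control"`, or `"responder"` vs `"non-responder"`), a dataset identifier
#' and a tissue compartment. Values are assumed to be already normalized and
#' log-scale; the package validates but never re-normalizes.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param labels Named character vector mapping every sample id to its group
#'   label, or a data frame with columns `sample` and `label`.
#' @param dataset_id Single string identifying the dataset.
#' @param compartment Single string, e.g. `"glomeruli"`,
#'   `"tubulointerstitium"`, `"blood"` or `"panel"`.
#' @param allow_missing Allow `NA` cells (only sensible for targeted-panel
#'   cohorts, where per-gene missingness feeds the dataset-exclusion rule).
#'
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, labels, dataset_id = "dataset",
                              compartment = "tissue", allow_missing = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    ln_stop("`values` must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    ln_stop("`values` must have rownames (genes) and colnames (samples)")
  if (anyDuplicated(genes))
    ln_stop("duplicate gene symbols: %s",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    ln_stop("duplicate sample ids: %s",
            paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (is.data.frame(labels)) {
    if (!all(c("sample", "label") %in% names(labels)))
      ln_stop("label table must have columns `sample` and `label`")
    labels <- stats::setNames(as.character(labels$label), labels$sample)
  }
  missing_lab <- setdiff(samples, names(labels))
  if (length(missing_lab))
    ln_stop("no label for sample(s): %s", paste(missing_lab, collapse = ", "))
  labels <- labels[samples]
  if (!allow_missing && anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    ln_stop("missing value at gene %s, sample %s (missing values are only allowed in panel cohorts)",
            genes[idx[1]], samples[idx[2]])
  }
  structure(
    list(values = values, labels = labels,
         dataset_id = as.character(dataset_id)[1],
         compartment = as.character(compartment)[1]),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s [%s]: %d genes x %d samples\n",
              x$dataset_id, x$compartment, nrow(x$values), ncol(x$values)))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

em_genes <- function(x) rownames(x$values)
em_samples <- function(x) colnames(x$values)

# Subset an expr_matrix by sample ids and/or gene symbols.
em_subset <- function(x, samples = NULL, genes = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[intersect(genes, rownames(v)), , drop = FALSE]
  if (!is.null(samples)) v <- v[, intersect(samples, colnames(v)), drop = FALSE]
  expression_matrix(v, x$labels[colnames(v)], x$dataset_id, x$compartment,
                    allow_missing = TRUE)
}

#' Tidy an expression matrix into long form
#'
#' @param x An [expression_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `value`, `label`,
#'   `dataset_id`, `compartment`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    label = rep(unname(x$labels), each = nrow(x$values)),
    dataset_id = x$dataset_id,
    compartment = x$compartment
  )
}

#' Read an expression table plus sample labels
#'
#' Reads a TSV/CSV expression table (gene symbols in the first column, sample
#' ids in the header) and a two-column label table (`sample`, `label`).
#' Duplicate gene rows are collapsed by their mean, preserving first-occurrence
#' order. Any non-numeric cell or unlabeled sample is a hard error.
#'
#' @param path Path to the expression table (`.tsv`/`.txt` tab-separated,
#'   `.csv` comma-separated).
#' @param labels_path Path to the label table (same delimiter convention,
#'   header `sample`, `label`).
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, labels_path, dataset_id = NULL,
                                  compartment = "tissue", allow_missing = FALSE) {
  dataset_id <- dataset_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- read_delim_auto(path)
  if (ncol(raw) < 2) ln_stop("expression table needs a gene column plus >=1 sample")
  genes <- as.character(raw[[1]])
  samples <- names(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & !(trimws(as.character(col)) %in% c("", "NA")))
    if (length(bad))
      ln_stop("non-numeric cell at row %d (gene %s), column %s: '%s'",
              bad[1], genes[bad[1]], samples[j], col[bad[1]])
    vals[, j] <- num
  }
  # collapse duplicate gene rows by mean, order preserved from first occurrence
  if (anyDuplicated(genes)) {
    keep <- unique(genes)
    vals <- do.call(rbind, lapply(keep, function(g) {
      colMeans(vals[genes == g, , drop = FALSE], na.rm = TRUE)
    }))
    genes <- keep
  }
  vals[is.nan(vals)] <- NA_real_
  rownames(vals) <- genes
  lab <- read_delim_auto(labels_path)
  if (!all(c("sample", "label") %in% names(lab)))
    ln_stop("label file %s must have header columns `sample` and `label`", labels_path)
  labels <- stats::setNames(as.character(lab$label), as.character(lab$sample))
  expression_matrix(vals, labels, dataset_id, compartment,
                    allow_missing = allow_missing)
}

#' Write an expression table plus label table
#'
#' Inverse of [read_expression_table()]; a write-then-read round trip
#' reproduces the object exactly (up to duplicate-row collapsing, which the
#' container already forbids).
#'
#' @param x An [expression_matrix()].
#' @param path,labels_path Output paths; delimiter chosen from the extension.
#' @return `x`, invisibly.
#' @export
write_expression_table <- function(x, path, labels_path) {
  df <- tibble::as_tibble(x$values, rownames = "gene")
  write_delim_auto(df, path)
  write_delim_auto(tibble(sample = names(x$labels), label = unname(x$labels)),
                   labels_path)
  invisible(x)
}

read_delim_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  else
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
}

write_delim_auto <- function(df, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::write_csv(df, path, progress = FALSE)
  else readr::write_tsv(df, path, progress = FALSE)
}
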