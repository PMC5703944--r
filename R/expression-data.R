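#' Construct an expression dataset
#'
#' Bundles a genes-by-samples matrix of expression values with a binary
#' class label per sample. By convention label 0 marks the cancerous
#' (case) class and 1 the normal (control) class, but any binary coding
#' works: every downstream statistic is either symmetric in the classes
#' or documents its sign convention.
#'
#' @param values Numeric matrix (genes in rows, samples in columns) or a
#'   data frame with gene ids in the first column. Row names (or the id
#'   column) become gene ids; column names become sample ids. Missing ids
#'   are filled in as `gene1..m` / `sample1..n`.
#' @param labels Vector of class codes, one per sample, coercible to
#'   integer 0/1.
#' @param label_map Optional named integer vector recording which raw
#'   label value was mapped to 0 and which to 1 (kept for provenance by
#'   [read_expression()]).
#'
#' @return An object of class `expr_dataset`: a list with elements
#'   `values` (m x n numeric matrix with dimnames), `labels` (named
#'   integer vector of 0/1), and `label_map`.
#'
#' @examples
#' x <- matrix(rnorm(24), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
#' ds <- expression_dataset(x, labels = c(0, 0, 0, 1, 1, 1))
#' ds
#' @export
expression_dataset <- function(values, labels, label_map = NULL) {
  if (is.data.frame(values)) {
    ids <- as.character(values[[1]])
    values <- as.matrix(values[, -1, drop = FALSE])
    rownames(values) <- ids
  }
  if (!is.matrix(values)) {
    abort("`values` must be a matrix or a data frame with gene ids in column 1.")
  }
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  }
  labels <- as.integer(labels)
  names(labels) <- colnames(values)
  out <- structure(
    list(values = values, labels = labels, label_map = label_map),
    class = "expr_dataset"
  )
  validate_expression_dataset(out)
}

validate_expression_dataset <- function(x) {
  v <- x$values
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Missing expression value for gene '%s' in sample '%s'.",
      rownames(v)[bad[1]], colnames(v)[bad[2]]
    ))
  }
  if (nrow(v) < 2) abort("At least 2 genes are required.")
  if (ncol(v) < 4) abort("At least 4 samples are required.")
  dup <- rownames(v)[duplicated(rownames(v))]
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene ids: ", paste(unique(dup), collapse = ", ")))
  }
  if (anyDuplicated(colnames(v))) abort("Sample ids must be distinct.")
  if (length(x$labels) != ncol(v)) {
    abort("`labels` must have one entry per sample.")
  }
  if (anyNA(x$labels) || !all(x$labels %in% c(0L, 1L))) {
    abort("`labels` must be binary 0/1 with no missing values.")
  }
  n0 <- sum(x$labels == 0L)
  n1 <- sum(x$labels == 1L)
  if (n0 < 2 || n1 < 2) {
    abort(sprintf(
      "Both classes need at least 2 samples (got %d in class 0, %d in class 1).",
      n0, n1
    ))
  }
  x
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset> %d genes x %d samples (class 0: %d, class 1: %d)\n",
    nrow(x$values), ncol(x$values),
    sum(x$labels == 0L), sum(x$labels == 1L)
  ))
  if (!is.null(x$label_map)) {
    cat("  label mapping:",
        paste(sprintf("'%s' -> %d", names(x$label_map), x$label_map),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Gene and sample identifiers
#'
#' @param x An `expr_dataset` or `rank_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) {
  rownames(if (inherits(x, "rank_matrix")) x$ranks else x$values)
}

#' @rdname gene_ids
#' @export
sample_ids <- function(x) {
  colnames(if (inherits(x, "rank_matrix")) x$ranks else x$values)
}

#' Keep a subset of samples
#'
#' Used by the nested cross-validation mode, where screening is redone
#' inside each training fold.
#'
#' @param data An `expr_dataset`.
#' @param idx Integer or logical index over samples.
#' @return An `expr_dataset` restricted to the selected samples.
#' @export
subset_samples <- function(data, idx) {
  expression_dataset(data$values[, idx, drop = FALSE],
                     data$labels[idx],
                     label_map = data$label_map)
}

#' @export
tidy.expr_dataset <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    label = rep(unname(x$labels), each = nrow(x$values))
  )
}

#' @export
glance.expr_dataset <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$values),
    n_samples = ncol(x$values),
    n_class0 = sum(x$labels == 0L),
    n_class1 = sum(x$labels == 1L)
  )
}
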