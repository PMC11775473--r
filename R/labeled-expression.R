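#' Labeled expression container
#'
#' Internal canonical form of a two-group expression dataset: a numeric
#' samples x genes matrix plus a two-level factor of class labels. The
#' class-1 / class-2 mapping follows the convention that the
#' lexicographically smaller label is class 1 unless `class1` overrides it.
#'
#' User-facing functions accept either this object or a wide tibble with one
#' row per sample, a label column and one numeric column per gene.
#'
#' @param values Numeric samples x genes matrix; column names are gene ids.
#' @param labels Per-sample labels (two distinct values).
#' @param sample_ids Optional sample identifiers.
#' @param class1 Optional label value to treat as class 1.
#' @return A `labeled_expression` object.
#' @export
labeled_expression <- function(values, labels, sample_ids = NULL,
                               class1 = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) abort("`values` must have gene column names")
  if (anyDuplicated(colnames(values))) abort("duplicate gene ids in `values`")
  if (!is.numeric(values)) abort("`values` must be numeric")
  if (length(labels) != nrow(values)) {
    abort("`labels` length must equal the number of samples")
  }
  lev <- sort(unique(as.character(labels)))
  if (!is.null(class1)) {
    class1 <- as.character(class1)
    if (!class1 %in% lev) abort("`class1` is not an observed label")
    lev <- c(class1, setdiff(lev, class1))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  }
  rownames(values) <- sample_ids
  structure(
    list(values = values,
         labels = factor(as.character(labels), levels = lev),
         sample_ids = as.character(sample_ids)),
    class = "labeled_expression")
}

#' Coerce a wide tibble (or labeled_expression) to labeled_expression
#'
#' @param x A `labeled_expression`, or a data frame with a label column, an
#'   optional sample-id column, and numeric gene columns.
#' @param label_col,sample_col Column names used when `x` is a data frame.
#' @inheritParams labeled_expression
#' @export
as_labeled_expression <- function(x, label_col = "label",
                                  sample_col = "sample_id", class1 = NULL) {
  if (inherits(x, "labeled_expression")) return(x)
  if (!is.data.frame(x)) abort("expected a data frame or labeled_expression")
  if (!label_col %in% names(x)) {
    abort(sprintf("label column '%s' not found", label_col))
  }
  labels <- x[[label_col]]
  ids <- if (sample_col %in% names(x)) as.character(x[[sample_col]]) else NULL
  gene_cols <- setdiff(names(x), c(label_col, sample_col))
  if (length(gene_cols) == 0L) abort("no gene columns found")
  bad <- gene_cols[!vapply(x[gene_cols], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("non-numeric gene columns: ", paste(head(bad, 5), collapse = ", ")))
  }
  labeled_expression(as.matrix(x[gene_cols]), labels, sample_ids = ids,
                     class1 = class1)
}

#' @export
print.labeled_expression <- function(x, ...) {
  cat(sprintf("labeled expression: %d samples x %d genes (classes: %s = %d, %s = %d)\n",
              nrow(x$values), ncol(x$values),
              levels(x$labels)[1], sum(x$labels == levels(x$labels)[1]),
              levels(x$labels)[2], sum(x$labels == levels(x$labels)[2])))
  invisible(x)
}

#' Convert a labeled_expression back to a wide tibble
#'
#' @param x A `labeled_expression`.
#' @param ... Unused.
#' @export
tidy.labeled_expression <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = x$sample_ids,
                   label = as.character(x$labels)),
    tibble::as_tibble(x$values))
}
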