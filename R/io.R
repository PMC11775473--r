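#' Read a labelled expression table
#'
#' Tab-separated, '.' decimal, UTF-8. In `samples_by_genes` orientation the
#' file has one row per sample: a sample-id column, a label column and one
#' numeric column per gene. In `genes_by_samples` orientation the file has
#' one row per gene (first column the gene id, remaining columns the
#' samples) plus one row whose id equals `label_column` carrying the
#' per-sample labels; it is transposed into the canonical form on read.
#' Gene identifiers are opaque strings; the class-1 mapping follows
#' [labeled_expression()] (lexicographically smaller label unless `class1`
#' overrides).
#'
#' @param path File path.
#' @param orientation `"samples_by_genes"` or `"genes_by_samples"`.
#' @param label_column Name of the label column (or label row id).
#' @param sample_column Name of the sample-id column.
#' @param class1 Optional label value mapped to class 1.
#' @return A wide tibble (`sample_id`, `label`, gene columns).
#' @export
read_expression <- function(path,
                            orientation = c("samples_by_genes",
                                            "genes_by_samples"),
                            label_column = "label",
                            sample_column = "sample_id",
                            class1 = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (orientation == "genes_by_samples") {
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      abort(sprintf("duplicate gene id in rows: %s",
                    ids[duplicated(ids)][1]))
    }
    li <- which(ids == label_column)
    if (!length(li)) {
      abort(sprintf("label row '%s' not found", label_column))
    }
    labels <- as.character(unlist(df[li, -1]))
    genes <- ids[-li]
    mat <- t(as.matrix(df[-li, -1, drop = FALSE]))
    mode(mat) <- "numeric"
    colnames(mat) <- genes
    df <- data.frame(sample_id = colnames(df)[-1], label = labels,
                     mat, check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1:2] <- c(sample_column, label_column)
  }
  if (!label_column %in% names(df)) {
    abort(sprintf("label column '%s' not found", label_column))
  }
  gene_cols <- names(df)[!names(df) %in% c(label_column, sample_column)]
  if (anyDuplicated(gene_cols)) {
    abort(sprintf("duplicate gene column: %s",
                  gene_cols[duplicated(gene_cols)][1]))
  }
  for (g in gene_cols) {
    v <- df[[g]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !all(is.na(v))) {
        bad <- which(is.na(vn) & !is.na(v))[1]
        abort(sprintf("non-numeric cell in column '%s', row %d", g, bad))
      }
      df[[g]] <- vn
    }
  }
  out <- tibble::as_tibble(df)
  nm <- names(out)
  nm[nm == label_column] <- "label"
  if (sample_column %in% nm) nm[nm == sample_column] <- "sample_id"
  names(out) <- nm
  if (!"sample_id" %in% names(out)) {
    out <- dplyr::bind_cols(
      tibble::tibble(sample_id = paste0("s", seq_len(nrow(out)))), out)
  }
  lev <- sort(unique(out$label))
  if (!is.null(class1)) lev <- c(class1, setdiff(lev, class1))
  dplyr::relocate(out, "sample_id", "label")
}

#' Write a labelled expression table
#'
#' @param data Wide tibble or [labeled_expression()].
#' @param path File path.
#' @inheritParams read_expression
#' @export
write_expression <- function(data, path, label_col = "label",
                             sample_col = "sample_id") {
  if (inherits(data, "labeled_expression")) data <- tidy(data)
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are deduplicated with a warning; duplicate set names and lines with
#' fewer than three fields are errors (reported with line numbers).
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of gene-id character vectors, with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicate set name: %s", nms[duplicated(nms)][1]))
  }
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(seq_along(parts), function(i) {
    g <- parts[[i]][-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warn(sprintf("duplicate genes in set '%s' deduplicated", nms[i]))
      g <- unique(g)
    }
    g
  })
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(desc, nms)
  sets
}

#' @rdname read_gmt
#' @param collection Named list of gene-id vectors.
#' @param descriptions Optional per-set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(names(collection))) abort("collection must be named")
  desc <- descriptions %||% attr(collection, "descriptions") %||%
    stats::setNames(rep("na", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene-interaction edge list
#'
#' Two tab-separated gene ids per line, with or without a header.
#'
#' @param path File path.
#' @return Tibble with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  header <- length(first) >= 2L &&
    all(tolower(first[1:2]) %in% c("from", "to", "gene_a", "gene_b"))
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("edge list needs two tab-separated columns")
  tibble::tibble(from = as.character(df[[1]]), to = as.character(df[[2]]))
}
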