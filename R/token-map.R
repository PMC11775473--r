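#' Deterministic gene token map
#'
#' Assigns every gene a unique integer pair (its "token") and a fixed slot
#' in a zero-padded vocabulary vector of length `pad_dim`. Gene identifiers
#' are canonicalised by sorting, so the map is invariant to the input order:
#' the gene at sorted rank `i` (0-based) receives the pair
#' `(i %/% K, i %% K)` with `K = ceiling(sqrt(pad_dim))`, and slot `i`.
#'
#' @param gene_ids Character vector of unique gene identifiers.
#' @param pad_dim Vocabulary capacity (default 60660, the full annotation
#'   size the original network was built for; desk-scale analyses can use a
#'   small value).
#' @return A `gene_token_map`: list with `vocabulary` (sorted ids), `tokens`
#'   (N x 2 integer matrix), `slots` (1-based slot index per vocabulary
#'   gene) and `pad_dim`.
#' @export
build_token_map <- function(gene_ids, pad_dim = 60660L) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    abort(paste0("duplicate gene identifiers: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (length(gene_ids) > pad_dim) {
    abort(sprintf("%d genes exceed pad_dim = %d", length(gene_ids), pad_dim))
  }
  if (length(gene_ids) == 0L) abort("empty gene list")
  vocab <- sort(gene_ids)
  K <- ceiling(sqrt(pad_dim))
  i <- seq_along(vocab) - 1L
  tokens <- cbind(i %/% K, i %% K)
  rownames(tokens) <- vocab
  structure(
    list(vocabulary = vocab, tokens = tokens,
         slots = stats::setNames(i + 1L, vocab), pad_dim = as.integer(pad_dim),
         K = as.integer(K)),
    class = "gene_token_map")
}

#' @export
print.gene_token_map <- function(x, ...) {
  cat(sprintf("gene token map: %d genes, pad_dim = %d\n",
              length(x$vocabulary), x$pad_dim))
  invisible(x)
}
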