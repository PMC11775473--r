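#' Rank genes by betweenness centrality
#'
#' Betweenness centrality — the fraction of shortest paths passing through a
#' node — ranks the "key genes" of an interaction network; the most central
#' members of a pathway are the ones stimulated by
#' [inject_stimulation()]. Ties are broken by gene identifier so the
#' ordering is deterministic.
#'
#' @param graph A two-column data frame / tibble edge list (undirected), or
#'   an igraph object.
#' @return A tibble with `gene`, `betweenness`, `rank`.
#' @examples
#' betweenness_rank(tibble::tibble(from = c("a", "b"), to = c("b", "c")))
#' @export
betweenness_rank <- function(graph) {
  g <- as_gene_graph(graph)
  if (igraph::vcount(g) == 0L) abort("empty graph")
  b <- igraph::betweenness(g, directed = FALSE)
  ord <- order(-b, names(b))
  tibble::tibble(gene = names(b)[ord], betweenness = unname(b[ord]),
                 rank = seq_along(ord))
}

as_gene_graph <- function(graph) {
  if (inherits(graph, "igraph")) return(graph)
  if (is.data.frame(graph)) {
    if (ncol(graph) < 2L) abort("edge list needs two columns")
    if (nrow(graph) == 0L) abort("empty graph")
    el <- cbind(as.character(graph[[1]]), as.character(graph[[2]]))
    return(igraph::graph_from_edgelist(el, directed = FALSE))
  }
  abort("`graph` must be an edge list data frame or an igraph object")
}

#' Stimulation configuration
#'
#' Controls the "real data with manually added stimulation" procedure:
#' sample labels are permuted (equalising group variance and destroying any
#' genuine signal), then within each target pathway the top
#' `centrality_fraction` of genes by betweenness centrality are shifted by
#' `effect_size` per-gene standard deviations in the treatment-labelled
#' samples.
#'
#' @param graph Gene-interaction edge list (two-column data frame) or
#'   igraph object.
#' @param target_sets Names of pathways to stimulate.
#' @param effect_size Mean shift in units of each gene's standard deviation.
#' @param centrality_fraction Fraction of a pathway's (eligible) genes to
#'   shift.
#' @param unique_only Restrict candidate genes to those belonging to no
#'   other pathway of the collection (the protocol used for overlapping
#'   real-pathway collections).
#' @param permute_labels Permute sample labels before injecting.
#' @param seed Integer seed.
#' @export
stimulation_config <- function(graph, target_sets, effect_size,
                               centrality_fraction = 0.10,
                               unique_only = TRUE,
                               permute_labels = TRUE, seed = 1L) {
  if (centrality_fraction <= 0 || centrality_fraction > 1) {
    abort("centrality_fraction must be in (0, 1]")
  }
  structure(
    list(graph = graph, target_sets = as.character(target_sets),
         effect_size = effect_size,
         centrality_fraction = centrality_fraction,
         unique_only = isTRUE(unique_only),
         permute_labels = isTRUE(permute_labels), seed = as.integer(seed)),
    class = "stimulation_config")
}

#' Inject a known stimulation into a labelled dataset
#'
#' Implements the real-data ground-truth construction: (i) permute the
#' sample labels with the configured seed, (ii) within each target pathway
#' select the top `centrality_fraction` genes by [betweenness_rank()]
#' (restricted to genes unique to that pathway when `unique_only`), and
#' (iii) add `effect_size` times the gene's standard deviation to those
#' genes in the treatment-labelled samples. The input is never modified;
#' non-target pathways are returned bit-identical.
#'
#' @param data Wide tibble or [labeled_expression()].
#' @param pathways Named list of gene-id vectors.
#' @param config A [stimulation_config()].
#' @param label_col,sample_col Column names used when `data` is a tibble.
#' @return A list with `expression` (wide tibble) and `truth`
#'   (`simulation_truth`).
#' @export
inject_stimulation <- function(data, pathways, config,
                               label_col = "label",
                               sample_col = "sample_id") {
  stopifnot(inherits(config, "stimulation_config"))
  le <- as_labeled_expression(data, label_col, sample_col)
  missing_sets <- setdiff(config$target_sets, names(pathways))
  if (length(missing_sets)) {
    abort(paste0("target pathways not in collection: ",
                 paste(missing_sets, collapse = ", ")))
  }
  rk <- betweenness_rank(config$graph)

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)

  labels <- le$labels
  if (config$permute_labels) labels <- labels[sample.int(length(labels))]

  X <- le$values
  gene_sd <- apply(X, 2, stats::sd)
  treat <- labels == levels(labels)[2]
  de_genes <- list()
  for (s in config$target_sets) {
    cand <- intersect(pathways[[s]], colnames(X))
    if (config$unique_only) {
      others <- unlist(pathways[setdiff(names(pathways), s)],
                       use.names = FALSE)
      cand <- setdiff(cand, others)
    }
    cand <- intersect(cand, rk$gene)
    if (length(cand) == 0L) {
      abort(sprintf("pathway '%s' has no graph-covered candidate genes", s))
    }
    k <- round(config$centrality_fraction * length(cand))
    if (k < 1L) {
      abort(sprintf("centrality_fraction selects zero genes in pathway '%s'", s))
    }
    key <- rk$gene[rk$gene %in% cand][seq_len(k)]
    if (config$effect_size != 0) {
      X[treat, key] <- sweep(X[treat, key, drop = FALSE], 2,
                             config$effect_size * gene_sd[key], "+")
    }
    de_genes[[s]] <- sort(key)
  }

  expression <- dplyr::bind_cols(
    tibble::tibble(sample_id = le$sample_ids,
                   label = as.character(labels)),
    tibble::as_tibble(X))
  truth <- structure(
    list(de_sets = sort(config$target_sets), de_genes = de_genes,
         shift = config$effect_size),
    class = "simulation_truth")
  list(expression = expression, truth = truth)
}

#' Synthetic surrogate for a real RNA-Seq count matrix
#'
#' Generates a skewed, overdispersed count matrix with pathway-correlated
#' latent factors and random (signal-free) labels, for exercising the
#' stimulation pipeline without any external download. This is a synthetic
#' stand-in that mimics only the *shape* of real tumour RNA-Seq data
#' (non-negative counts, gene-level dispersion, within-pathway correlation);
#' it does not reproduce any real cohort.
#'
#' @param n_samples Number of samples.
#' @param pathways Named list of gene-id vectors; the gene universe is their
#'   union.
#' @param seed Integer seed.
#' @return A wide tibble (sample_id, label, gene columns) of counts.
#' @export
surrogate_real_dataset <- function(n_samples, pathways, seed = 1L) {
  if (length(pathways) == 0L) abort("pathway collection is empty")
  genes <- sort(unique(unlist(pathways, use.names = FALSE)))
  first_set <- vapply(genes, function(g) {
    which(vapply(pathways, function(p) g %in% p, logical(1)))[1]
  }, integer(1))

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  base <- stats::rnorm(length(genes), mean = 3, sd = 1.2)   # log-scale mean
  size <- stats::runif(length(genes), 0.5, 2)               # NB dispersion
  load <- stats::runif(length(genes), 0.3, 0.7)             # factor loading
  fac <- matrix(stats::rnorm(n_samples * length(pathways)),
                n_samples, length(pathways))
  logmu <- outer(rep(1, n_samples), base) +
    fac[, first_set, drop = FALSE] *
      matrix(load, n_samples, length(genes), byrow = TRUE)
  counts <- matrix(
    stats::rnbinom(n_samples * length(genes),
                   mu = exp(logmu),
                   size = matrix(size, n_samples, length(genes),
                                 byrow = TRUE)),
    n_samples, length(genes))
  colnames(counts) <- genes
  labels <- sample(rep(c("groupA", "groupB"), length.out = n_samples))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%04d", seq_len(n_samples)),
                   label = labels),
    tibble::as_tibble(counts))
}
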