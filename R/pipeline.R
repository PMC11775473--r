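#' Classifier specification
#'
#' One contract for every classifier the pipeline can score a pathway with:
#' the built-in kinds are `"logistic"` (binomial GLM), `"linear_svm"`
#' (linear-kernel SVM) and `"gpnet"` (the point-cloud network of
#' [fit_gpnet()]); `"plugin"` accepts user `fit(x, y, seed)` /
#' `predict(model, x)` functions. The P-value downstream depends on the
#' classifier only through its held-out confusion matrix.
#'
#' @param kind Classifier kind.
#' @param ... Hyperparameters: `cost` for the SVM; `hidden`, `epochs`,
#'   `batch_size`, `lr`, `mode`, `patience`, `validation_fraction`,
#'   `pad_dim` for the network; `fit` and `predict` for plugins.
#' @param seed Integer seed for any fitting randomness.
#' @export
classifier_spec <- function(kind = c("logistic", "linear_svm", "gpnet",
                                     "plugin"),
                            ..., seed = 1L) {
  kind <- match.arg(kind)
  hp <- list(...)
  if (kind == "plugin" &&
      (!is.function(hp$fit) || !is.function(hp$predict))) {
    abort("plugin classifiers need `fit` and `predict` functions")
  }
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train/test split scheme
#'
#' Stratified k-fold cross-validation (default, k = 5) pools out-of-fold
#' predictions from all folds into one confusion matrix; `"holdout"` uses a
#' single stratified split and scores only the test part. Training-set
#' confusion matrices are never used — they are optimistically biased and
#' would destroy Type-I-error control.
#'
#' @param method `"k_fold_cv"` or `"holdout"`.
#' @param k Number of folds.
#' @param test_fraction Held-out fraction for `"holdout"`.
#' @param stratified Keep class proportions in every fold.
#' @param seed Integer seed for the split.
#' @export
split_scheme <- function(method = c("k_fold_cv", "holdout"), k = 5L,
                         test_fraction = 0.25, stratified = TRUE,
                         seed = 1L) {
  method <- match.arg(method)
  if (method == "k_fold_cv" && k < 2L) abort("k must be >= 2")
  if (method == "holdout" &&
      (test_fraction <= 0 || test_fraction >= 1)) {
    abort("test_fraction must be in (0, 1)")
  }
  structure(list(method = method, k = as.integer(k),
                 test_fraction = test_fraction,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_scheme")
}

#' Fit a shallow baseline classifier
#'
#' Logistic regression or a linear-kernel SVM on per-gene standardized
#' features; the standardization statistics are estimated on the training
#' data and frozen into the fit, so applying the model to held-out samples
#' never leaks test-set information. Constant (zero-variance) features are
#' dropped with a warning.
#'
#' @param x Numeric training matrix (samples x genes).
#' @param y Two-level factor (or coercible) of training labels.
#' @param kind `"logistic"` or `"linear_svm"`.
#' @param cost SVM cost parameter.
#' @param seed Integer seed.
#' @return A `pea_baseline` supporting [predict()] (returns labels in the
#'   levels of `y`).
#' @export
fit_baseline <- function(x, y, kind = c("logistic", "linear_svm"),
                         cost = 1, seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2L) abort("`y` must have exactly two classes")
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  keep <- sd > 0
  if (!all(keep)) {
    warn(sprintf("dropping %d constant feature(s)", sum(!keep)))
    if (!any(keep)) abort("all features are constant")
  }
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  model <- if (kind == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, xs), y == levels(y)[2],
                     family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    list(beta = beta)
  } else {
    e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
  }
  structure(list(kind = kind, model = model, mu = mu, sd = sd, keep = keep,
                 classes = levels(y)),
            class = "pea_baseline")
}

#' @export
predict.pea_baseline <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  xs <- sweep(sweep(x[, object$keep, drop = FALSE], 2,
                    object$mu[object$keep]), 2,
              object$sd[object$keep], "/")
  if (object$kind == "logistic") {
    eta <- as.vector(cbind(1, xs) %*% object$model$beta)
    factor(object$classes[(eta > 0) + 1L], levels = object$classes)
  } else {
    factor(as.character(predict(object$model, xs)), levels = object$classes)
  }
}

# classifier contract: fit(X, y_factor, seed) -> model; predict(model, X) -> factor
make_classifier <- function(spec) {
  hp <- spec$hyperparameters
  switch(spec$kind,
    logistic = list(
      fit = function(X, y, seed) fit_baseline(X, y, "logistic", seed = seed),
      predict = function(m, X) predict(m, X)),
    linear_svm = list(
      fit = function(X, y, seed) {
        fit_baseline(X, y, "linear_svm", cost = hp$cost %||% 1, seed = seed)
      },
      predict = function(m, X) predict(m, X)),
    gpnet = list(
      fit = function(X, y, seed) {
        le <- labeled_expression(X, y, class1 = levels(y)[1])
        fit_gpnet(le,
                  mode = hp$mode %||% "from_scratch",
                  hidden = hp$hidden %||% 32L,
                  epochs = hp$epochs %||% 20L,
                  batch_size = hp$batch_size %||% 64L,
                  lr = hp$lr %||% 1e-2,
                  validation_fraction = hp$validation_fraction %||% 0.2,
                  patience = hp$patience %||% 5L,
                  pad_dim = max(ncol(X), hp$pad_dim %||% 0L),
                  seed = seed)
      },
      predict = function(m, X) predict(m, X, type = "class")),
    plugin = list(
      fit = function(X, y, seed) hp$fit(X, y, seed),
      predict = function(m, X) hp$predict(m, X)))
}

assign_folds <- function(y, k, stratified, seed) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(y))
  if (stratified) {
    for (lev in levels(y)) {
      ci <- which(y == lev)
      if (length(ci) < k) {
        abort(sprintf(
          "stratification error: class '%s' has %d samples for %d folds",
          lev, length(ci), k))
      }
      fold[ci[sample.int(length(ci))]] <- rep_len(seq_len(k), length(ci))
    }
  } else {
    fold <- rep_len(seq_len(k), length(y))[sample.int(length(y))]
  }
  fold
}

#' Score one pathway by held-out classification
#'
#' Restricts the expression matrix to the pathway's genes, obtains held-out
#' predictions under the split scheme (out-of-fold predictions pooled over
#' all folds under cross-validation; predictions are never made on training
#' samples), pools them into one 2x2 confusion matrix, and converts it to
#' the combined binomial P-value of [combined_pvalue()].
#'
#' @param data Wide tibble or [labeled_expression()].
#' @param gene_set Character vector of gene ids; genes absent from `data`
#'   are dropped with a warning, and fewer than 2 surviving genes is an
#'   error.
#' @param spec A [classifier_spec()].
#' @param split A [split_scheme()].
#' @param set_name Optional pathway name recorded in the result.
#' @param label_col,sample_col,class1 Passed to [as_labeled_expression()].
#' @return A `pathway_result`; [tidy()] gives a one-row tibble.
#' @examples
#' d <- simulate_dataset(simulation_config(n_genes = 40, n_sets = 2,
#'   genes_per_set = 20, n_de_sets = 1, snr = 2, n_per_group = 25, seed = 3))
#' r <- evaluate_pathway(d$expression, d$gene_sets[[1]],
#'                       classifier_spec("logistic"), split_scheme(seed = 3))
#' tidy(r)
#' @export
evaluate_pathway <- function(data, gene_set,
                             spec = classifier_spec("logistic"),
                             split = split_scheme(),
                             set_name = NULL,
                             label_col = "label", sample_col = "sample_id",
                             class1 = NULL) {
  le <- as_labeled_expression(data, label_col, sample_col, class1)
  gene_set <- unique(as.character(gene_set))
  present <- intersect(gene_set, colnames(le$values))
  dropped <- setdiff(gene_set, present)
  if (length(dropped)) {
    warn(sprintf("dropping %d gene(s) absent from the data (e.g. %s)",
                 length(dropped), paste(head(dropped, 3), collapse = ", ")))
  }
  if (length(present) < 2L) {
    abort("fewer than 2 genes of the set are present in the data")
  }
  if (nlevels(le$labels) < 2L || any(table(le$labels) == 0L)) {
    abort("both classes must be present")
  }
  X <- le$values[, present, drop = FALSE]
  y <- le$labels
  clf <- make_classifier(spec)

  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  if (split$method == "k_fold_cv") {
    fold <- assign_folds(y, split$k, split$stratified, split$seed)
    for (f in seq_len(split$k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) {
        abort("stratification error: a training fold lost a class")
      }
      m <- clf$fit(X[tr, , drop = FALSE], y[tr], spec$seed + f)
      pred[!tr] <- clf$predict(m, X[!tr, , drop = FALSE])
    }
    scored <- rep(TRUE, length(y))
  } else {
    fold <- assign_folds(y, max(2L, round(1 / split$test_fraction)),
                         split$stratified, split$seed)
    test <- fold == 1L
    m <- clf$fit(X[!test, , drop = FALSE], y[!test], spec$seed + 1L)
    pred[test] <- clf$predict(m, X[test, , drop = FALSE])
    scored <- test
  }

  yt <- as.integer(y[scored]); yp <- as.integer(pred[scored])
  cm <- confusion_matrix(sum(yt == 1 & yp == 1), sum(yt == 1 & yp == 2),
                         sum(yt == 2 & yp == 1), sum(yt == 2 & yp == 2))
  structure(
    list(pathway = set_name %||% NA_character_,
         n_genes = ncol(X), n_dropped = length(dropped),
         confusion = cm, pvalue = combined_pvalue(cm),
         classifier = spec$kind, split = split$method,
         classes = levels(y)),
    class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  cat(sprintf("pathway %s: %s classifier, %d genes, combined P = %.4g (accuracy %.3f)\n",
              x$pathway %||% "<unnamed>", x$classifier, x$n_genes,
              x$pvalue$pvalue_combined, x$pvalue$accuracy))
  invisible(x)
}

#' @export
tidy.pathway_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(pathway = x$pathway, classifier = x$classifier,
                   n_genes = x$n_genes),
    tidy(x$pvalue))
}

# order-independent per-pathway seed: 31-ary polynomial hash of the name
# folded with the master seed, reduced mod 2^31 - 1 (doubles stay exact)
seed_for <- function(master, name) {
  h <- 0
  for (code in utf8ToInt(as.character(name))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((h + as.numeric(master)) %% 2147483647)
}

#' Run pathway enrichment over a gene-set collection
#'
#' Applies [evaluate_pathway()] to every set of the collection with one
#' classifier and split scheme. Each pathway receives its own seeds, derived
#' from `seed` and the pathway name (order-independent), so adding or
#' reordering pathways never changes another pathway's result. Per-pathway
#' failures are recorded in the `error` column rather than aborting the
#' batch. P-values are reported raw; `adjust = TRUE` appends a
#' Benjamini-Hochberg column.
#'
#' @param data Wide tibble or [labeled_expression()].
#' @param collection Named list of gene-id vectors.
#' @param spec A [classifier_spec()].
#' @param split A [split_scheme()].
#' @param seed Master seed for per-pathway seed derivation.
#' @param adjust Append a BH-adjusted column.
#' @inheritParams evaluate_pathway
#' @return A `pea_results` tibble, one row per pathway.
#' @export
run_pea <- function(data, collection,
                    spec = classifier_spec("logistic"),
                    split = split_scheme(), seed = 1L, adjust = FALSE,
                    label_col = "label", sample_col = "sample_id",
                    class1 = NULL) {
  if (length(collection) == 0L) abort("gene-set collection is empty")
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    abort("collection must have unique names")
  }
  le <- as_labeled_expression(data, label_col, sample_col, class1)
  rows <- purrr::map(names(collection), function(nm) {
    s <- seed_for(seed, nm)
    spec_i <- spec; spec_i$seed <- s
    split_i <- split; split_i$seed <- s + 1L
    tryCatch({
      r <- evaluate_pathway(le, collection[[nm]], spec_i, split_i,
                            set_name = nm)
      dplyr::mutate(tidy(r), error = NA_character_)
    }, error = function(e) {
      tibble::tibble(pathway = nm, classifier = spec$kind,
                     n_genes = NA_integer_, a11 = NA_integer_,
                     a12 = NA_integer_, a21 = NA_integer_,
                     a22 = NA_integer_, p1 = NA_real_, p2 = NA_real_,
                     pvalue1 = NA_real_, pvalue2 = NA_real_,
                     pvalue_combined = NA_real_, accuracy = NA_real_,
                     error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(rows)
  if (adjust) {
    out$p_adjusted <- stats::p.adjust(out$pvalue_combined, method = "BH")
  }
  class(out) <- c("pea_results", class(out))
  out
}
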