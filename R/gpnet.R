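#' @section Architecture:
#' The network treats a sample's gene set as an unordered point cloud: each
#' gene contributes a 4-channel point built from its z-scored expression and
#' a learned 3-channel linear embedding of its integer token pair. A residual
#' pointwise (per-gene) two-layer convolution backbone refines the points, a
#' pointwise pooling convolution collapses each point to a scalar, the scalars
#' are scattered into a fixed zero-padded vocabulary vector at each gene's
#' slot, and a masked linear layer plus ReLU and a linear head produce two
#' class logits. Because every layer before the scatter is per-gene and the
#' scatter is slot-addressed, the logits are exactly invariant to the order
#' in which genes are presented.
#' @name gpnet-architecture
NULL

relu <- function(x) x * (x > 0)

row_zscore <- function(X) {
  mu <- rowMeans(X)
  sd <- sqrt(rowSums((X - mu)^2) / max(1L, ncol(X) - 1L))
  sd[sd == 0] <- Inf  # constant sample -> z-scores defined as 0
  (X - mu) / sd
}

add_row <- function(M, v) M + matrix(v, nrow(M), length(v), byrow = TRUE)

#' Initialise network parameters
#'
#' He (Kaiming) initialisation for weight matrices (fan-in of the masked
#' linear layer taken as the number of active, unmasked inputs); biases start
#' at zero except when reinitialised for bias-only training.
#'
#' @param token_map A [build_token_map()] result for the analysed gene set.
#' @param hidden Hidden width of the masked linear layer.
#' @param mask Optional binary `hidden x N` mask; default all-ones over the
#'   analysed set (slots outside the set are implicitly masked by the
#'   zero-padding itself).
#' @param seed Integer seed.
#' @return A `gpnet_params` list.
#' @export
gpnet_init <- function(token_map, hidden = 64L, mask = NULL, seed = 1L) {
  N <- length(token_map$vocabulary)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  if (is.null(mask)) mask <- matrix(1, hidden, N)
  stopifnot(nrow(mask) == hidden, ncol(mask) == N)
  fan_mlp <- max(1, mean(rowSums(mask != 0)))
  structure(
    list(
      We = he(2, 3, 2), be = numeric(3),
      W1 = he(4, 4, 4), b1 = numeric(4),
      W2 = he(4, 4, 4), b2 = numeric(4),
      wp = he(4, 1, 4), bp = 0,
      Wm = he(hidden, N, fan_mlp), Mm = (mask != 0) * 1,
      B = numeric(hidden),
      Wh = he(hidden, 2, hidden), bh = numeric(2),
      hidden = as.integer(hidden),
      token_map = token_map,
      tok_scaled = token_map$tokens / token_map$K),
    class = "gpnet_params")
}

trainable_names <- function(mode) {
  if (mode == "bias_only") "B"
  else c("We", "be", "W1", "b1", "W2", "b2", "wp", "bp", "Wm", "B", "Wh", "bh")
}

#' Embed one sample as a gene point cloud
#'
#' Returns the N x 4 point matrix: column 1 the sample's z-scored counts
#' (defined as 0 for a constant sample), columns 2-4 the linear embedding of
#' each gene's token pair.
#'
#' @param sample Numeric expression vector, ordered as
#'   `token_map$vocabulary`.
#' @param token_map A [build_token_map()] result.
#' @param params A `gpnet_params` object.
#' @export
embed_points <- function(sample, token_map, params) {
  N <- length(token_map$vocabulary)
  if (length(sample) != N) abort("sample length must match the vocabulary")
  z <- row_zscore(matrix(sample, 1L))
  G <- add_row(params$tok_scaled %*% params$We, params$be)
  unname(cbind(as.vector(z), G))
}

#' Residual pointwise backbone
#'
#' `f = h + Conv2(ReLU(Conv1(h)))` with both convolutions pointwise 4 -> 4
#' maps, so each gene's output row depends only on its own input row and the
#' zero-weight limit is the identity map.
#'
#' @param h N x 4 point features.
#' @param params A `gpnet_params` object.
#' @export
backbone_features <- function(h, params) {
  a1 <- add_row(h %*% params$W1, params$b1)
  h + add_row(relu(a1) %*% params$W2, params$b2)
}

#' Pool, zero-pad and classify
#'
#' The pooling convolution collapses each gene's 4 channels to one scalar;
#' the scalars are scattered into a zero-padded `pad_dim` vector at each
#' gene's slot; the masked linear layer `(W * M) S + B`, a ReLU and a linear
#' head yield the two class logits. Genes absent from the input contribute
#' exactly zero, so two samples that agree on the analysed set agree on the
#' logits.
#'
#' @param f N x 4 backbone features.
#' @param token_map A [build_token_map()] result.
#' @param params A `gpnet_params` object.
#' @return Length-2 logit vector.
#' @export
pool_pad_classify <- function(f, token_map, params) {
  if (anyDuplicated(token_map$slots)) abort("slot collision in token map")
  s <- as.vector(f %*% params$wp + params$bp)
  z <- as.vector((params$Wm * params$Mm) %*% s) + params$B
  as.vector(relu(z) %*% params$Wh) + params$bh
}

# Batched forward pass. X: n x N matrix in vocabulary order.
gpnet_forward <- function(params, X, keep_cache = FALSE) {
  n <- nrow(X); N <- ncol(X)
  Z <- row_zscore(X)
  G <- add_row(params$tok_scaled %*% params$We, params$be)        # N x 3
  H <- cbind(as.vector(Z), G[rep(seq_len(N), each = n), , drop = FALSE])
  A1 <- add_row(H %*% params$W1, params$b1)
  R1 <- relu(A1)
  A2 <- add_row(R1 %*% params$W2, params$b2)
  Fm <- H + A2
  s <- as.vector(Fm %*% params$wp) + params$bp                    # nN
  S <- matrix(s, n, N)
  WmM <- params$Wm * params$Mm                                    # hidden x N
  Zb <- add_row(S %*% t(WmM), params$B)
  Am <- relu(Zb)
  O <- add_row(Am %*% params$Wh, params$bh)                       # n x 2
  out <- list(O = O)
  if (keep_cache) {
    out <- c(out, list(H = H, A1 = A1, R1 = R1, Fm = Fm, S = S,
                       Zb = Zb, Am = Am, WmM = WmM, n = n, N = N))
  }
  out
}

softmax_rows <- function(O) {
  m <- apply(O, 1, max)
  e <- exp(O - m)
  e / rowSums(e)
}

# Mean cross-entropy and parameter gradients for a batch.
# y: integer class in {1, 2}.
gpnet_loss_grad <- function(params, X, y) {
  fw <- gpnet_forward(params, X, keep_cache = TRUE)
  n <- fw$n; N <- fw$N
  P <- softmax_rows(fw$O)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dO <- P
  dO[idx] <- dO[idx] - 1
  dO <- dO / n                                                    # n x 2
  g <- list()
  g$Wh <- t(fw$Am) %*% dO
  g$bh <- colSums(dO)
  dAm <- dO %*% t(params$Wh)
  dZb <- dAm * (fw$Zb > 0)
  g$B <- colSums(dZb)
  g$Wm <- (t(dZb) %*% fw$S) * params$Mm
  dS <- dZb %*% fw$WmM                                            # n x N
  ds <- as.vector(dS)                                             # nN
  g$wp <- t(fw$Fm) %*% ds
  g$bp <- sum(ds)
  dF <- tcrossprod(ds, as.vector(params$wp))                      # nN x 4
  dA2 <- dF
  g$W2 <- t(fw$R1) %*% dA2
  g$b2 <- colSums(dA2)
  dR1 <- dA2 %*% t(params$W2)
  dA1 <- dR1 * (fw$A1 > 0)
  g$W1 <- t(fw$H) %*% dA1
  g$b1 <- colSums(dA1)
  dH <- dF + dA1 %*% t(params$W1)
  dG <- rowsum(dH[, 2:4, drop = FALSE], rep(seq_len(N), each = n))
  g$We <- t(params$tok_scaled) %*% dG
  g$be <- colSums(dG)
  list(loss = loss, grads = g)
}

adam_state <- function(params, names) {
  st <- lapply(names, function(nm) {
    list(m = params[[nm]] * 0, v = params[[nm]] * 0)
  })
  stats::setNames(st, names)
}

adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(state)) {
    gmat <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * gmat
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * gmat^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Fit the point-cloud gene-set classifier
#'
#' Trains the network on the expression of one gene set. In `from_scratch`
#' mode every parameter is trained; in `bias_only` mode the masked-layer bias
#' is He-reinitialised and is the only tensor updated, all other parameters
#' staying bit-identical to their initial values — the cheap adaptation mode
#' intended for reusing a pretrained backbone across pathways.
#'
#' Optimisation is minibatch Adam on the softmax cross-entropy, with an
#' internal stratified validation split for early stopping. All randomness
#' (initialisation, splits, shuffling) derives from `seed`.
#'
#' @param data A wide tibble (sample id, label, gene columns) or a
#'   [labeled_expression()].
#' @param gene_set Character vector of gene ids to analyse; default all
#'   genes in `data`.
#' @param mode `"from_scratch"` or `"bias_only"`.
#' @param hidden Hidden width of the masked linear layer.
#' @param epochs,batch_size,lr Optimiser settings.
#' @param validation_fraction Fraction held out (stratified) for early
#'   stopping; 0 disables early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param pad_dim Vocabulary capacity of the zero-padded layer.
#' @param normalize `"per_sample"` (z-score each sample across its genes,
#'   the default) or `"per_gene"` (z-score each gene using statistics that
#'   are then frozen into the fit).
#' @param init Optional `gpnet_params` to start from (e.g. a pretrained
#'   checkpoint) — required to make `bias_only` meaningful across calls.
#' @param seed Integer seed.
#' @param label_col,sample_col,class1 Passed to [as_labeled_expression()].
#' @return A `gpnet_fit` with elements `params`, `log` (tibble of per-epoch
#'   losses), `classes`, `config`. Supports [predict()], [tidy()] and
#'   [glance()].
#' @examples
#' d <- simulate_dataset(simulation_config(n_genes = 40, n_sets = 2,
#'   genes_per_set = 20, n_de_sets = 1, snr = 4, n_per_group = 30, seed = 1))
#' fit <- fit_gpnet(d$expression, gene_set = d$gene_sets[[1]],
#'                  epochs = 5, seed = 1)
#' glance(fit)
#' @export
fit_gpnet <- function(data, gene_set = NULL,
                      mode = c("from_scratch", "bias_only"),
                      hidden = 64L, epochs = 50L, batch_size = 32L,
                      lr = 1e-3, validation_fraction = 0.2, patience = 5L,
                      pad_dim = 60660L,
                      normalize = c("per_sample", "per_gene"),
                      init = NULL, seed = 1L,
                      label_col = "label", sample_col = "sample_id",
                      class1 = NULL) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  le <- as_labeled_expression(data, label_col, sample_col, class1)
  if (nlevels(le$labels) < 2L || any(table(le$labels) == 0L)) {
    abort("training data must contain both classes")
  }
  if (is.null(gene_set)) gene_set <- colnames(le$values)
  gene_set <- unique(as.character(gene_set))
  present <- intersect(gene_set, colnames(le$values))
  if (length(present) == 0L) abort("empty gene set after matching to data")
  token_map <- build_token_map(present, pad_dim = pad_dim)
  X <- le$values[, token_map$vocabulary, drop = FALSE]
  y <- as.integer(le$labels)
  gene_stats <- NULL
  if (normalize == "per_gene") {
    mu <- colMeans(X); sd <- apply(X, 2, stats::sd); sd[sd == 0] <- 1
    gene_stats <- list(mu = mu, sd = sd)
    X <- sweep(sweep(X, 2, mu), 2, sd, "/")
  }

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  params <- init %||% gpnet_init(token_map, hidden = hidden,
                                 seed = seed + 1L)
  if (!identical(params$token_map$vocabulary, token_map$vocabulary)) {
    abort("`init` parameters were built for a different vocabulary")
  }
  frozen <- NULL
  if (mode == "bias_only") {
    fan <- max(1, mean(rowSums(params$Mm != 0)))
    params$B <- stats::rnorm(params$hidden, sd = sqrt(2 / fan))
    frozen <- params[setdiff(trainable_names("from_scratch"), "B")]
  }

  # stratified validation split
  n <- nrow(X)
  val_idx <- integer(0)
  if (validation_fraction > 0 && n >= 10L) {
    for (cls in 1:2) {
      ci <- which(y == cls)
      k <- max(1L, round(validation_fraction * length(ci)))
      val_idx <- c(val_idx, ci[sample.int(length(ci), k)])
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[tr_idx])) < 2L) abort("training split lost a class")

  upd <- trainable_names(mode)
  state <- adam_state(params, upd)
  t <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  log <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0
    for (b in batches) {
      lg <- gpnet_loss_grad(params, X[b, , drop = FALSE], y[b])
      t <- t + 1L
      stp <- adam_step(params, lg$grads[upd], state, t, lr)
      params <- stp$params; state <- stp$state
      ep_loss <- ep_loss + lg$loss * length(b)
    }
    ep_loss <- ep_loss / length(ord)
    val_loss <- NA_real_
    if (length(val_idx)) {
      fwv <- gpnet_forward(params, X[val_idx, , drop = FALSE])
      Pv <- softmax_rows(fwv$O)
      val_loss <- -mean(log(pmax(Pv[cbind(seq_along(val_idx), y[val_idx])],
                                 1e-12)))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    log[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss,
                                val_loss = val_loss)
    if (length(val_idx) && wait >= patience) break
  }
  if (length(val_idx) && is.finite(best$loss)) params <- best$params
  if (!is.null(frozen)) params[names(frozen)] <- frozen  # belt and braces

  structure(
    list(params = params, token_map = token_map,
         classes = levels(le$labels), mode = mode,
         normalize = normalize, gene_stats = gene_stats,
         log = dplyr::bind_rows(log[!vapply(log, is.null, logical(1))]),
         config = list(hidden = params$hidden, epochs = epochs,
                       batch_size = batch_size, lr = lr,
                       validation_fraction = validation_fraction,
                       patience = patience, pad_dim = pad_dim,
                       seed = seed)),
    class = "gpnet_fit")
}

#' Predict classes with a fitted point-cloud classifier
#'
#' @param object A `gpnet_fit`.
#' @param newdata Wide tibble or [labeled_expression()] (labels optional) or
#'   a numeric samples x genes matrix with gene column names. Columns are
#'   matched to the fit's vocabulary by name, so gene order is irrelevant;
#'   genes missing from the vocabulary are an error.
#' @param type `"class"`, `"prob"` or `"logit"`.
#' @param ... Unused.
#' @export
predict.gpnet_fit <- function(object, newdata,
                              type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  X <- extract_matrix(newdata)
  vocab <- object$token_map$vocabulary
  missing <- setdiff(vocab, colnames(X))
  if (length(missing)) {
    abort(paste0("genes missing from newdata: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  X <- X[, vocab, drop = FALSE]
  if (!is.null(object$gene_stats)) {
    X <- sweep(sweep(X, 2, object$gene_stats$mu), 2, object$gene_stats$sd, "/")
  }
  O <- gpnet_forward(object$params, X)$O
  switch(type,
    logit = O,
    prob = softmax_rows(O),
    class = factor(object$classes[max.col(O, ties.method = "first")],
                   levels = object$classes))
}

extract_matrix <- function(newdata) {
  if (inherits(newdata, "labeled_expression")) return(newdata$values)
  if (is.matrix(newdata)) {
    if (is.null(colnames(newdata))) abort("matrix must have gene column names")
    return(newdata)
  }
  if (is.data.frame(newdata)) {
    gene_cols <- names(newdata)[vapply(newdata, is.numeric, logical(1))]
    gene_cols <- setdiff(gene_cols, c("label"))
    return(as.matrix(newdata[gene_cols]))
  }
  abort("unsupported newdata type")
}

#' @export
tidy.gpnet_fit <- function(x, ...) x$log

#' @export
glance.gpnet_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_genes = length(x$token_map$vocabulary),
    hidden = x$params$hidden,
    epochs_run = nrow(x$log),
    final_train_loss = x$log$train_loss[nrow(x$log)],
    best_val_loss = suppressWarnings(min(x$log$val_loss, na.rm = TRUE)))
}

#' @export
print.gpnet_fit <- function(x, ...) {
  cat(sprintf("point-cloud gene-set classifier (%s): %d genes, hidden %d, %d epochs\n",
              x$mode, length(x$token_map$vocabulary), x$params$hidden,
              nrow(x$log)))
  invisible(x)
}

#' Save / load a fitted classifier checkpoint
#'
#' Single-file serialized parameter container, embedding the token map,
#' class labels and training configuration, with a format version tag.
#'
#' @param fit A `gpnet_fit`.
#' @param path File path.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "gpnet_fit"))
  saveRDS(list(format = "peaclass-gpnet", version = 1L, fit = fit), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "peaclass-gpnet")) {
    abort("not a classifier checkpoint file")
  }
  obj$fit
}
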