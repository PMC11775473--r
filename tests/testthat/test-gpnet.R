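test_that("token map is deterministic, order-invariant and capacity-checked", {
  m1 <- build_token_map(c("tp53", "brca1", "egfr"), pad_dim = 100)
  m2 <- build_token_map(c("egfr", "tp53", "brca1"), pad_dim = 100)
  expect_identical(m1, m2)
  expect_identical(m1$vocabulary, sort(c("tp53", "brca1", "egfr")))
  expect_identical(nrow(unique(m1$tokens)), 3L)

  big <- build_token_map(paste0("g", 1:5))
  expect_identical(big$pad_dim, 60660L)
  expect_error(build_token_map(paste0("g", 1:11), pad_dim = 10), "exceed")
  expect_error(build_token_map(c("a", "a", "b")), "duplicate")
})

test_that("point embedding has the contracted shape and z-score semantics", {
  tm <- build_token_map(paste0("g", 1:7), pad_dim = 50)
  p <- gpnet_init(tm, hidden = 4, seed = 1)
  h <- embed_points(rnorm(7), tm, p)
  expect_identical(dim(h), c(7L, 4L))

  # constant sample: z-scores defined as 0, not NaN
  hc <- embed_points(rep(2.5, 7), tm, p)
  expect_identical(hc[, 1], rep(0, 7))
  expect_false(anyNA(hc))
})

test_that("backbone is residual and pointwise", {
  tm <- build_token_map(paste0("g", 1:6), pad_dim = 30)
  p <- gpnet_init(tm, hidden = 4, seed = 2)
  h <- matrix(rnorm(24), 6, 4)

  # zero backbone weights: exact identity
  p0 <- p
  p0$W1[] <- 0; p0$b1[] <- 0; p0$W2[] <- 0; p0$b2[] <- 0
  expect_identical(backbone_features(h, p0), h)

  # duplicated point rows give duplicated feature rows
  h2 <- h[c(1, 1, 2:6), ]
  f2 <- backbone_features(h2, p)
  expect_identical(f2[1, ], f2[2, ])
  expect_true(all(is.finite(backbone_features(h, p))))
})

test_that("pooling/padding baseline and mask invariance hold exactly", {
  tm <- build_token_map(paste0("g", 1:5), pad_dim = 40)
  mask <- matrix(1, 3, 5); mask[2, 4] <- 0
  p <- gpnet_init(tm, hidden = 3, mask = mask, seed = 3)

  # all-zero pooled vector: logits reduce to the head on ReLU(B)
  p$B <- rnorm(3)
  fzero <- matrix(0, 5, 4)
  pz <- p; pz$wp[] <- 0; pz$bp <- 0
  expect_equal(pool_pad_classify(fzero, tm, pz),
               as.vector(pmax(p$B, 0) %*% p$Wh) + p$bh)

  # perturbing a masked-out weight leaves the logits unchanged
  f <- matrix(rnorm(20), 5, 4)
  o1 <- pool_pad_classify(f, tm, p)
  p2 <- p; p2$Wm[2, 4] <- p2$Wm[2, 4] + 100
  expect_identical(pool_pad_classify(f, tm, p2), o1)
})

test_that("analytic gradients match finite differences", {
  tm <- build_token_map(paste0("g", 1:6), pad_dim = 20)
  p <- gpnet_init(tm, hidden = 5, seed = 2)
  set.seed(3)
  X <- matrix(rnorm(4 * 6), 4, 6)
  y <- c(1L, 2L, 1L, 2L)
  lg <- peaclass:::gpnet_loss_grad(p, X, y)
  eps <- 1e-6
  for (nm in c("We", "W1", "W2", "wp", "Wm", "B", "Wh", "bh")) {
    v <- p[[nm]]
    for (i in seq_len(min(4, length(v)))) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (peaclass:::gpnet_loss_grad(pp, X, y)$loss -
                peaclass:::gpnet_loss_grad(pm, X, y)$loss) / (2 * eps)
      expect_lt(abs(num - lg$grads[[nm]][i]), 1e-6)
    }
  }
})

test_that("predictions are exactly invariant to gene-column permutation", {
  d <- tiny_sim(snr = 2, n_per_group = 20, seed = 5)
  genes <- d$gene_sets[[1]]
  fit <- fit_gpnet(d$expression, genes, epochs = 5, hidden = 8, seed = 2)
  X <- as.matrix(d$expression[, genes])
  perm <- sample(ncol(X))
  expect_identical(predict(fit, X, type = "logit"),
                   predict(fit, X[, perm], type = "logit"))
  # batch prediction equals concatenated per-sample prediction
  one_by_one <- do.call(rbind, lapply(seq_len(5), function(i) {
    predict(fit, X[i, , drop = FALSE], type = "logit")
  }))
  expect_equal(unname(predict(fit, X[1:5, ], type = "logit")),
               unname(one_by_one), tolerance = 1e-12)
})

test_that("bias-only training leaves every non-bias tensor bit-identical", {
  d <- tiny_sim(snr = 1, n_per_group = 25, seed = 6)
  genes <- d$gene_sets[[1]]
  tm <- build_token_map(genes, pad_dim = 100)
  init <- gpnet_init(tm, hidden = 8, seed = 11)
  fit <- fit_gpnet(d$expression, genes, mode = "bias_only", init = init,
                   epochs = 10, hidden = 8, pad_dim = 100, seed = 11,
                   validation_fraction = 0)
  frozen <- setdiff(peaclass:::trainable_names("from_scratch"), "B")
  for (nm in frozen) expect_identical(fit$params[[nm]], init[[nm]])
  expect_false(identical(fit$params$B, init$B))
})

test_that("training is deterministic given the seed", {
  d <- tiny_sim(snr = 1, n_per_group = 20, seed = 7)
  genes <- d$gene_sets[[1]]
  f1 <- fit_gpnet(d$expression, genes, epochs = 6, hidden = 8, seed = 4)
  f2 <- fit_gpnet(d$expression, genes, epochs = 6, hidden = 8, seed = 4)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params$Wm, f2$params$Wm)
})

test_that("the full model separates a strongly shifted synthetic set", {
  # 10% of the set's genes shifted by 5 sigma; held-out accuracy >= 0.95
  d <- tiny_sim(snr = 25, n_per_group = 60, seed = 8)
  de <- d$truth$de_sets
  r <- evaluate_pathway(d$expression, d$gene_sets[[de]],
                        classifier_spec("gpnet"), split_scheme(seed = 1))
  expect_gte(r$pvalue$accuracy, 0.95)
})

test_that("degenerate training inputs are rejected", {
  d <- tiny_sim(seed = 9, n_per_group = 15)
  one_class <- dplyr::filter(d$expression, label == "control")
  expect_error(fit_gpnet(one_class, d$gene_sets[[1]]), "both classes")
  expect_error(fit_gpnet(d$expression, character(0)), "empty gene set")
  expect_error(predict(fit_gpnet(d$expression, d$gene_sets[[1]], epochs = 2),
                       matrix(0, 2, 2,
                              dimnames = list(NULL, c("zz1", "zz2")))),
               "missing")
})

test_that("checkpoints round-trip through a single file", {
  d <- tiny_sim(snr = 1, n_per_group = 15, seed = 10)
  fit <- fit_gpnet(d$expression, d$gene_sets[[1]], epochs = 3, hidden = 8,
                   seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  X <- as.matrix(d$expression[, d$gene_sets[[1]]])
  expect_identical(predict(fit, X, type = "logit"),
                   predict(fit2, X, type = "logit"))
})
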