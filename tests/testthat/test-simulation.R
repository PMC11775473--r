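test_that("configuration invariants are enforced with informative errors", {
  expect_error(simulation_config(n_genes = 100, n_sets = 3,
                                 genes_per_set = 30), "must equal n_genes")
  expect_error(simulation_config(n_genes = 100, n_sets = 2,
                                 genes_per_set = 50, rho_within = 0.1,
                                 rho_between = 0.5), "PSD")
  expect_error(simulation_config(n_genes = 100, n_sets = 2,
                                 genes_per_set = 50, rho_within = 1), "PSD")
  expect_error(simulation_config(n_genes = 100, n_sets = 2,
                                 genes_per_set = 50, n_de_sets = 5),
               "n_de_sets")
  expect_error(simulation_config(n_genes = 100, n_sets = 2,
                                 genes_per_set = 50, snr = -1), "snr")
})

test_that("block covariance has exactly the two off-diagonal levels", {
  cfg <- simulation_config(n_genes = 40, n_sets = 4, genes_per_set = 10,
                           sigma = 2, n_de_sets = 1)
  S <- as.matrix(build_block_covariance(cfg))
  blk <- rep(1:4, each = 10)
  same <- outer(blk, blk, "==")
  off <- !diag(40)
  expect_identical(unique(diag(S)), 4)
  expect_identical(unique(as.vector(S[same & off])), 0.8 * 4)
  expect_identical(unique(as.vector(S[!same])), 0.05 * 4)

  # independence limit: scaled identity
  cfg0 <- simulation_config(n_genes = 20, n_sets = 2, genes_per_set = 10,
                            rho_within = 0, rho_between = 0, sigma = 3,
                            n_de_sets = 1)
  expect_identical(as.matrix(build_block_covariance(cfg0)), diag(9, 20))
})

test_that("SNR inverts to the mean shift", {
  expect_identical(snr_to_shift(0), 0)
  expect_equal(snr_to_shift(0.05), sqrt(0.05), tolerance = 1e-15)
  expect_equal(snr_to_shift(0.05), 0.223607, tolerance = 1e-6)
  expect_identical(snr_to_shift(1, sigma = 2), 2)
  expect_error(snr_to_shift(-0.1), ">= 0")
})

test_that("simulation is bit-reproducible and respects the null", {
  cfg <- simulation_config(n_genes = 60, n_sets = 3, genes_per_set = 20,
                           n_de_sets = 1, snr = 0, n_per_group = 200,
                           seed = 21)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$truth$de_sets, d2$truth$de_sets)

  # snr = 0: every gene's group-mean difference is within 4/sqrt(n) of 0
  X <- as.matrix(d1$expression[, -(1:2)])
  grp <- d1$expression$label
  diff <- colMeans(X[grp == "treatment", ]) - colMeans(X[grp == "control", ])
  expect_lt(max(abs(diff)), 4 / sqrt(200))
})

test_that("empirical moments converge to the configured ones", {
  cfg <- simulation_config(n_genes = 200, n_sets = 4, genes_per_set = 50,
                           n_de_sets = 1, snr = 0.05, n_per_group = 2000,
                           seed = 22)
  d <- simulate_dataset(cfg)
  X <- as.matrix(d$expression[, -(1:2)])
  blk <- rep(1:4, each = 50)
  C <- stats::cor(X)
  within <- C[outer(blk, blk, "==") & row(C) != col(C)]
  expect_lt(abs(mean(within) - 0.8), 0.02)

  sh <- unlist(d$truth$de_genes)
  grp <- d$expression$label
  diff <- colMeans(X[grp == "treatment", sh, drop = FALSE]) -
    colMeans(X[grp == "control", sh, drop = FALSE])
  expect_lt(abs(mean(diff) - sqrt(0.05)), 0.05)
  # truth bookkeeping: 10% of a 50-gene set
  expect_identical(lengths(d$truth$de_genes)[[1]], 5L)
})

test_that("the factor-form sampler reproduces the constructed covariance", {
  cfg <- simulation_config(n_genes = 200, n_sets = 4, genes_per_set = 50,
                           n_de_sets = 1, snr = 0, n_per_group = 25000,
                           seed = 23)
  d <- simulate_dataset(cfg)
  X <- as.matrix(d$expression[, -(1:2)])
  n <- nrow(X)
  emp <- stats::cov(X)
  target <- as.matrix(build_block_covariance(cfg))
  # entrywise MC standard error for Gaussian covariance: sqrt((1+rho^2)/n)
  se <- sqrt((1 + target^2) / n)
  z <- (emp - target) / se
  expect_lt(mean(abs(z) > 3), 0.01)   # ~0.27% expected by chance
  expect_lt(max(abs(z)), 6)
  expect_lt(abs(mean(emp[row(emp) != col(emp) &
                           outer(rep(1:4, each = 50),
                                 rep(1:4, each = 50), "!=")]) - 0.05),
            3 * sqrt(1 / n))
})

test_that("betweenness ranking matches analytic graph cases", {
  path <- tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  rk <- betweenness_rank(path)
  expect_identical(rk$gene[1], "b")

  star <- tibble::tibble(from = rep("hub", 4),
                         to = c("l1", "l2", "l3", "l4"))
  rs <- betweenness_rank(star)
  expect_identical(rs$gene[1], "hub")
  expect_identical(rs$gene[-1], c("l1", "l2", "l3", "l4"))  # id-ordered ties

  cg <- t(combn(c("x", "y", "z"), 2))
  rc <- betweenness_rank(tibble::tibble(from = cg[, 1], to = cg[, 2]))
  expect_identical(unique(rc$betweenness), 0)
  expect_identical(rc$gene, c("x", "y", "z"))
  expect_error(betweenness_rank(tibble::tibble(from = character(),
                                               to = character())),
               "empty")
})

test_that("stimulation injects only into key genes of target pathways", {
  d <- tiny_sim(seed = 31, n_per_group = 40, n_sets = 3, genes_per_set = 20)
  sets <- d$gene_sets
  # chain graph over the first target set's genes: interior genes central
  g1 <- sets[[1]]
  graph <- tibble::tibble(from = g1[-length(g1)], to = g1[-1])
  cfg <- stimulation_config(graph, target_sets = names(sets)[1],
                            effect_size = 2, centrality_fraction = 0.25,
                            seed = 5)
  out <- inject_stimulation(d$expression, sets, cfg)

  # label permutation is a bijection of the original labels
  expect_identical(sort(out$expression$label), sort(d$expression$label))
  # k = round(0.25 * 20) = 5 genes shifted
  expect_identical(lengths(out$truth$de_genes)[[1]], 5L)
  # non-target pathways bit-identical
  untouched <- unlist(sets[-1], use.names = FALSE)
  expect_identical(out$expression[, untouched], d$expression[, untouched])
  # within the target set, non-key genes bit-identical too
  quiet <- setdiff(g1, out$truth$de_genes[[1]])
  expect_identical(out$expression[, quiet], d$expression[, quiet])
  # input untouched (pure function)
  expect_identical(d$expression, tiny_sim(seed = 31, n_per_group = 40,
                                          n_sets = 3,
                                          genes_per_set = 20)$expression)

  # zero effect: output is exactly the label-permuted input
  cfg0 <- stimulation_config(graph, names(sets)[1], effect_size = 0,
                             centrality_fraction = 0.25, seed = 5)
  out0 <- inject_stimulation(d$expression, sets, cfg0)
  expect_identical(out0$expression[, unlist(sets, use.names = FALSE)],
                   d$expression[, unlist(sets, use.names = FALSE)])

  # errors: no graph coverage, zero-gene selection
  badg <- tibble::tibble(from = "nogene1", to = "nogene2")
  expect_error(inject_stimulation(
    d$expression, sets,
    stimulation_config(badg, names(sets)[1], 1)), "no graph-covered")
  expect_error(inject_stimulation(
    d$expression, sets,
    stimulation_config(graph, names(sets)[1], 1,
                       centrality_fraction = 0.01)), "zero genes")
})

test_that("the surrogate real-like dataset is signal-free count data", {
  sets <- list(pw1 = paste0("g", 1:15), pw2 = paste0("g", 16:30))
  s1 <- surrogate_real_dataset(40, sets, seed = 2)
  s2 <- surrogate_real_dataset(40, sets, seed = 2)
  expect_identical(s1, s2)
  counts <- as.matrix(s1[, -(1:2)])
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  expect_setequal(colnames(counts), paste0("g", 1:30))
  expect_identical(sort(unique(s1$label)), c("groupA", "groupB"))
})
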