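# shared fixtures: everything is generated in code at test time

# explicit binomial lower-tail sum, independent of pbinom's implementation path
binom_tail_oracle <- function(k, n, p) {
  j <- 0:k
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# small simulated dataset used across pipeline tests
tiny_sim <- function(snr = 0, n_per_group = 30L, seed = 1L,
                     n_sets = 3L, genes_per_set = 20L, n_de_sets = 1L) {
  simulate_dataset(simulation_config(
    n_genes = n_sets * genes_per_set, n_sets = n_sets,
    genes_per_set = genes_per_set, n_de_sets = n_de_sets,
    snr = snr, n_per_group = n_per_group, seed = seed))
}

# two-gene, strongly separated toy data (class means +/- delta)
toy_separated <- function(n = 40L, delta = 3, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * 2, -delta), n, 2),
             matrix(rnorm(n * 2, delta), n, 2))
  colnames(X) <- c("gA", "gB")
  labeled_expression(X, rep(c("case", "ctrl"), each = n), class1 = "case")
}

# 1-nearest-neighbour plugin classifier: memorises its training set, so any
# train/test leakage shows up as perfect accuracy
knn1_spec <- function(seed = 1L) {
  classifier_spec(
    "plugin",
    fit = function(X, y, seed) list(X = X, y = y),
    predict = function(m, X) {
      idx <- apply(X, 1, function(r) {
        which.min(colSums((t(m$X) - r)^2))
      })
      m$y[idx]
    },
    seed = seed)
}

random_confusion <- function(max_n = 30L) {
  n1 <- sample(1:max_n, 1); n2 <- sample(1:max_n, 1)
  a12 <- sample(0:n1, 1); a21 <- sample(0:n2, 1)
  confusion_matrix(n1 - a12, a12, a21, n2 - a21)
}
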