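#' Build a 2x2 confusion matrix object
#'
#' The confusion matrix of a binary classifier is the sufficient statistic of
#' the analytic pathway P-value: `a11` class-1 samples predicted class 1,
#' `a12` class-1 samples predicted class 2 (class-1 errors), `a21` class-2
#' samples predicted class 1 (class-2 errors), `a22` class-2 samples predicted
#' class 2.
#'
#' @param a11,a12,a21,a22 Non-negative integer counts.
#' @return An object of class `pea_confusion` (a named integer vector).
#' @examples
#' confusion_matrix(40, 10, 15, 35)
#' @export
confusion_matrix <- function(a11, a12, a21, a22) {
  counts <- c(a11 = a11, a12 = a12, a21 = a21, a22 = a22)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    rlang::abort("confusion matrix counts must be non-negative integers")
  }
  structure(as.integer(round(counts)), names = names(counts),
            class = "pea_confusion")
}

as_confusion <- function(cm) {
  if (inherits(cm, "pea_confusion")) return(cm)
  if (is.numeric(cm) && length(cm) == 4L) {
    return(confusion_matrix(cm[[1]], cm[[2]], cm[[3]], cm[[4]]))
  }
  rlang::abort("expected a `pea_confusion` or a numeric vector of 4 counts")
}

#' @export
print.pea_confusion <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(true = c("class1", "class2"),
                              predicted = c("class1", "class2")))
  cat("2x2 confusion matrix (true x predicted)\n")
  print(m)
  invisible(x)
}

check_nondegenerate <- function(cm) {
  n1 <- cm[["a11"]] + cm[["a12"]]
  n2 <- cm[["a21"]] + cm[["a22"]]
  if (n1 < 1L) rlang::abort("class 1 empty: n1 = a11 + a12 must be >= 1")
  if (n2 < 1L) rlang::abort("class 2 empty: n2 = a21 + a22 must be >= 1")
  invisible(cm)
}

#' Empirical class priors from a confusion matrix
#'
#' The prior of class 1 is the proportion of samples whose true label is
#' class 1, `p1 = (a11 + a12) / N`; it is the success probability of the
#' random-guesser null model against which the classifier is scored.
#'
#' @param cm A `pea_confusion` object or numeric vector of 4 counts
#'   (a11, a12, a21, a22).
#' @return A named list with elements `p1` and `p2` (`p1 + p2 == 1`).
#' @examples
#' compute_priors(confusion_matrix(9, 1, 60, 30))
#' @export
compute_priors <- function(cm) {
  cm <- check_nondegenerate(as_confusion(cm))
  n1 <- cm[["a11"]] + cm[["a12"]]
  n  <- sum(cm)
  p1 <- n1 / n
  list(p1 = p1, p2 = 1 - p1)
}

#' Per-class binomial tail P-value
#'
#' Models a random classifier that assigns class 1 independently per sample
#' with probability `p1` (the empirical prior). For class 1 the observed
#' error count is `a12` out of `n1 = a11 + a12` trials, each an error with
#' probability `1 - p1`; the P-value is the inclusive lower binomial tail
#' `P[X <= a12]`, i.e. the probability that the random classifier makes no
#' more class-1 errors than the model did.
#'
#' For class 2 the symmetric error-count form uses `k = a21` errors out of
#' `n2` trials with error probability `1 - p2` (the default). Setting
#' `as_printed = TRUE` instead uses `k = a22` (the count of correct class-2
#' predictions) as the tail argument — a literal transcription of the
#' published formula, which is large for accurate classifiers and is kept
#' only for comparability.
#'
#' @param cm A `pea_confusion` or numeric vector of 4 counts.
#' @param class_index 1 or 2.
#' @param as_printed Logical; use the literal published form for class 2.
#' @return A single probability.
#' @examples
#' class_pvalue(confusion_matrix(10, 0, 0, 10), 1)  # 0.5^10
#' @export
class_pvalue <- function(cm, class_index, as_printed = FALSE) {
  cm <- as_confusion(cm)
  pr <- compute_priors(cm)
  if (!class_index %in% c(1L, 2L)) {
    rlang::abort("`class_index` must be 1 or 2")
  }
  if (class_index == 1L) {
    k <- cm[["a12"]]
    n <- cm[["a11"]] + cm[["a12"]]
    p <- 1 - pr$p1
  } else {
    k <- if (as_printed) cm[["a22"]] else cm[["a21"]]
    n <- cm[["a21"]] + cm[["a22"]]
    p <- 1 - pr$p2
  }
  if (k > n) rlang::abort("inconsistent confusion matrix: k > n")
  stats::pbinom(k, n, p)
}

#' Overall classification accuracy
#'
#' @inheritParams compute_priors
#' @return `(a11 + a22) / N`.
#' @export
overall_accuracy <- function(cm) {
  cm <- as_confusion(cm)
  n <- sum(cm)
  if (n < 1L) rlang::abort("all-zero confusion matrix: no samples")
  (cm[["a11"]] + cm[["a22"]]) / n
}

#' Combined confusion-matrix P-value
#'
#' Combines the two per-class binomial tails as
#' `P = 1 - (1 - P1)(1 - P2)`: the probability that a random classifier
#' matches or beats the model on at least one of the two classes. Small only
#' when the classifier beats chance on both classes, which makes the
#' statistic conservative by construction.
#'
#' @inheritParams class_pvalue
#' @return An object of class `pea_pvalue`: a list with `pvalue1`, `pvalue2`,
#'   `pvalue_combined`, `accuracy`, `priors` and the input matrix. Use
#'   [generics::tidy()] for a one-row tibble.
#' @examples
#' combined_pvalue(confusion_matrix(40, 10, 15, 35))
#' @export
combined_pvalue <- function(cm, as_printed = FALSE) {
  cm <- as_confusion(cm)
  p1 <- class_pvalue(cm, 1L)
  p2 <- class_pvalue(cm, 2L, as_printed = as_printed)
  structure(
    list(pvalue1 = p1, pvalue2 = p2,
         pvalue_combined = 1 - (1 - p1) * (1 - p2),
         accuracy = overall_accuracy(cm),
         priors = compute_priors(cm),
         confusion = cm,
         as_printed = as_printed),
    class = "pea_pvalue")
}

#' @export
print.pea_pvalue <- function(x, ...) {
  cat(sprintf(
    "confusion-matrix P-value\n  P1 = %.6g  P2 = %.6g  combined = %.6g\n  accuracy = %.4f  (p1 = %.4f, p2 = %.4f)\n",
    x$pvalue1, x$pvalue2, x$pvalue_combined, x$accuracy,
    x$priors$p1, x$priors$p2))
  invisible(x)
}

#' @export
tidy.pea_pvalue <- function(x, ...) {
  tibble::tibble(
    a11 = x$confusion[["a11"]], a12 = x$confusion[["a12"]],
    a21 = x$confusion[["a21"]], a22 = x$confusion[["a22"]],
    p1 = x$priors$p1, p2 = x$priors$p2,
    pvalue1 = x$pvalue1, pvalue2 = x$pvalue2,
    pvalue_combined = x$pvalue_combined,
    accuracy = x$accuracy)
}

#' Monte-Carlo null P-value (validation oracle)
#'
#' Estimates the per-class P-value by simulation instead of the binomial CDF:
#' each draw assigns every sample of the scored class to class 1 with the
#' empirical prior probability (independent uniform comparisons, not a
#' binomial sampler, so the oracle shares nothing with the analytic path)
#' and counts how often the random classifier's error count is at most the
#' observed one.
#'
#' @inheritParams class_pvalue
#' @param n_draws Number of Monte-Carlo draws (>= 1000).
#' @param seed Integer seed; results are reproducible given it.
#' @return A list with `estimate`, `se` (binomial standard error) and
#'   `n_draws`.
#' @export
mc_null_pvalue <- function(cm, class_index, n_draws = 1e5, seed = 1L) {
  cm <- as_confusion(cm)
  pr <- compute_priors(cm)
  if (n_draws < 1000) rlang::abort("`n_draws` must be >= 1000")
  if (!class_index %in% c(1L, 2L)) rlang::abort("`class_index` must be 1 or 2")
  if (class_index == 1L) {
    k <- cm[["a12"]]; n <- cm[["a11"]] + cm[["a12"]]; p_err <- 1 - pr$p1
  } else {
    k <- cm[["a21"]]; n <- cm[["a21"]] + cm[["a22"]]; p_err <- 1 - pr$p2
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  # errors per draw: each of the n true-class samples misassigned w.p. p_err
  err <- matrix(stats::runif(n_draws * n) < p_err, nrow = n_draws)
  hits <- rowSums(err) <= k
  est <- mean(hits)
  list(estimate = est,
       se = sqrt(est * (1 - est) / n_draws),
       n_draws = n_draws)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
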