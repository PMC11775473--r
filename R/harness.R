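#' Experiment grid for replicated Type-I-error / power studies
#'
#' @param sample_sizes Per-group sample sizes to sweep.
#' @param snrs Signal-to-noise ratios to sweep (0 = null).
#' @param n_replicates Simulation replicates per cell (the full-scale study
#'   uses 100; desk-scale runs use fewer).
#' @param methods Named list of [classifier_spec()]s.
#' @param base_config A [simulation_config()] giving the gene universe and
#'   correlation structure; its `n_per_group`, `snr` and `seed` are
#'   overridden per cell.
#' @param master_seed Master seed; every replicate's seed is derived from it
#'   and the cell coordinates.
#' @export
experiment_grid <- function(sample_sizes, snrs, n_replicates = 30L,
                            methods = list(logistic = classifier_spec("logistic")),
                            base_config = simulation_config(
                              n_genes = 1000L, n_sets = 10L,
                              genes_per_set = 100L, n_de_sets = 2L),
                            master_seed = 1L) {
  if (!length(sample_sizes) || !length(snrs) || !length(methods)) {
    abort("sample_sizes, snrs and methods must be non-empty")
  }
  if (n_replicates < 2L) abort("n_replicates must be >= 2")
  if (is.null(names(methods))) {
    names(methods) <- vapply(methods, function(m) m$kind, character(1))
  }
  structure(
    list(sample_sizes = as.integer(sample_sizes), snrs = snrs,
         n_replicates = as.integer(n_replicates), methods = methods,
         base_config = base_config, master_seed = as.integer(master_seed)),
    class = "experiment_grid")
}

#' Run every replicate of an experiment grid
#'
#' For each (sample size, SNR, method) cell and replicate, draws a fresh
#' simulated dataset with a seed derived from the master seed and the cell
#' coordinates, runs [run_pea()], and records the per-pathway combined
#' P-values together with the ground truth. Per-replicate failures are
#' logged into the `error` column, never fatal. With an `out_dir`, finished
#' cells are written to disk and skipped on re-runs (resumability).
#'
#' @param grid An [experiment_grid()].
#' @param scope `"all"` scores every pathway (Type I and power);
#'   `"de_only"` scores only the truly differential pathways (a cheap
#'   power-only run).
#' @param split A [split_scheme()].
#' @param out_dir Optional directory for per-cell record files.
#' @return A tibble with one row per (cell, replicate, pathway):
#'   `n`, `snr`, `method`, `replicate`, `pathway`, `is_de`,
#'   `pvalue_combined`, `accuracy`, `error`.
#' @export
replicate_experiment <- function(grid, scope = c("all", "de_only"),
                                 split = split_scheme(), out_dir = NULL) {
  stopifnot(inherits(grid, "experiment_grid"))
  scope <- match.arg(scope)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  cells <- tidyr::expand_grid(
    n = grid$sample_sizes, snr = grid$snrs,
    method = names(grid$methods))
  res <- purrr::pmap(cells, function(n, snr, method) {
    cell_id <- sprintf("cell_n%d_snr%s_%s", n, format(snr), method)
    cache <- if (!is.null(out_dir)) file.path(out_dir, paste0(cell_id, ".rds"))
    if (!is.null(cache) && file.exists(cache)) return(readRDS(cache))
    out <- purrr::map(seq_len(grid$n_replicates), function(r) {
      seed <- seed_for(grid$master_seed, paste(cell_id, r))
      cfg <- grid$base_config
      cfg$n_per_group <- as.integer(n)
      cfg$snr <- snr
      cfg$seed <- seed
      tryCatch({
        d <- simulate_dataset(cfg)
        coll <- if (scope == "de_only") {
          d$gene_sets[d$truth$de_sets]
        } else d$gene_sets
        pr <- run_pea(d$expression, coll, grid$methods[[method]],
                      split, seed = seed + 1L)
        tibble::tibble(
          n = n, snr = snr, method = method, replicate = r,
          pathway = pr$pathway,
          is_de = pr$pathway %in% d$truth$de_sets,
          pvalue_combined = pr$pvalue_combined,
          accuracy = pr$accuracy, error = pr$error)
      }, error = function(e) {
        tibble::tibble(n = n, snr = snr, method = method, replicate = r,
                       pathway = NA_character_, is_de = NA,
                       pvalue_combined = NA_real_, accuracy = NA_real_,
                       error = conditionMessage(e))
      })
    })
    out <- dplyr::bind_rows(out)
    if (!is.null(cache)) saveRDS(out, cache)
    out
  })
  dplyr::bind_rows(res)
}

#' Type I error and power at a threshold
#'
#' Type I error is the fraction of (replicate, truly-null pathway) pairs
#' with `P <= threshold`; power is the same fraction over truly differential
#' pathways. By default pathways are pooled across replicates;
#' `per_replicate = TRUE` first averages within each replicate. A side with
#' no pathways yields `NA`, never 0.
#'
#' @param records Tibble from [replicate_experiment()] (needs `is_de` and
#'   `pvalue_combined`; optionally `replicate`).
#' @param threshold Significance threshold.
#' @param by Optional character vector of grouping columns (e.g.
#'   `c("n", "snr", "method")`).
#' @param per_replicate Average within replicates before across them.
#' @return A tibble with `type_i`, `power`, `threshold`, `n_null`, `n_de`
#'   (one row per group).
#' @export
type_i_and_power <- function(records, threshold = 0.05, by = NULL,
                             per_replicate = FALSE) {
  if (nrow(records) == 0L) abort("no records")
  records <- dplyr::filter(records, is.na(.data$error) | .data$error == "")
  summarise_one <- function(d) {
    rate <- function(sub) {
      if (nrow(sub) == 0L) return(NA_real_)
      if (per_replicate) {
        mean(tapply(sub$pvalue_combined <= threshold, sub$replicate, mean))
      } else {
        mean(sub$pvalue_combined <= threshold)
      }
    }
    tibble::tibble(
      type_i = rate(dplyr::filter(d, !.data$is_de)),
      power = rate(dplyr::filter(d, .data$is_de)),
      threshold = threshold,
      n_null = sum(!d$is_de), n_de = sum(d$is_de))
  }
  if (is.null(by)) return(summarise_one(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ summarise_one(.x)) |>
    dplyr::ungroup()
}

#' Calibrate a significance threshold under an error-rate constraint
#'
#' Reproduces the cross-constrained reporting protocol: Type I error is
#' reported at the smallest threshold whose empirical Type II error (missed
#' differential pathways) is at most `bound`; power is reported at the
#' largest threshold whose empirical Type I error is at most `bound`
#' (default bound 0.1 on both sides). Because the empirical error rates are
#' step functions of the threshold, the search space is the set of observed
#' P-values plus {0, 1}. When no threshold satisfies the bound — e.g. more
#' than `bound` of the null P-values are exactly zero — the result is
#' flagged infeasible (the situation in which a method's power cannot be
#' reported).
#'
#' @param records Tibble with `is_de` and `pvalue_combined` columns.
#' @param constrain `"type_ii_le"` or `"type_i_le"`.
#' @param bound Error-rate bound.
#' @return One-row tibble: `constraint`, `bound`, `feasible`, `threshold`,
#'   `type_i`, `type_ii`, `power` (rates evaluated at the returned
#'   threshold; `NA` when infeasible).
#' @export
calibrate_threshold <- function(records,
                                constrain = c("type_ii_le", "type_i_le"),
                                bound = 0.1) {
  constrain <- match.arg(constrain)
  if (nrow(records) == 0L) abort("no records")
  if ("error" %in% names(records)) {
    records <- dplyr::filter(records, is.na(.data$error) | .data$error == "")
  }
  p_null <- records$pvalue_combined[!records$is_de]
  p_de <- records$pvalue_combined[records$is_de]
  if (!length(p_null) || !length(p_de)) {
    abort("records must contain both null and differential pathways")
  }
  cand <- sort(unique(c(0, records$pvalue_combined, 1)))
  type_i <- vapply(cand, function(t) mean(p_null <= t), numeric(1))
  type_ii <- vapply(cand, function(t) mean(p_de > t), numeric(1))
  ok <- if (constrain == "type_ii_le") type_ii <= bound else type_i <= bound
  idx <- if (constrain == "type_ii_le") {
    if (any(ok)) min(which(ok)) else NA_integer_
  } else {
    if (any(ok)) max(which(ok)) else NA_integer_
  }
  if (is.na(idx)) {
    return(tibble::tibble(constraint = constrain, bound = bound,
                          feasible = FALSE, threshold = NA_real_,
                          type_i = NA_real_, type_ii = NA_real_,
                          power = NA_real_))
  }
  ti_at <- type_i[idx]
  tii_at <- type_ii[idx]
  tibble::tibble(constraint = constrain, bound = bound, feasible = TRUE,
                 threshold = cand[idx], type_i = ti_at,
                 type_ii = tii_at, power = 1 - tii_at)
}
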