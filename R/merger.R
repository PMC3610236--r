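#' Random train/test partition scheme
#'
#' Draws `n_splits` independent random partitions of a cohort: each split
#' samples `train_n + test_n` rows without replacement and assigns the first
#' `train_n` to training. Splits are mutually independent (fresh random
#' draws, not a rotation) and the whole scheme is deterministic given
#' `seed`.
#'
#' @param n number of rows available.
#' @param n_splits number of repeats (default 10).
#' @param train_n,test_n split sizes (defaults 538 / 200).
#' @param seed partition seed.
#' @return A `partition_scheme`: list with the parameters and `splits`, a
#'   list of `list(train =, test =)` index vectors.
#' @export
make_partitions <- function(n, n_splits = 10, train_n = 538, test_n = 200, seed = 1L) {
  if (train_n + test_n > n)
    stop_nbc("train_n + test_n = %d exceeds available rows (%d)", train_n + test_n, n)
  splits <- with_seed(seed, lapply(seq_len(n_splits), function(i) {
    idx <- sample.int(n, train_n + test_n)
    list(train = idx[seq_len(train_n)], test = idx[train_n + seq_len(test_n)])
  }))
  structure(list(n = n, n_splits = n_splits, train_n = train_n,
                 test_n = test_n, seed = as.integer(seed), splits = splits),
            class = "partition_scheme")
}

#' Run the partition ensemble
#'
#' For each split: fit the discretization map on the training rows only,
#' apply it to train and test, run greedy backward selection on the training
#' rows, fit the classifier on the selected variables, and evaluate it on
#' the held-out test rows. Nothing from the test rows touches binning,
#' selection or fitting.
#'
#' @param table a raw (not yet discretized) [cohort_table()].
#' @param scheme a [make_partitions()] scheme.
#' @param alpha smoothing pseudo-count (default 0.5).
#' @param k bins per continuous predictor (default 3).
#' @param candidates candidate predictors (default all).
#' @param objective greedy objective, see [greedy_select()].
#' @return An `ensemble_result`: per-split selected sets, models and test
#'   `diagnostics_report`s; `presence` (variable x split logical matrix);
#'   `consensus_counts` (its row sums); `aggregate` (mean/SD table across
#'   splits).
#' @export
run_ensemble <- function(table, scheme, alpha = 0.5, k = 3,
                         candidates = predictor_names(table),
                         objective = "logscore") {
  vars_all <- predictor_names(table)
  presence <- matrix(FALSE, nrow = length(vars_all), ncol = scheme$n_splits,
                     dimnames = list(vars_all, paste0("split", seq_len(scheme$n_splits))))
  splits <- vector("list", scheme$n_splits)
  for (s in seq_len(scheme$n_splits)) {
    tr <- cohort_rows(table, scheme$splits[[s]]$train)
    te <- cohort_rows(table, scheme$splits[[s]]$test)
    map <- fit_discretization(tr, k = k, vars = candidates)
    tr_d <- apply_discretization(tr, map)
    te_d <- apply_discretization(te, map)
    sel <- greedy_select(tr_d, candidates, objective = objective, alpha = alpha)
    model <- fit_nbc(tr_d, sel$selected, alpha = alpha)
    post <- predict_posterior(model, te_d)
    rep <- confusion_metrics(classify(model, posterior = post),
                             te$data$outcome, scores = post)
    presence[sel$selected, s] <- TRUE
    splits[[s]] <- list(selected = sel$selected, trace = sel, map = map,
                        model = model, test_report = rep)
  }
  structure(list(splits = splits, presence = presence,
                 consensus_counts = rowSums(presence),
                 aggregate = if (scheme$n_splits >= 2)
                   aggregate_splits(lapply(splits, `[[`, "test_report")),
                 scheme = scheme, alpha = alpha, k = k,
                 candidates = candidates),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: %d splits (train %d / test %d), %d candidates\n",
              x$scheme$n_splits, x$scheme$train_n, x$scheme$test_n, length(x$candidates)))
  cc <- sort(x$consensus_counts[x$consensus_counts > 0], decreasing = TRUE)
  cat("  selected in >=1 split:",
      paste(sprintf("%s(%d)", names(cc), cc), collapse = ", "), "\n")
  invisible(x)
}

#' Consensus variables across the ensemble
#'
#' Variables selected in at least `min_models` of the splits — the "likely
#' variables" admitted to final model building.
#'
#' @param ensemble an `ensemble_result`.
#' @param min_models minimum number of splits (default 4 of 10).
#' @return Character vector in schema order.
#' @export
consensus_variables <- function(ensemble, min_models = 4) {
  if (min_models < 1) stop_nbc("min_models must be >= 1")
  names(which(ensemble$consensus_counts >= min_models))
}

#' Fit the final merger model on the full cohort
#'
#' Re-discretizes on all rows, greedy-selects from the consensus candidate
#' pool, fits the final classifier, and attaches a LOOCV report, full-data
#' diagnostics and the posterior-odds evidence table.
#'
#' @param table a raw [cohort_table()].
#' @param candidates consensus candidate pool (non-empty).
#' @param alpha smoothing pseudo-count (default 0.5).
#' @param k bins per continuous predictor (default 3).
#' @param objective greedy objective.
#' @param level credibility level for the posterior-odds table.
#' @return A `final_model_result`: `candidates`, `selected`, `model`,
#'   `map`, `loocv` ([loocv()] report), `diagnostics` (full-data
#'   `diagnostics_report`), `po_table` (see [build_po_table()]), and the
#'   discretized table used.
#' @export
fit_final <- function(table, candidates, alpha = 0.5, k = 3,
                      objective = "logscore", level = 0.95) {
  if (!length(candidates)) stop_nbc("candidate pool is empty")
  map <- fit_discretization(table, k = k, vars = candidates)
  tab_d <- apply_discretization(table, map)
  sel <- greedy_select(tab_d, candidates, objective = objective, alpha = alpha)
  model <- fit_nbc(tab_d, sel$selected, alpha = alpha)
  post <- predict_posterior(model, tab_d)
  diag <- confusion_metrics(classify(model, posterior = post),
                            table$data$outcome, scores = post)
  res <- structure(list(candidates = candidates, selected = sel$selected,
                        trace = sel, map = map, model = model,
                        loocv = loocv(tab_d, sel$selected, alpha = alpha),
                        diagnostics = diag, table_discretized = tab_d,
                        alpha = alpha),
                   class = "final_model_result")
  res$po_table <- build_po_table(res, tab_d, level = level)
  res
}

#' @export
print.final_model_result <- function(x, ...) {
  cat(sprintf("final_model_result: %d of %d candidates selected\n",
              length(x$selected), length(x$candidates)))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  print(x$loocv)
  print(x$diagnostics)
  invisible(x)
}

#' One call for the whole merger-model pipeline
#'
#' Convenience wrapper: partitions, ensemble, consensus pool, final model.
#'
#' @param table a raw [cohort_table()].
#' @param seed partition seed.
#' @param n_splits,train_n,test_n partition parameters (defaults 10, 538, 200).
#' @param min_models consensus threshold (default 4).
#' @param alpha,k,objective forwarded to the stages.
#' @return List with `ensemble`, `consensus`, `final`.
#' @export
nbcmm <- function(table, seed = 1L, n_splits = 10, train_n = 538, test_n = 200,
                  min_models = 4, alpha = 0.5, k = 3, objective = "logscore") {
  scheme <- make_partitions(nrow(table$data), n_splits = n_splits,
                            train_n = train_n, test_n = test_n, seed = seed)
  ens <- run_ensemble(table, scheme, alpha = alpha, k = k, objective = objective)
  pool <- consensus_variables(ens, min_models = min_models)
  if (!length(pool)) stop_nbc("no variable reached the consensus threshold (%d models)", min_models)
  list(ensemble = ens, consensus = pool,
       final = fit_final(table, pool, alpha = alpha, k = k, objective = objective))
}
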