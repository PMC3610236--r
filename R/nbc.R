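#' Fit a naive Bayesian classifier
#'
#' Estimates the class prior as the positive fraction of the training rows
#' and, for every selected predictor, a per-category, per-class conditional
#' frequency table smoothed with a pseudo-count `alpha` per cell:
#' \deqn{P(x = c \mid y) = (n_{cy} + \alpha) / (n_{\cdot y} + \alpha K)}
#' with K the number of categories. Rows missing a predictor are excluded
#' from that predictor's table only (pairwise deletion), which is how the
#' classifier uses every row of a sparse clinical table while complete-case
#' regressions shed them.
#'
#' @param table a [cohort_table()] whose selected columns are categorical or
#'   binary (discretize continuous predictors first, see
#'   [fit_discretization()]).
#' @param vars predictors to include, in schema order.
#' @param alpha pseudo-count per cell; default 0.5 (a Jeffreys-style prior,
#'   the minimal smoothing that keeps zero cells finite).
#' @return An `nbc_model`: list with `prior`, `alpha`, `vars`, `levels`,
#'   per-predictor count `tables`, and training class counts.
#' @export
fit_nbc <- function(table, vars = predictor_names(table), alpha = 0.5) {
  y <- table$data$outcome
  if (length(unique(y)) < 2) stop_nbc("training outcome contains a single class")
  if (!length(vars)) vars <- character(0)
  tabs <- list(); levs <- list()
  for (nm in vars) {
    sc <- table$schema[[nm]]
    if (is.null(sc)) stop_nbc("unknown predictor '%s'", nm)
    if (sc$kind == "continuous")
      stop_nbc("predictor '%s' is continuous; apply a discretization map first", nm)
    codes <- match(table$data[[nm]], sc$levels)
    obs <- !is.na(codes)
    cnt <- matrix(0, nrow = length(sc$levels), ncol = 2,
                  dimnames = list(sc$levels, c("0", "1")))
    if (any(obs)) {
      t2 <- table(factor(codes[obs], levels = seq_along(sc$levels)),
                  factor(y[obs], levels = c(0, 1)))
      cnt[] <- as.numeric(t2)
    }
    tabs[[nm]] <- cnt
    levs[[nm]] <- sc$levels
  }
  structure(list(prior = mean(y), n = length(y),
                 class_n = c(`0` = sum(y == 0), `1` = sum(y == 1)),
                 alpha = alpha, vars = vars, levels = levs, tables = tabs),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat(sprintf("nbc_model: prior P(y=1) = %.3f (n = %d), %d predictors, alpha = %g\n",
              x$prior, x$n, length(x$vars), x$alpha))
  if (length(x$vars)) cat("  vars:", paste(x$vars, collapse = ", "), "\n")
  invisible(x)
}

#' Smoothed conditional probability table of one predictor
#' @param model an `nbc_model`.
#' @param var predictor name.
#' @return Matrix categories x classes of P(category | class); each column
#'   sums to one.
#' @export
nbc_cond_prob <- function(model, var) {
  cnt <- model$tables[[var]]
  if (is.null(cnt)) stop_nbc("'%s' is not in the model", var)
  sweep(cnt + model$alpha, 2, colSums(cnt) + model$alpha * nrow(cnt), "/")
}

# per-row log conditional contributions for both classes; unseen categories
# warn once and contribute nothing (same as missing)
nbc_logcontrib <- function(model, data, var) {
  lv <- model$levels[[var]]
  v <- data[[var]]
  codes <- match(as.character(v), lv)
  unseen <- !is.na(v) & is.na(codes)
  if (is.numeric(v) && any(unseen))
    stop_nbc("predictor '%s' is numeric in new data; discretize with the fitted map", var)
  if (any(unseen))
    warning(sprintf("%d value(s) of '%s' not among fit-time categories; treated as missing",
                    sum(unseen), var), call. = FALSE)
  pr <- nbc_cond_prob(model, var)
  l0 <- l1 <- numeric(length(codes))
  ok <- !is.na(codes)
  l0[ok] <- log(pr[codes[ok], 1])
  l1[ok] <- log(pr[codes[ok], 2])
  cbind(l0 = l0, l1 = l1)
}

#' Posterior probability of the positive class
#'
#' Applies Bayes rule under conditional independence over the model's
#' predictors: the posterior is proportional to the prior times the product
#' of P(observed value | class). Missing predictors contribute no factor, so
#' a patient with no observed predictors scores exactly the class prior.
#'
#' @param model an `nbc_model`.
#' @param newdata a [cohort_table()], data.frame, or single named list/row.
#' @return Numeric vector of posterior probabilities P(y = 1 | observed).
#' @export
predict_posterior <- function(model, newdata) {
  df <- if (inherits(newdata, "cohort_table")) newdata$data
        else if (is.data.frame(newdata)) newdata
        else as.data.frame(lapply(newdata, function(v) if (is.null(v)) NA else v),
                           optional = TRUE, stringsAsFactors = FALSE)
  n <- nrow(df)
  dl <- rep(stats::qlogis(model$prior), n)
  for (nm in model$vars) {
    if (!nm %in% names(df)) next  # absent column = missing for every row
    lc <- nbc_logcontrib(model, df, nm)
    d <- lc[, "l1"] - lc[, "l0"]
    d[is.nan(d)] <- 0  # -Inf vs -Inf under alpha = 0: no evidence either way
    dl <- dl + d
  }
  unname(stats::plogis(dl))
}

#' Classify from posterior probabilities
#'
#' Positive when the posterior exceeds `threshold`; an exact tie goes to the
#' majority training class so the decision is deterministic.
#'
#' @param model an `nbc_model`.
#' @param newdata rows to classify (or omit and pass `posterior`).
#' @param threshold decision threshold in (0, 1), default 0.5.
#' @param posterior optional pre-computed posteriors.
#' @return Integer vector of 0/1 calls.
#' @export
classify <- function(model, newdata = NULL, threshold = 0.5, posterior = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(posterior)) posterior <- predict_posterior(model, newdata)
  majority <- as.integer(model$prior > 0.5)
  out <- as.integer(posterior > threshold)
  out[posterior == threshold] <- majority
  out
}

# ---- leave-one-out machinery ----------------------------------------------

# Cached LOO-adjusted per-row log-contributions. Because the naive-Bayes
# log-posterior is additive over predictors and each predictor's table uses
# pairwise deletion, the leave-one-out posterior for any predictor subset is
# the LOO prior logit plus the sum of the cached per-predictor terms —
# identical to refitting n models, at O(n k) cost.
loo_contributions <- function(table, vars, alpha) {
  y <- table$data$outcome
  n <- length(y)
  if (n < 2) stop_nbc("leave-one-out needs at least 2 rows")
  if (length(unique(y)) < 2) stop_nbc("outcome contains a single class")
  D <- matrix(0, nrow = n, ncol = length(vars), dimnames = list(NULL, vars))
  for (nm in vars) {
    sc <- table$schema[[nm]]
    if (is.null(sc)) stop_nbc("unknown predictor '%s'", nm)
    if (sc$kind == "continuous")
      stop_nbc("predictor '%s' is continuous; apply a discretization map first", nm)
    lv <- sc$levels
    K <- length(lv)
    codes <- match(table$data[[nm]], lv)
    obs <- !is.na(codes)
    cnt <- matrix(0, nrow = K, ncol = 2)
    if (any(obs)) {
      t2 <- table(factor(codes[obs], levels = seq_len(K)),
                  factor(y[obs], levels = c(0, 1)))
      cnt[] <- as.numeric(t2)
    }
    Nv <- colSums(cnt)
    same_cnt <- cnt[cbind(codes, y + 1L)] - 1
    other_cnt <- cnt[cbind(codes, 2L - y)]
    l_same <- log(same_cnt + alpha) - log(Nv[y + 1L] - 1 + alpha * K)
    l_other <- log(other_cnt + alpha) - log(Nv[2L - y] + alpha * K)
    l1 <- ifelse(y == 1L, l_same, l_other)
    l0 <- ifelse(y == 1L, l_other, l_same)
    d <- l1 - l0
    d[!obs | is.nan(d)] <- 0
    D[, nm] <- d
  }
  n1 <- sum(y == 1)
  p1_loo <- (n1 - y) / (n - 1)
  list(D = D, prior_logit_loo = stats::qlogis(p1_loo), y = y, n = n, prior = mean(y))
}

# objective of a predictor subset from cached contributions;
# log-score = mean -ln P(true class), accuracy in percent
loo_objective <- function(ctx, vars, threshold = 0.5) {
  dl <- ctx$prior_logit_loo
  if (length(vars)) dl <- dl + rowSums(ctx$D[, vars, drop = FALSE])
  p1 <- stats::plogis(dl)
  p_true <- ifelse(ctx$y == 1L, p1, 1 - p1)
  majority <- as.integer(ctx$prior > 0.5)
  call <- as.integer(p1 > threshold)
  call[p1 == threshold] <- majority
  list(logscore = mean(-log(p_true)),
       accuracy = 100 * mean(call == ctx$y))
}

#' Leave-one-out cross-validation of a naive Bayes model
#'
#' Scores each row with a model fit on the remaining n - 1 rows and reports
#' percent accuracy and the log-score (mean of -ln of the predicted
#' probability of the true class, natural log), alongside the same two
#' numbers for the "best guess" reference that always predicts from the
#' class prior alone.
#'
#' @param table a discretized [cohort_table()].
#' @param vars predictors to use.
#' @param alpha smoothing pseudo-count (default 0.5).
#' @param threshold decision threshold (default 0.5).
#' @return A `loocv_report` list: `accuracy`, `log_score`,
#'   `default_accuracy`, `default_log_score`, `posterior` (per-row LOO
#'   posteriors), `n`.
#' @export
loocv <- function(table, vars, alpha = 0.5, threshold = 0.5) {
  ctx <- loo_contributions(table, vars, alpha)
  obj <- loo_objective(ctx, vars, threshold)
  pbar <- ctx$prior
  p_true_default <- ifelse(ctx$y == 1L, pbar, 1 - pbar)
  dl <- ctx$prior_logit_loo + if (length(vars)) rowSums(ctx$D[, vars, drop = FALSE]) else 0
  structure(list(accuracy = obj$accuracy,
                 log_score = obj$logscore,
                 default_accuracy = 100 * max(pbar, 1 - pbar),
                 default_log_score = mean(-log(p_true_default)),
                 posterior = stats::plogis(dl),
                 n = ctx$n, vars = vars, alpha = alpha),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("LOOCV (n = %d, %d vars): accuracy %.1f%% (log-score %.3f); default %.1f%% (log-score %.3f)\n",
              x$n, length(x$vars), x$accuracy, x$log_score,
              x$default_accuracy, x$default_log_score))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

#' Serialize an NBC model to JSON
#' @param model an `nbc_model`.
#' @param path output path, or `NULL` to return the JSON string.
#' @return The path (invisibly) or the JSON string.
#' @export
write_nbc_model <- function(model, path = NULL) {
  obj <- list(prior = model$prior, n = model$n, alpha = model$alpha,
              vars = model$vars,
              tables = lapply(model$vars, function(v) {
                list(levels = model$levels[[v]],
                     counts = unname(apply(model$tables[[v]], 2, as.numeric, simplify = FALSE)),
                     cond_prob = unname(apply(nbc_cond_prob(model, v), 2, as.numeric,
                                              simplify = FALSE)))
              }))
  names(obj$tables) <- model$vars
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Export the model structure as a DOT star graph
#'
#' The naive Bayes structure is a star: the outcome node with one edge to
#' each selected predictor — the usual way these models are drawn.
#'
#' @param model an `nbc_model`.
#' @param outcome_label label for the hub node.
#' @return A character scalar of DOT source.
#' @export
nbc_to_dot <- function(model, outcome_label = "outcome") {
  lines <- c("digraph nbc {",
             sprintf("  \"%s\" [shape=doublecircle];", outcome_label),
             vapply(model$vars, function(v)
               sprintf("  \"%s\" -> \"%s\";", outcome_label, v), character(1)),
             "}")
  paste(lines, collapse = "\n")
}
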