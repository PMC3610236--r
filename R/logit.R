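#' Worst-possible correct classification over a full cohort
#'
#' A complete-case model evaluated on `n_used` of `n_total` rows leaves the
#' remainder unclassified; assuming every unused row would be misclassified
#' gives the floor `round(correct_pct/100 * n_used) / n_total * 100` — the
#' guaranteed lower bound on whole-cohort percent correct.
#'
#' @param correct_pct percent correct among the rows the model used.
#' @param n_used rows used by the complete-case fit.
#' @param n_total rows in the full cohort.
#' @return Percent, in `[0, correct_pct]`.
#' @export
floor_classification <- function(correct_pct, n_used, n_total) {
  if (n_used > n_total) stop_nbc("n_used exceeds n_total")
  round(correct_pct / 100 * n_used) / n_total * 100
}

# raw model frame for regression: binary flags numeric 0/1, categorical as
# factor, continuous as-is
logit_frame <- function(table) {
  df <- table$data
  for (nm in predictor_names(table)) {
    sc <- table$schema[[nm]]
    if (sc$kind == "binary") df[[nm]] <- as.numeric(df[[nm]] == "1")
    else if (sc$kind == "categorical") df[[nm]] <- factor(df[[nm]], levels = sc$levels)
  }
  df
}

term_pvalues <- function(fit) {
  d <- stats::drop1(fit, test = "LRT")
  stats::setNames(d[["Pr(>Chi)"]][-1], rownames(d)[-1])
}

#' Fit one of the six logistic-regression comparison strategies
#'
#' All variants are complete-case maximum-likelihood logistic fits, differing
#' only in how the predictor list is chosen:
#' \describe{
#'   \item{1}{the variables of the final merger model (`nbcmm_vars`);}
#'   \item{2}{variables with at least 80\% of observations present;}
#'   \item{3}{variables with 100\% of observations present;}
#'   \item{4}{forward stepwise over all candidates, LRT entry p < 0.10;}
#'   \item{5}{backward stepwise over all candidates, LRT stay p < 0.10;}
#'   \item{6}{manual one-by-one dropping of the worst-p predictor, refitting
#'     on the complete cases of the remaining predictors, until all p < 0.10.}
#' }
#' Variants 4 and 5 run on the complete-case rows of the full candidate set
#' (as an automated stepwise procedure would), which is why their n can be
#' far smaller than variant 6's, whose usable rows grow as predictors leave.
#'
#' @param table a raw [cohort_table()].
#' @param variant integer 1..6.
#' @param nbcmm_vars final merger-model variable list (required for variant 1).
#' @param candidates candidate predictors (default all).
#' @param p_threshold stepwise entry/stay threshold (default 0.10).
#' @param threshold classification threshold on the fitted probability
#'   (default 0.5).
#' @return A `logit_variant_result`: variant id, `predictors`, coefficient
#'   table (`or`, `se` of the OR by the delta method, `p`), `n_used`,
#'   `n_total`, `proportion_used`, model `chi2` and `chi2_p` (LR test
#'   against the null), McFadden `pseudo_r2`, `log_lik`, `aic`, `bic`,
#'   `diagnostics` at the threshold, `correct_pct`, `floor_pct`, and
#'   `converged` (FALSE flags separation).
#' @export
fit_logit_variant <- function(table, variant, nbcmm_vars = NULL,
                              candidates = predictor_names(table),
                              p_threshold = 0.10, threshold = 0.5) {
  if (!variant %in% 1:6) stop_nbc("variant must be in 1..6")
  df <- logit_frame(table)
  n_total <- nrow(df)
  obs_frac <- vapply(candidates, function(nm) mean(!is.na(df[[nm]])), numeric(1))
  pick_rows <- function(vars) {
    if (!length(vars)) return(seq_len(n_total))
    which(stats::complete.cases(df[, vars, drop = FALSE]))
  }

  if (variant == 1) {
    if (is.null(nbcmm_vars) || !length(nbcmm_vars))
      stop_nbc("variant 1 requires the final merger-model variable list")
    vars <- nbcmm_vars
    rows <- pick_rows(vars)
  } else if (variant == 2) {
    vars <- candidates[obs_frac >= 0.80]
    rows <- pick_rows(vars)
  } else if (variant == 3) {
    vars <- candidates[obs_frac == 1]
    rows <- pick_rows(vars)
  } else if (variant %in% c(4, 5)) {
    rows <- pick_rows(candidates)
    dd <- df[rows, , drop = FALSE]
    vars <- if (variant == 4) stepwise_forward(dd, candidates, p_threshold)
            else stepwise_backward(dd, candidates, p_threshold)
  } else {
    vars <- candidates
    repeat {
      rows <- pick_rows(vars)
      fit <- stats::glm(stats::reformulate(vars, "outcome"),
                        family = stats::binomial(), data = df[rows, , drop = FALSE])
      pv <- term_pvalues(fit)
      if (!length(pv) || max(pv) < p_threshold || length(vars) == 1) break
      vars <- setdiff(vars, names(which.max(pv)))
    }
  }
  fml <- if (length(vars)) stats::reformulate(vars, "outcome")
         else stats::as.formula("outcome ~ 1")
  dd <- df[rows, , drop = FALSE]
  if (length(unique(dd$outcome)) < 2) stop_nbc("complete-case rows contain a single outcome class")
  fit <- stats::glm(fml, family = stats::binomial(), data = dd)
  sm <- summary(fit)$coefficients
  beta <- sm[, 1]; se_b <- sm[, 2]; pz <- sm[, 4]
  keep <- rownames(sm) != "(Intercept)"
  coefs <- data.frame(term = rownames(sm)[keep],
                      or = exp(beta[keep]),
                      se = exp(beta[keep]) * se_b[keep],  # delta-method SE of the OR
                      p = pz[keep], row.names = NULL, stringsAsFactors = FALSE)
  # separation shows up as runaway slopes/SEs; the intercept is excluded
  # because its scale follows the predictors' raw units
  converged <- fit$converged && all(se_b[keep] < 50) && all(abs(beta[keep]) < 15)
  ll <- as.numeric(stats::logLik(fit))
  null_fit <- stats::glm(outcome ~ 1, family = stats::binomial(), data = dd)
  ll0 <- as.numeric(stats::logLik(null_fit))
  chi2 <- 2 * (ll - ll0)
  dfree <- length(stats::coef(fit)) - 1
  prob <- stats::predict(fit, type = "response")
  calls <- as.integer(prob > threshold)
  diag <- confusion_metrics(calls, dd$outcome,
                            scores = if (length(unique(dd$outcome)) == 2) prob else NULL)
  structure(list(variant = variant, predictors = vars, coefficients = coefs,
                 n_used = length(rows), n_total = n_total,
                 proportion_used = length(rows) / n_total,
                 chi2 = chi2,
                 chi2_p = if (dfree > 0) stats::pchisq(chi2, dfree, lower.tail = FALSE) else NA_real_,
                 pseudo_r2 = if (ll0 != 0) 1 - ll / ll0 else NA_real_,
                 log_lik = ll, aic = stats::AIC(fit), bic = stats::BIC(fit),
                 diagnostics = diag, correct_pct = diag$accuracy,
                 floor_pct = floor_classification(diag$accuracy, length(rows), n_total),
                 converged = converged, fit = fit),
            class = "logit_variant_result")
}

stepwise_forward <- function(dd, candidates, p_threshold) {
  vars <- character(0)
  fit <- stats::glm(outcome ~ 1, family = stats::binomial(), data = dd)
  repeat {
    remaining <- setdiff(candidates, vars)
    if (!length(remaining)) break
    # upper scope must contain the current terms as well as the additions
    a <- stats::add1(fit, scope = stats::reformulate(candidates), test = "LRT")
    pv <- stats::setNames(a[["Pr(>Chi)"]][-1], rownames(a)[-1])
    if (!length(pv) || min(pv, na.rm = TRUE) >= p_threshold) break
    vars <- c(vars, names(which.min(pv)))
    fit <- stats::glm(stats::reformulate(vars, "outcome"),
                      family = stats::binomial(), data = dd)
  }
  vars
}

stepwise_backward <- function(dd, candidates, p_threshold) {
  vars <- candidates
  repeat {
    if (!length(vars)) break
    fit <- stats::glm(stats::reformulate(vars, "outcome"),
                      family = stats::binomial(), data = dd)
    pv <- term_pvalues(fit)
    if (!length(pv) || max(pv, na.rm = TRUE) < p_threshold) break
    vars <- setdiff(vars, names(which.max(pv)))
  }
  vars
}

#' @export
print.logit_variant_result <- function(x, ...) {
  cat(sprintf("logit variant %d: %d predictors, n = %d/%d (%.1f%%), correct %.2f%%, floor %.2f%%%s\n",
              x$variant, length(x$predictors), x$n_used, x$n_total,
              100 * x$proportion_used, x$correct_pct, x$floor_pct,
              if (x$converged) "" else " [non-converged]"))
  invisible(x)
}

#' Run all six logistic benchmark variants
#'
#' @inheritParams fit_logit_variant
#' @param variants which variants to run (default 1:6).
#' @return List of `logit_variant_result`s named `logit1`..`logit6`.
#' @export
run_logit_benchmark <- function(table, nbcmm_vars, candidates = predictor_names(table),
                                p_threshold = 0.10, variants = 1:6) {
  out <- lapply(variants, function(v)
    fit_logit_variant(table, v, nbcmm_vars = nbcmm_vars,
                      candidates = candidates, p_threshold = p_threshold))
  stats::setNames(out, paste0("logit", variants))
}
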