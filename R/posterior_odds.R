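#' Posterior odds of a probability
#'
#' The evidence-strength measure reported for each factor:
#' `PO = p / (1 - p)`, the odds of the predicted class against the
#' non-predicted class. Degenerate probabilities signal distinctly: p = 0
#' returns 0 and p = 1 returns `Inf`, each with a warning.
#'
#' @param p probability (vectorised).
#' @return Odds, same length as `p`.
#' @export
compute_po <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_nbc("probabilities must lie in [0,1]")
  if (any(p %in% c(0, 1)))
    warning("degenerate probability 0 or 1: posterior odds are 0 or Inf", call. = FALSE)
  p / (1 - p)
}

#' Jeffreys credibility interval for a binomial proportion
#'
#' Equal-tailed interval from the Beta(x + 1/2, n - x + 1/2) posterior (the
#' Jeffreys prior), with the conventional boundary fixes: the lower limit is
#' 0 when x = 0 and the upper limit is 1 when x = n.
#'
#' @param successes number of successes x.
#' @param n number of trials.
#' @param level credibility level (default 0.95).
#' @return Numeric `c(lo, hi)` on the probability scale.
#' @export
jeffreys_interval <- function(successes, n, level = 0.95) {
  if (!is_count(n) || n < 1) stop_nbc("n must be a positive integer")
  if (!is_count(successes) || successes > n) stop_nbc("successes must lie in 0..n")
  a <- (1 - level) / 2
  lo <- if (successes == 0) 0 else stats::qbeta(a, successes + 0.5, n - successes + 0.5)
  hi <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 0.5, n - successes + 0.5)
  c(lo = lo, hi = hi)
}

#' Odds-transform a probability interval
#'
#' Applies `p / (1 - p)` to both endpoints; the transform is strictly
#' increasing on (0, 1) so ordering and containment are preserved.
#'
#' @param p_interval numeric `c(lo, hi)` with `0 < lo <= hi < 1` (0 and 1
#'   signal as in [compute_po()]).
#' @return Numeric `c(lo, hi)` on the odds scale.
#' @export
po_interval <- function(p_interval) {
  if (length(p_interval) != 2 || p_interval[1] > p_interval[2])
    stop_nbc("p_interval must be c(lo, hi) with lo <= hi")
  out <- compute_po(p_interval)
  names(out) <- c("lo", "hi")
  out
}

#' Single-factor posterior probability of a class
#'
#' Raw conditional frequency P(class | variable = category), computed over
#' the rows where the variable is observed. This is the "predicted class"
#' percentage of the evidence table; counts are returned so credibility
#' intervals can be formed under either convention.
#'
#' @param table a discretized [cohort_table()].
#' @param factor `c(variable, category)`.
#' @param class outcome class the probability refers to (default 1).
#' @return List: `p`, `successes` (factor rows in the class), `n_factor`
#'   (rows with the factor), `n_observed` (rows with the variable observed).
#' @export
single_factor_posterior <- function(table, factor, class = 1L) {
  var <- factor[[1]]; cat <- as.character(factor[[2]])
  v <- table$data[[var]]
  if (is.null(v)) stop_nbc("unknown variable '%s'", var)
  has <- !is.na(v) & v == cat
  if (!any(has)) stop_nbc("factor %s=%s never observed", var, cat)
  y <- table$data$outcome
  list(p = mean(y[has] == class),
       successes = sum(y[has] == class),
       n_factor = sum(has),
       n_observed = sum(!is.na(v)))
}

#' Inversed probability P(factor | class)
#'
#' The likelihood direction of Bayes rule: among the rows of the given class
#' in which the variable is observed, the fraction carrying the factor's
#' category.
#'
#' @inheritParams single_factor_posterior
#' @return List: `p`, `successes`, `n_class` (class rows with the variable
#'   observed).
#' @export
inversed_probability <- function(table, factor, class = 1L) {
  var <- factor[[1]]; cat <- as.character(factor[[2]])
  v <- table$data[[var]]
  if (is.null(v)) stop_nbc("unknown variable '%s'", var)
  y <- table$data$outcome
  in_class <- y == class & !is.na(v)
  if (!any(in_class)) stop_nbc("class %s has no observed rows for '%s'", class, var)
  list(p = mean(v[in_class] == cat),
       successes = sum(v[in_class] == cat),
       n_class = sum(in_class))
}

#' Build the posterior-odds evidence table for a final model
#'
#' For every variable of the final model, emits one protective-direction
#' record (the category most frequent in the good-outcome class, predicted
#' class = alive without very poor HRQoL) and one risk-direction record (the
#' category most associated with the poor outcome), each with: the raw
#' single-factor posterior percentage, its Jeffreys credibility interval,
#' the posterior odds and odds-transformed interval, and the inversed
#' probability P(factor | predicted class) with its own interval and odds.
#' Percentages and odds are rounded to one decimal for presentation; the
#' unrounded values are kept in `attr(, "raw")`.
#'
#' @param final a `final_model_result` (or any list with `selected`).
#' @param table the discretized [cohort_table()] the model was fit on.
#' @param level credibility level (default 0.95).
#' @param ci_n denominator convention for the posterior-percentage interval:
#'   `"observed"` (default) uses the number of rows with the variable
#'   observed, mirroring published usage where intervals are formed on the
#'   analysis cohort; `"factor"` uses only the rows carrying the factor.
#' @return Data.frame with columns factor, direction, p, p_lo, p_hi, po,
#'   po_lo, po_hi, inv_p, inv_lo, inv_hi, inv_po, inv_po_lo, inv_po_hi.
#' @export
build_po_table <- function(final, table, level = 0.95,
                           ci_n = c("observed", "factor")) {
  ci_n <- match.arg(ci_n)
  vars <- final$selected
  rows <- list(); raws <- list()
  for (nm in vars) {
    sc <- table$schema[[nm]]
    v <- table$data[[nm]]
    y <- table$data$outcome
    obs <- !is.na(v)
    cats <- sc$levels[sc$levels %in% v[obs]]
    p1 <- vapply(cats, function(cc) mean(y[obs & v == cc] == 1L), numeric(1))
    picks <- c(protective = cats[which.min(p1)], risk = cats[which.max(p1)])
    for (dir in c("protective", "risk")) {
      cls <- if (dir == "protective") 0L else 1L
      fac <- c(nm, picks[[dir]])
      sf <- single_factor_posterior(table, fac, class = cls)
      n_ci <- if (ci_n == "observed") sf$n_observed else sf$n_factor
      x_ci <- if (ci_n == "observed") round(sf$p * sf$n_observed) else sf$successes
      p_ci <- jeffreys_interval(x_ci, n_ci, level)
      inv <- inversed_probability(table, fac, class = cls)
      inv_ci <- jeffreys_interval(inv$successes, inv$n_class, level)
      clamp <- function(p) pmin(pmax(p, 0), 1)
      raw <- data.frame(
        factor = sprintf("%s=%s", nm, picks[[dir]]), direction = dir,
        p = 100 * sf$p, p_lo = 100 * p_ci[1], p_hi = 100 * p_ci[2],
        po = compute_po(clamp(sf$p)), po_lo = compute_po(p_ci[1]), po_hi = compute_po(p_ci[2]),
        inv_p = 100 * inv$p, inv_lo = 100 * inv_ci[1], inv_hi = 100 * inv_ci[2],
        inv_po = compute_po(clamp(inv$p)),
        inv_po_lo = compute_po(inv_ci[1]), inv_po_hi = compute_po(inv_ci[2]),
        stringsAsFactors = FALSE)
      raws[[length(raws) + 1L]] <- raw
      rnd <- raw
      num <- vapply(rnd, is.numeric, logical(1))
      rnd[num] <- lapply(rnd[num], round, 1)
      rows[[length(rows) + 1L]] <- rnd
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "raw") <- do.call(rbind, raws)
  attr(out, "level") <- level
  attr(out, "ci_n") <- ci_n
  out
}
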