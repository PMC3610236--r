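#' Declare a predictor column
#'
#' Helper used when assembling a [cohort_spec()]. Each predictor is one of
#' three kinds: `"binary"` (0/1 flag), `"categorical"` (finite level set) or
#' `"continuous"` (real-valued, later discretized for the classifier).
#'
#' @param name column name, unique within a spec.
#' @param kind one of `"binary"`, `"categorical"`, `"continuous"`.
#' @param prevalence for binary predictors, P(flag = 1).
#' @param levels,probs for categorical predictors, the level labels and their
#'   marginal probabilities (probs are normalised).
#' @param dist for continuous predictors, `"normal"` or `"lognormal"`.
#' @param mean,sd moments of the continuous marginal on the natural scale.
#' @param cutpoints optional fixed discretization cutpoints (a clinical rule,
#'   e.g. BMI classes); when present they override data-driven binning.
#' @return A `predictor_spec` list.
#' @export
predictor_spec <- function(name, kind = c("binary", "categorical", "continuous"),
                           prevalence = NULL, levels = NULL, probs = NULL,
                           dist = c("normal", "lognormal"), mean = NULL, sd = NULL,
                           cutpoints = NULL) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    stopifnot(is.numeric(prevalence), prevalence >= 0, prevalence <= 1)
    levels <- c("0", "1")
  } else if (kind == "categorical") {
    stopifnot(length(levels) >= 2)
    levels <- as.character(levels)
    if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
    probs <- probs / sum(probs)
  } else {
    dist <- match.arg(dist)
    stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  }
  if (!is.null(cutpoints) && is.unsorted(cutpoints, strictly = TRUE))
    stop_nbc("fixed cutpoints for '%s' must be strictly increasing", name)
  structure(list(name = name, kind = kind, prevalence = prevalence,
                 levels = levels, probs = probs,
                 dist = if (kind == "continuous") dist else NULL,
                 mean = mean, sd = sd, cutpoints = cutpoints),
            class = "predictor_spec")
}

#' Specification of a synthetic cohort
#'
#' Bundles everything needed to draw a reproducible patient table: the
#' predictor roster, planted log-odds effects on the latent (pre-binning)
#' predictor scale, the outcome model intercept, and per-column missingness.
#'
#' The binary outcome is drawn from a logistic model
#' \deqn{logit P(y=1) = \beta_0 + \sum_j \beta_j x_j}
#' where binary predictors enter as 0/1 and continuous predictors enter
#' centred at their marginal mean (so `baseline_log_odds` is the log-odds of
#' a reference patient). If `target_prevalence` is non-`NULL` the intercept
#' is instead solved at generation time so that the mean outcome probability
#' over the realised covariates equals the target exactly.
#'
#' @param n_patients number of rows to draw.
#' @param predictors list of [predictor_spec()] entries with unique names.
#' @param effects named numeric vector of planted log-odds coefficients;
#'   names must be binary or continuous predictors in the roster.
#' @param baseline_log_odds intercept used when `target_prevalence` is `NULL`.
#' @param target_prevalence optional marginal outcome prevalence to calibrate
#'   the intercept to.
#' @param missingness list of entries `list(predictor=, mechanism=, rate=,
#'   depends_on=)`; mechanism is `"MCAR"` or `"MAR"` (rate modulated by an
#'   observed covariate named in `depends_on`).
#' @param seed default root seed for [generate_cohort()].
#' @return A `cohort_spec` object.
#' @seealso [default_cohort_spec()] for the 49-predictor COPD-style default.
#' @export
cohort_spec <- function(n_patients, predictors, effects = numeric(0),
                        baseline_log_odds = 0, target_prevalence = NULL,
                        missingness = list(), seed = 1L) {
  if (!is_count(n_patients)) stop_nbc("n_patients must be a non-negative integer")
  nms <- vapply(predictors, `[[`, "", "name")
  if (anyDuplicated(nms)) stop_nbc("duplicate predictor names: %s",
                                   paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (length(effects)) {
    bad <- setdiff(names(effects), nms)
    if (length(bad)) stop_nbc("plantedEffects refer to unknown predictors: %s",
                              paste(bad, collapse = ", "))
    kinds <- vapply(predictors, `[[`, "", "kind")
    names(kinds) <- nms
    if (any(kinds[names(effects)] == "categorical"))
      stop_nbc("planted effects must act on binary or continuous predictors")
  }
  for (m in missingness) {
    if (!m$predictor %in% nms) stop_nbc("missingness refers to unknown predictor '%s'", m$predictor)
    if (!is.numeric(m$rate) || m$rate < 0 || m$rate > 1)
      stop_nbc("missingness rate for '%s' outside [0,1]", m$predictor)
  }
  structure(list(n_patients = as.integer(n_patients),
                 predictors = stats::setNames(predictors, nms),
                 effects = effects, baseline_log_odds = baseline_log_odds,
                 target_prevalence = target_prevalence,
                 missingness = missingness, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  kinds <- table(vapply(x$predictors, `[[`, "", "kind"))
  cat(sprintf("cohort_spec: %d patients, %d predictors (%s), %d planted effects\n",
              x$n_patients, length(x$predictors),
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", "),
              length(x$effects)))
  invisible(x)
}

#' Default synthetic COPD-style cohort specification
#'
#' A 49-predictor roster shaped like a secondary-care COPD cohort: binary
#' comorbidity and medication flags, spirometry and ECG measurements,
#' anthropometry and two ordered categorical severity scores. Ten planted
#' effects (odds ratios roughly 2-4.7 on comorbidity flags; per-unit effects
#' on FEV1 % predicted, QTc, age at asthma onset and BMI) drive a composite
#' binary outcome with default marginal prevalence 0.287. Default
#' missingness is MCAR on twelve measurement columns with rates chosen so
#' that the all-variable complete-case fraction is about 0.56.
#'
#' @param n_patients cohort size (default 738).
#' @param target_prevalence marginal outcome prevalence (default 0.287).
#' @param seed default generation seed.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_patients = 738, target_prevalence = 0.287, seed = 1L) {
  bin <- function(name, p) predictor_spec(name, "binary", prevalence = p)
  con <- function(name, mean, sd, dist = "normal", cutpoints = NULL)
    predictor_spec(name, "continuous", dist = dist, mean = mean, sd = sd, cutpoints = cutpoints)
  preds <- list(
    bin("gender_male", 0.64),
    bin("current_smoking", 0.35),
    con("year_copd_onset", 1999, 5),
    con("age_copd_onset", 58.2, 7.4),
    con("age_asthma_onset", 56.6, 7.5),
    con("copd_duration", 5.5, 4.9),
    bin("hypertension", 0.41),
    bin("cerebrovascular_disease", 0.075),
    bin("paod", 0.045),
    bin("cardiovascular_disease", 0.28),
    bin("diabetes", 0.15),
    bin("metabolic_syndrome", 0.22),
    bin("hypercholesterolemia", 0.30),
    bin("hypothyreosis", 0.06),
    bin("alcohol_abuse", 0.15),
    bin("cancer", 0.08),
    bin("atrial_fibrillation", 0.08),
    bin("psychiatric_disease", 0.10),
    con("bmi", 26.3, 4.2, cutpoints = c(20, 25, 30)),
    con("bmi_change", 0.5, 2.0),
    con("dlco_pct", 76, 22),
    con("rv_pct", 120, 35),
    con("fvc_pct", 74.5, 18),
    con("fev1_pct", 57.2, 18.6),
    con("qrs_axis", 30, 35),
    con("qtc_ms", 420, 25),
    con("qrs_ms", 95, 12),
    con("age", 64.0, 6.8),
    con("pack_years", 50, 20, dist = "lognormal"),
    bin("coronary_disease", 0.215),
    bin("home_oxygen", 0.031),
    con("fev1_fvc_ratio", 61.5, 13.9),
    con("fev1_postbd_pct", 60.9, 17.6),
    con("fvc_postbd_pct", 77.5, 17.2),
    con("fev1_fvc_postbd", 63.2, 13.5),
    predictor_spec("gold_stage", "categorical",
                   levels = c("0", "1", "2", "3", "4", "undef"),
                   probs = c(0.10, 0.025, 0.37, 0.18, 0.05, 0.275)),
    con("arterial_o2", 9.6, 1.5),
    con("arterial_co2", 5.3, 0.6),
    bin("inhaled_steroid_use", 0.60),
    bin("oral_steroid_use", 0.10),
    bin("beta_agonist_use", 0.55),
    bin("anticholinergic_use", 0.40),
    bin("theophylline_use", 0.12),
    con("exacerbations_prev_year", 1.5, 1.5, dist = "lognormal"),
    predictor_spec("mrc_dyspnoea", "categorical",
                   levels = c("1", "2", "3", "4", "5"),
                   probs = c(0.10, 0.25, 0.30, 0.25, 0.10)),
    con("heart_rate", 78, 12),
    con("pr_interval_ms", 160, 20),
    con("haemoglobin", 142, 14),
    con("crp", 5, 6, dist = "lognormal")
  )
  effects <- c(
    cerebrovascular_disease = log(2.2),
    diabetes                = log(2.1),
    alcohol_abuse           = log(2.1),
    cancer                  = log(2.5),
    psychiatric_disease     = log(4.7),
    atrial_fibrillation     = log(3.2),
    fev1_pct                = log(0.976),
    qtc_ms                  = log(1.0093),
    age_asthma_onset        = log(0.93),
    bmi                     = log(1.05)
  )
  miss <- list()
  mcar <- c(qtc_ms = 0.04, qrs_axis = 0.04, qrs_ms = 0.04,
            dlco_pct = 0.07, rv_pct = 0.07,
            fev1_postbd_pct = 0.04, fvc_postbd_pct = 0.04, fev1_fvc_postbd = 0.04,
            arterial_o2 = 0.06, arterial_co2 = 0.06,
            bmi_change = 0.04, pack_years = 0.03)
  for (nm in names(mcar))
    miss[[length(miss) + 1L]] <- list(predictor = nm, mechanism = "MCAR",
                                      rate = unname(mcar[nm]), depends_on = NULL)
  cohort_spec(n_patients, preds, effects = effects,
              baseline_log_odds = stats::qlogis(target_prevalence %||% 0.287),
              target_prevalence = target_prevalence,
              missingness = miss, seed = seed)
}

# ---- cohort table ----------------------------------------------------------

#' Construct a typed cohort table
#'
#' A `cohort_table` is a data.frame of predictors plus a mandatory integer
#' `outcome` column (0/1, never missing), together with the schema that fixes
#' each column's kind and category levels. Missing predictor cells are `NA`.
#'
#' @param data data.frame with one row per patient.
#' @param schema named list of per-column entries with fields `kind` and,
#'   for non-continuous columns, `levels` (a [predictor_spec()] works).
#' @return A `cohort_table` object (list with elements `data` and `schema`).
#' @export
cohort_table <- function(data, schema) {
  if (!"outcome" %in% names(data)) stop_nbc("cohort table must contain an 'outcome' column")
  y <- data$outcome
  if (anyNA(y)) stop_nbc("outcome column may not contain missing values")
  if (!all(y %in% c(0L, 1L))) stop_nbc("outcome must be coded 0/1")
  data$outcome <- as.integer(y)
  extra <- setdiff(setdiff(names(data), "outcome"), names(schema))
  if (length(extra)) stop_nbc("columns missing from schema: %s", paste(extra, collapse = ", "))
  for (nm in setdiff(names(data), "outcome")) {
    sc <- schema[[nm]]
    v <- data[[nm]]
    if (sc$kind == "continuous") {
      if (!is.numeric(v)) stop_nbc("column '%s' declared continuous but is not numeric", nm)
    } else {
      v <- as.character(v)
      bad <- which(!is.na(v) & !v %in% sc$levels)
      if (length(bad))
        stop_nbc("value '%s' at row %d, column '%s' not in declared levels {%s}",
                 v[bad[1]], bad[1], nm, paste(sc$levels, collapse = ", "))
      data[[nm]] <- v
    }
  }
  structure(list(data = data, schema = schema), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  kinds <- table(vapply(x$schema[predictor_names(x)], `[[`, "", "kind"))
  cat(sprintf("cohort_table: %d patients x %d predictors (%s); outcome prevalence %.3f; %.1f%% cells missing\n",
              nrow(x$data), length(predictor_names(x)),
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", "),
              mean(x$data$outcome),
              100 * mean(is.na(x$data[predictor_names(x)]))))
  invisible(x)
}

#' Predictor column names of a cohort table
#' @param table a [cohort_table()].
#' @return Character vector in schema (declaration) order.
#' @export
predictor_names <- function(table) {
  intersect(names(table$schema), setdiff(names(table$data), "outcome"))
}

#' Subset rows of a cohort table
#' @param table a [cohort_table()].
#' @param i row index vector.
#' @return A `cohort_table` with the selected rows, schema unchanged.
#' @export
cohort_rows <- function(table, i) {
  structure(list(data = table$data[i, , drop = FALSE], schema = table$schema),
            class = "cohort_table")
}

# ---- generation ------------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws predictors column-by-column (one child RNG stream per column in
#' declaration order, so results do not depend on evaluation order), draws
#' the outcome from the planted logistic model, and (by default) applies the
#' spec's missingness. Deterministic given `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param spec a [cohort_spec()].
#' @param seed root seed (defaults to `spec$seed`).
#' @param missingness apply the spec's missingness entries (default `TRUE`).
#' @return A [cohort_table()]. The intercept actually used is stored in
#'   `attr(, "baseline_log_odds")`.
#' @export
generate_cohort <- function(spec, seed = spec$seed, missingness = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  nms <- names(spec$predictors)
  cols <- vector("list", length(nms))
  names(cols) <- nms
  lat <- matrix(0, nrow = n, ncol = length(nms), dimnames = list(NULL, nms))
  for (j in seq_along(nms)) {
    p <- spec$predictors[[j]]
    v <- with_seed(child_seed(seed, j), draw_predictor(p, n))
    cols[[j]] <- v$column
    lat[, j] <- v$latent
  }
  eta <- rep(spec$baseline_log_odds, n)
  if (length(spec$effects) && n > 0) {
    for (nm in names(spec$effects)) {
      p <- spec$predictors[[nm]]
      x <- lat[, nm]
      if (p$kind == "continuous") x <- x - continuous_mean(p)
      eta <- eta + spec$effects[[nm]] * x
    }
  }
  b0 <- spec$baseline_log_odds
  if (!is.null(spec$target_prevalence) && n > 0) {
    eta0 <- eta - spec$baseline_log_odds
    f <- function(b) mean(stats::plogis(b + eta0)) - spec$target_prevalence
    b0 <- stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
    eta <- b0 + eta0
  }
  y <- with_seed(child_seed(seed, 0L),
                 if (n > 0) stats::rbinom(n, 1L, stats::plogis(eta)) else integer(0))
  df <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  if (n == 0) df <- as.data.frame(lapply(cols, `[`, integer(0)), optional = TRUE)
  df$outcome <- y
  tab <- cohort_table(df, spec$predictors)
  attr(tab, "baseline_log_odds") <- b0
  if (missingness && length(spec$missingness))
    tab <- inject_missingness(tab, spec, seed = seed)
  tab
}

draw_predictor <- function(p, n) {
  if (n == 0) {
    col <- if (p$kind == "continuous") numeric(0) else character(0)
    return(list(column = col, latent = numeric(0)))
  }
  switch(p$kind,
    binary = {
      x <- stats::rbinom(n, 1L, p$prevalence)
      list(column = as.character(x), latent = as.numeric(x))
    },
    categorical = {
      x <- sample(p$levels, n, replace = TRUE, prob = p$probs)
      list(column = x, latent = as.numeric(match(x, p$levels)))
    },
    continuous = {
      x <- if (p$dist == "lognormal") {
        s2 <- log(1 + (p$sd / p$mean)^2)
        stats::rlnorm(n, meanlog = log(p$mean) - s2 / 2, sdlog = sqrt(s2))
      } else stats::rnorm(n, p$mean, p$sd)
      list(column = x, latent = x)
    })
}

continuous_mean <- function(p) p$mean  # both marginals are parameterised by their natural-scale mean

#' Inject missing values into a cohort table
#'
#' Applies the spec's missingness entries: MCAR cells are independent
#' Bernoulli(rate); MAR cells are Bernoulli with a per-row rate modulated on
#' the logit scale by a named observed covariate (standardised, unit slope).
#' The outcome column is never touched.
#'
#' @param table a [cohort_table()].
#' @param spec the [cohort_spec()] carrying `missingness`.
#' @param seed root seed (defaults to `spec$seed`); one child stream per
#'   missingness entry.
#' @return The table with `NA` holes added.
#' @export
inject_missingness <- function(table, spec, seed = spec$seed) {
  n <- nrow(table$data)
  for (j in seq_along(spec$missingness)) {
    m <- spec$missingness[[j]]
    if (m$rate < 0 || m$rate > 1) stop_nbc("missingness rate outside [0,1]")
    if (n == 0) next
    rate <- if (identical(m$mechanism, "MCAR") || is.null(m$depends_on)) {
      rep(m$rate, n)
    } else {
      z <- table$data[[m$depends_on]]
      if (is.null(z)) stop_nbc("MAR covariate '%s' not in table", m$depends_on)
      z <- as.numeric(if (is.character(z)) match(z, spec$predictors[[m$depends_on]]$levels) else z)
      z[is.na(z)] <- mean(z, na.rm = TRUE)
      zs <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
      stats::plogis(stats::qlogis(pmin(pmax(m$rate, 1e-12), 1 - 1e-12)) + zs)
    }
    if (m$rate == 0) next
    hole <- if (m$rate == 1) rep(TRUE, n) else
      with_seed(child_seed(seed, 10000L + j), stats::runif(n) < rate)
    table$data[[m$predictor]][hole] <- NA
  }
  table
}

#' Complete-case fractions for sets of variables
#'
#' For each variable set, the fraction of rows in which every listed
#' variable is observed — the rows a complete-case analysis of that set
#' would keep.
#'
#' @param table a [cohort_table()].
#' @param variable_sets list of character vectors of predictor names.
#' @return Numeric vector of fractions in `[0, 1]`, one per set.
#' @export
attrition_profile <- function(table, variable_sets) {
  vapply(variable_sets, function(vars) {
    bad <- setdiff(vars, predictor_names(table))
    if (length(bad)) stop_nbc("unknown variable(s): %s", paste(bad, collapse = ", "))
    if (!length(vars)) return(1)
    mean(stats::complete.cases(table$data[, vars, drop = FALSE]))
  }, numeric(1))
}
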