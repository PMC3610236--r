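# Small in-code fixtures shared across test files.

# categorical/binary table built directly from vectors (already "discretized")
toy_table <- function(..., outcome) {
  cols <- list(...)
  schema <- lapply(cols, function(v) {
    lv <- sort(unique(as.character(v[!is.na(v)])))
    if (identical(lv, c("0", "1"))) list(kind = "binary", levels = c("0", "1"))
    else list(kind = "categorical", levels = lv)
  })
  df <- as.data.frame(lapply(cols, as.character), optional = TRUE,
                      stringsAsFactors = FALSE)
  df$outcome <- as.integer(outcome)
  cohort_table(df, schema)
}

# cohort spec with a handful of named predictors, for fast simulations
small_spec <- function(n = 500, effects = c(x1 = log(3)), prevalence = 0.3,
                       n_noise = 5, seed = 1L) {
  preds <- list(predictor_spec("x1", "binary", prevalence = 0.3))
  for (i in seq_len(n_noise))
    preds[[length(preds) + 1L]] <- predictor_spec(paste0("z", i), "binary", prevalence = 0.4)
  cohort_spec(n, preds, effects = effects, target_prevalence = prevalence, seed = seed)
}

# brute-force Bayes posterior by summing the enumerated joint distribution of
# an NBC model over binary predictors; unobserved predictors are marginalised
brute_force_posterior <- function(model, record) {
  vars <- model$vars
  obs <- vars[!vapply(vars, function(v) is.na(record[[v]] %||% NA), logical(1))]
  free <- setdiff(vars, obs)
  grid <- if (length(free)) {
    do.call(expand.grid, c(stats::setNames(lapply(free, function(v) model$levels[[v]]), free),
                           stringsAsFactors = FALSE))
  } else data.frame(row.names = 1)
  joint <- c(`0` = 0, `1` = 0)
  for (cls in c("0", "1")) {
    pc <- if (cls == "1") model$prior else 1 - model$prior
    tot <- 0
    for (g in seq_len(max(1, nrow(grid)))) {
      p <- pc
      for (v in vars) {
        val <- if (v %in% obs) as.character(record[[v]]) else as.character(grid[g, v])
        p <- p * nbc_cond_prob(model, v)[val, cls]
      }
      tot <- tot + p
    }
    joint[cls] <- tot
  }
  unname(joint["1"] / sum(joint))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
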