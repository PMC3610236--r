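test_that("partitions have the configured sizes, are disjoint, and are seed-deterministic", {
  sch <- make_partitions(738, n_splits = 10, train_n = 538, test_n = 200, seed = 4)
  expect_length(sch$splits, 10)
  for (sp in sch$splits) {
    expect_length(sp$train, 538)
    expect_length(sp$test, 200)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_true(all(c(sp$train, sp$test) %in% 1:738))
  }
  expect_identical(make_partitions(738, seed = 4), sch)
  expect_false(identical(make_partitions(738, seed = 5)$splits, sch$splits))
  expect_error(make_partitions(700, train_n = 538, test_n = 200), "exceeds")
})

test_that("row coverage across splits matches the sampling probability", {
  # P(a row is in >= 1 of 10 independent splits) = 1 - (1 - 738/738 * 738ths)...
  n <- 200; m <- 150; k <- 8
  p_one <- m / n
  p_any <- 1 - (1 - p_one)^k
  set.seed(1)
  cover <- replicate(400, {
    sch <- make_partitions(n, n_splits = k, train_n = 100, test_n = 50,
                           seed = sample.int(1e6, 1))
    used <- unique(unlist(lapply(sch$splits, function(s) c(s$train, s$test))))
    length(used) / n
  })
  expect_lt(abs(mean(cover) - p_any), 0.05)
})

test_that("presence-matrix row sums equal consensus counts; thresholds behave", {
  spec <- default_cohort_spec(n_patients = 260)
  tab <- generate_cohort(spec, seed = 10)
  sch <- make_partitions(260, n_splits = 4, train_n = 180, test_n = 60, seed = 10)
  ens <- run_ensemble(tab, sch)
  expect_equal(rowSums(ens$presence), ens$consensus_counts)
  all_sel <- consensus_variables(ens, min_models = 1)
  expect_setequal(all_sel, unique(unlist(lapply(ens$splits, `[[`, "selected"))))
  expect_length(consensus_variables(ens, min_models = ens$scheme$n_splits + 1), 0)
  expect_error(consensus_variables(ens, min_models = 0), "min_models")
})

test_that("the published-style presence matrix yields the >=4-of-10 consensus set", {
  f <- system.file("extdata", "presence_matrix_published.csv", package = "nbcmerge")
  pm <- read.csv(f)
  counts <- rowSums(pm[, paste0("split", 1:10)])
  expected <- pm$variable[counts >= 4]  # counting oracle on the fixture
  ens <- list(consensus_counts = setNames(counts, pm$variable))
  expect_setequal(consensus_variables(structure(ens, class = "ensemble_result"), 4), expected)
  expect_length(expected, 13)
  expect_true(all(c("alcohol_abuse", "psychiatric_disease", "cancer",
                    "diabetes", "cerebrovascular_disease", "atrial_fibrillation",
                    "qtc_ms", "fev1_pct", "bmi") %in% expected))
})

test_that("ensemble on pure-noise predictors stays near the majority-class rate", {
  accs <- vapply(1:20, function(s) {
    spec <- small_spec(n = 260, effects = numeric(0), prevalence = 0.3,
                       n_noise = 7, seed = s)
    tab <- generate_cohort(spec, seed = s)
    sch <- make_partitions(260, n_splits = 4, train_n = 180, test_n = 60, seed = s)
    ens <- run_ensemble(tab, sch)
    maj <- 100 * max(mean(tab$data$outcome), 1 - mean(tab$data$outcome))
    ens$aggregate$mean[ens$aggregate$metric == "accuracy"] - maj
  }, numeric(1))
  expect_lt(abs(mean(accs)), 5)
})

test_that("no test-set leakage: corrupting test rows leaves the per-split models unchanged", {
  spec <- default_cohort_spec(n_patients = 300)
  tab <- generate_cohort(spec, seed = 6)
  sch <- make_partitions(300, n_splits = 3, train_n = 200, test_n = 80, seed = 6)
  ens <- run_ensemble(tab, sch)
  for (s in seq_along(sch$splits)) {
    corrupt <- tab
    test_rows <- sch$splits[[s]]$test
    for (nm in predictor_names(tab)) {
      v <- corrupt$data[[nm]]
      sc <- corrupt$schema[[nm]]
      v[test_rows] <- if (sc$kind == "continuous") 1e6 else sc$levels[1]
      corrupt$data[[nm]] <- v
    }
    one <- sch
    one$n_splits <- 1L
    one$splits <- sch$splits[s]
    ens2 <- run_ensemble(corrupt, one)
    expect_identical(ens2$splits[[1]]$selected, ens$splits[[s]]$selected)
    expect_identical(ens2$splits[[1]]$model, ens$splits[[s]]$model)
    expect_identical(ens2$splits[[1]]$map, ens$splits[[s]]$map)
  }
})

test_that("fit_final honours its contract: subset of candidates, perfect predictor wins", {
  y <- rep(c(0L, 1L), c(70, 30))
  df <- data.frame(copy = as.character(y), junk = rep(c("0", "1"), 50), outcome = y)
  tab <- cohort_table(df, list(copy = list(kind = "binary", levels = c("0", "1")),
                               junk = list(kind = "binary", levels = c("0", "1"))))
  # a perfect predictor drives single-factor posteriors to the 0/1 boundary,
  # which the evidence table flags with degenerate-odds warnings
  fin <- suppressWarnings(fit_final(tab, c("copy", "junk"), alpha = 0))
  expect_true(all(fin$selected %in% c("copy", "junk")))
  expect_true("copy" %in% fin$selected)
  expect_equal(fin$diagnostics$accuracy, 100)
  expect_error(fit_final(tab, character(0)), "empty")
})

test_that("the whole pipeline is deterministic given the root seed", {
  spec <- default_cohort_spec(n_patients = 300)
  tab <- generate_cohort(spec, seed = 2)
  r1 <- nbcmm(tab, seed = 11, n_splits = 3, train_n = 200, test_n = 80, min_models = 2)
  r2 <- nbcmm(tab, seed = 11, n_splits = 3, train_n = 200, test_n = 80, min_models = 2)
  expect_identical(r1$final$selected, r2$final$selected)
  expect_identical(r1$final$po_table, r2$final$po_table)
  expect_identical(r1$ensemble$presence, r2$ensemble$presence)
})
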