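test_that("empty cohort keeps the full schema", {
  spec <- default_cohort_spec(n_patients = 0)
  tab <- generate_cohort(spec, seed = 1)
  expect_equal(nrow(tab$data), 0)
  expect_setequal(names(tab$data), c(names(spec$predictors), "outcome"))
  expect_length(predictor_names(tab), 49)
})

test_that("default spec has 49 predictors of mixed kinds", {
  spec <- default_cohort_spec()
  expect_length(spec$predictors, 49)
  kinds <- vapply(spec$predictors, `[[`, "", "kind")
  expect_true(all(c("binary", "categorical", "continuous") %in% kinds))
  tab <- generate_cohort(spec, seed = 3)
  expect_length(predictor_names(tab), 49)
})

test_that("observed prevalence lies in the exact binomial 99% interval of the target", {
  spec <- default_cohort_spec()
  # exact binomial oracle bounds for n = 738, p = 0.287
  lo <- qbinom(0.005, 738, 0.287) / 738
  hi <- qbinom(0.995, 738, 0.287) / 738
  for (s in c(11, 42, 99)) {
    prev <- mean(generate_cohort(spec, seed = s)$data$outcome)
    expect_gte(prev, lo)
    expect_lte(prev, hi)
  }
})

test_that("generation is deterministic given seed, bitwise on the stored CSV", {
  spec <- default_cohort_spec()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(spec, seed = 7), f1)
  write_cohort(generate_cohort(spec, seed = 7), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  # and a different seed gives a different table
  write_cohort(generate_cohort(spec, seed = 8), f2)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f2, "raw", file.size(f2))))
})

test_that("unknown predictor in planted effects is a configuration error", {
  preds <- list(predictor_spec("a", "binary", prevalence = 0.5))
  expect_error(cohort_spec(10, preds, effects = c(nope = 1)), "unknown predictor")
  expect_error(cohort_spec(10, c(preds, preds)), "duplicate")
})

test_that("missingness: identity at rate 0, saturation at rate 1, MCAR rate respected", {
  spec <- small_spec(n = 10000, n_noise = 2)
  tab <- generate_cohort(spec, seed = 5, missingness = FALSE)

  spec0 <- spec
  spec0$missingness <- list(list(predictor = "x1", mechanism = "MCAR", rate = 0))
  expect_identical(inject_missingness(tab, spec0, seed = 5)$data, tab$data)

  spec1 <- spec
  spec1$missingness <- list(list(predictor = "z1", mechanism = "MCAR", rate = 1))
  expect_true(all(is.na(inject_missingness(tab, spec1, seed = 5)$data$z1)))

  spec2 <- spec
  spec2$missingness <- list(list(predictor = "z2", mechanism = "MCAR", rate = 0.2))
  out <- inject_missingness(tab, spec2, seed = 5)
  frac <- mean(is.na(out$data$z2))
  expect_gte(frac, 0.18)  # binomial 99.9% bound at n = 10000
  expect_lte(frac, 0.22)
  expect_false(anyNA(out$data$outcome))

  spec3 <- spec
  spec3$missingness <- list(list(predictor = "z1", mechanism = "MCAR", rate = 1.7))
  expect_error(inject_missingness(tab, spec3, seed = 1), "rate")
})

test_that("MAR missingness depends on the named covariate", {
  preds <- list(predictor_spec("sev", "continuous", mean = 0, sd = 1),
                predictor_spec("meas", "continuous", mean = 10, sd = 2))
  spec <- cohort_spec(8000, preds, baseline_log_odds = -1,
                      missingness = list(list(predictor = "meas", mechanism = "MAR",
                                              rate = 0.3, depends_on = "sev")))
  tab <- generate_cohort(spec, seed = 2)
  hi <- tab$data$sev > 0
  expect_gt(mean(is.na(tab$data$meas[hi])), mean(is.na(tab$data$meas[!hi])))
})

test_that("attrition profile: trivial cases and default calibration", {
  spec <- default_cohort_spec()
  tab <- generate_cohort(spec, seed = 42)
  expect_equal(attrition_profile(tab, list(character(0))), 1.0)
  fully <- c("diabetes", "cancer", "hypertension")  # no missingness entries
  expect_equal(attrition_profile(tab, list(fully)), 1.0)
  expect_error(attrition_profile(tab, list("not_a_column")), "unknown variable")
  # full 49-variable complete-case fraction matches the calibrated attrition
  frac <- attrition_profile(tab, list(predictor_names(tab)))
  expect_gte(frac, 0.50)
  expect_lte(frac, 0.62)
})

test_that("logistic regression recovers planted coefficients (Wald coverage)", {
  eff <- c(x1 = log(2.2), c1 = log(1.04))
  preds <- list(predictor_spec("x1", "binary", prevalence = 0.3),
                predictor_spec("z1", "binary", prevalence = 0.5),
                predictor_spec("c1", "continuous", mean = 50, sd = 15),
                predictor_spec("c2", "continuous", mean = 0, sd = 1))
  spec <- cohort_spec(10000, preds, effects = eff, target_prevalence = 0.3)
  hits <- matrix(FALSE, 50, length(eff), dimnames = list(NULL, names(eff)))
  for (r in 1:50) {
    tab <- generate_cohort(spec, seed = 100 + r)
    df <- tab$data
    df$x1 <- as.numeric(df$x1 == "1"); df$z1 <- as.numeric(df$z1 == "1")
    fit <- glm(outcome ~ x1 + z1 + c1 + c2, family = binomial(), data = df)
    sm <- summary(fit)$coefficients
    for (nm in names(eff)) {
      ci <- sm[nm, 1] + c(-1.96, 1.96) * sm[nm, 2]
      hits[r, nm] <- eff[nm] >= ci[1] && eff[nm] <= ci[2]
    }
  }
  expect_true(all(colMeans(hits) >= 0.90))
})

test_that("expected prevalence is monotone in the baseline log-odds", {
  preds <- list(predictor_spec("x1", "binary", prevalence = 0.3),
                predictor_spec("c1", "continuous", mean = 0, sd = 1))
  prev <- vapply(c(-2, -1, 0, 1), function(b0) {
    spec <- cohort_spec(4000, preds, effects = c(x1 = 1, c1 = 0.5),
                        baseline_log_odds = b0)
    tab <- generate_cohort(spec, seed = 9)
    # compare expected probabilities, not sampling noise: reconstruct eta
    x <- as.numeric(tab$data$x1 == "1"); z <- tab$data$c1
    mean(plogis(b0 + 1 * x + 0.5 * z))
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})
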