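test_that("conditional tables are plain frequencies at alpha = 0 and smooth correctly", {
  # (class+, x=1) = 8 of 10; (class-, x=1) = 2 of 10
  x <- c(rep("1", 8), rep("0", 2), rep("1", 2), rep("0", 8))
  y <- c(rep(1L, 10), rep(0L, 10))
  tab <- toy_table(x = x, outcome = y)
  m0 <- fit_nbc(tab, "x", alpha = 0)
  pr <- nbc_cond_prob(m0, "x")
  expect_equal(pr["1", "1"], 0.8)
  expect_equal(pr["1", "0"], 0.2)
  # alpha = 0.5, zero count in a 2-category cell with class count 10
  x2 <- c(rep("1", 10), rep("0", 5), rep("1", 5))
  tab2 <- toy_table(x = x2, outcome = y)
  pr2 <- nbc_cond_prob(fit_nbc(tab2, "x", alpha = 0.5), "x")
  expect_equal(pr2["0", "1"], 0.5 / 11)
  # normalisation: per class, probabilities over categories sum to 1
  for (m in list(m0, fit_nbc(tab2, "x", alpha = 0.5)))
    expect_equal(colSums(nbc_cond_prob(m, "x")), c(`0` = 1, `1` = 1), tolerance = 1e-12)
})

test_that("single-class training outcome and continuous predictors are rejected", {
  expect_error(fit_nbc(toy_table(x = c("0", "1", "0"), outcome = c(1L, 1L, 1L)), "x"),
               "single class")
  df <- data.frame(v = c(1.2, 3.4), outcome = 0:1)
  tab <- cohort_table(df, list(v = list(kind = "continuous")))
  expect_error(fit_nbc(tab, "v"), "continuous")
})

test_that("a record with no observed evidence scores the class prior", {
  set.seed(1)
  tab <- toy_table(a = sample(c("0", "1"), 40, TRUE),
                   b = sample(c("0", "1"), 40, TRUE),
                   outcome = rbinom(40, 1, 0.3))
  m <- fit_nbc(tab, c("a", "b"))
  expect_equal(predict_posterior(m, list(a = NA, b = NA)), m$prior)
  # uniform conditional tables are equally uninformative
  m$tables$a[] <- 5; m$tables$b[] <- 5
  expect_equal(predict_posterior(m, list(a = "1", b = "0")), m$prior, tolerance = 1e-12)
})

test_that("posterior equals brute-force Bayes on the enumerated joint table", {
  set.seed(42)
  n <- 200
  tab <- toy_table(a = sample(c("0", "1"), n, TRUE, prob = c(0.3, 0.7)),
                   b = sample(c("0", "1"), n, TRUE),
                   c = sample(c("0", "1"), n, TRUE, prob = c(0.6, 0.4)),
                   outcome = rbinom(n, 1, 0.35))
  m <- fit_nbc(tab, c("a", "b", "c"), alpha = 0.5)
  grid <- expand.grid(a = c("0", "1"), b = c("0", "1"), c = c("0", "1"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    rec <- as.list(grid[i, ])
    expect_equal(predict_posterior(m, rec), brute_force_posterior(m, rec),
                 tolerance = 1e-10)
  }
  # factor-skipping equals marginalising the unobserved predictor out of the joint
  for (rec in list(list(a = "1", b = NA, c = "0"), list(a = NA, b = NA, c = "1")))
    expect_equal(predict_posterior(m, rec), brute_force_posterior(m, rec),
                 tolerance = 1e-10)
})

test_that("posterior is invariant to predictor order and to class-identical predictors", {
  set.seed(3)
  n <- 100
  tab <- toy_table(a = sample(c("0", "1"), n, TRUE), b = sample(c("x", "y", "z"), n, TRUE),
                   outcome = rbinom(n, 1, 0.4))
  m_ab <- fit_nbc(tab, c("a", "b"))
  m_ba <- fit_nbc(tab, c("b", "a"))
  rows <- tab$data[1:20, ]
  expect_equal(predict_posterior(m_ab, rows), predict_posterior(m_ba, rows), tolerance = 1e-12)
  # a predictor with identical conditional tables across classes changes nothing
  m3 <- fit_nbc(tab, c("a", "b"))
  m3$vars <- c(m3$vars, "d")
  m3$levels$d <- c("0", "1")
  m3$tables$d <- matrix(c(7, 3, 7, 3), 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  rows$d <- sample(c("0", "1"), 20, TRUE)
  expect_equal(predict_posterior(m3, rows), predict_posterior(m_ab, rows), tolerance = 1e-12)
})

test_that("unseen categories warn and act as missing", {
  tab <- toy_table(a = c("0", "1", "0", "1"), outcome = c(0L, 1L, 0L, 1L))
  m <- fit_nbc(tab, "a")
  expect_warning(p <- predict_posterior(m, list(a = "surprise")), "treated as missing")
  expect_equal(p, m$prior)
})

test_that("classification thresholds and tie-breaking are deterministic", {
  tab <- toy_table(a = rep(c("0", "1"), c(30, 12)), outcome = rep(c(0L, 1L), c(30, 12)))
  m <- fit_nbc(tab, "a")
  expect_equal(classify(m, posterior = 0.51), 1L)
  expect_equal(classify(m, posterior = 0.49), 0L)
  expect_equal(classify(m, posterior = 0.5), 0L)       # tie -> majority (negative) class
  expect_equal(classify(m, posterior = 0.5, threshold = 0.49), 1L)
  # raising the threshold never converts a negative call to positive
  post <- seq(0.01, 0.99, by = 0.01)
  calls <- sapply(c(0.2, 0.4, 0.6, 0.8), function(th) classify(m, posterior = post, threshold = th))
  expect_true(all(diff(t(calls)) <= 0))
  expect_error(classify(m, posterior = 0.5, threshold = 1), "threshold")
})

test_that("LOOCV matches brute-force leave-one-out refits on a small table", {
  set.seed(9)
  n <- 40
  tab <- toy_table(a = sample(c("0", "1"), n, TRUE),
                   b = sample(c("x", "y", "z"), n, TRUE),
                   outcome = rbinom(n, 1, 0.4))
  tab$data$a[c(3, 17)] <- NA
  for (alpha in c(0.5, 1)) {
    rep <- loocv(tab, c("a", "b"), alpha = alpha)
    post <- vapply(seq_len(n), function(i) {
      m <- fit_nbc(cohort_rows(tab, setdiff(seq_len(n), i)), c("a", "b"), alpha = alpha)
      predict_posterior(m, cohort_rows(tab, i))
    }, numeric(1))
    expect_equal(rep$posterior, post, tolerance = 1e-12)
    p_true <- ifelse(tab$data$outcome == 1, post, 1 - post)
    expect_equal(rep$log_score, mean(-log(p_true)), tolerance = 1e-12)
  }
})

test_that("LOOCV on a perfect predictor is 100% accurate; default score is the majority class", {
  y <- rep(c(0L, 1L), c(18, 7))   # 72% majority
  tab <- toy_table(mirror = as.character(y), outcome = y)
  rep <- loocv(tab, "mirror", alpha = 0)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$default_accuracy, 72.0)
  expect_equal(rep$default_log_score, mean(-log(ifelse(y == 1, 0.28, 0.72))))
})

test_that("model export: JSON round-trips the tables and DOT is a star on the predictors", {
  tab <- toy_table(a = c("0", "1", "0", "1"), b = c("1", "1", "0", "0"),
                   outcome = c(0L, 1L, 0L, 1L))
  m <- fit_nbc(tab, c("a", "b"))
  js <- jsonlite::fromJSON(write_nbc_model(m))
  expect_equal(js$prior, m$prior)
  expect_equal(js$vars, c("a", "b"))
  dot <- nbc_to_dot(m)
  expect_match(dot, "digraph")
  expect_match(dot, "\"outcome\" -> \"a\"", fixed = TRUE)
  expect_match(dot, "\"outcome\" -> \"b\"", fixed = TRUE)
})
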