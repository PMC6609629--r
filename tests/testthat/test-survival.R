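test_that("median dichotomization sends ties and the witness to low", {
  m <- make_expr(matrix(c(1, 2, 3, 4), 1, 4), genes = "G1")
  g <- dichotomize_expression(m, "G1")
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  # odd n: the median witness goes low
  m2 <- make_expr(matrix(c(1, 2, 3, 4, 5), 1, 5), genes = "G1")
  g2 <- dichotomize_expression(m2, "G1")
  expect_equal(as.character(g2[3]), "low")
  expect_equal(unname(abs(diff(as.vector(attr(g2, "sizes"))))), 1)
  expect_error(dichotomize_expression(make_expr(matrix(1, 1, 4), genes = "G1"),
                                      "G1"), "constant")
})

test_that("Kaplan-Meier estimates match hand product-limit computation", {
  # single subject with an event at 5
  km1 <- km_estimate(5, 1)
  expect_equal(km1$survival, 0)
  expect_equal(km1$time, 5)
  # events at 1 and 2, censor at 3: S(1) = 2/3, S(2) = 1/3
  km2 <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km2$survival[km2$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km2$survival[km2$time == 2], 1 / 3, tolerance = 1e-12)
  # all censored: survival stays 1
  km3 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km3$survival == 1))
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("uncensored Kaplan-Meier equals one minus the empirical CDF", {
  set.seed(41)
  t <- round(rexp(30, 0.2), 2)
  km <- km_estimate(t, rep(1, 30))
  for (i in seq_len(nrow(km))) {
    expect_equal(km$survival[i], mean(t > km$time[i]), tolerance = 1e-12)
  }
})

test_that("log-rank equals brute-force O-E accumulation on small instances", {
  set.seed(63)
  for (i in 1:15) {
    n <- sample(6:20, 1)
    time <- sample(1:8, n, replace = TRUE)        # ties included
    event <- rbinom(n, 1, 0.7)
    group <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    if (sum(event[group == "a"]) == 0 && sum(event[group == "b"]) == 0) next
    res <- log_rank_test(time, event, group)
    expect_equal(res$chi_square, logrank_by_accumulation(time, event, group),
                 tolerance = 1e-9)
    expect_equal(res$df, 1)
  }
})

test_that("log-rank detects a planted hazard ratio of 3 and ignores mirrored groups", {
  set.seed(11)
  n <- 200
  group <- rep(c("low", "high"), each = n / 2)
  time <- c(rexp(n / 2, 0.1), rexp(n / 2, 0.3))
  res <- log_rank_test(time, rep(1, n), group)
  expect_lt(res$p_value, 0.001)

  # identical mirrored event patterns: no signal
  res0 <- log_rank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                        rep(c("a", "b"), each = 3))
  expect_equal(res0$chi_square, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  expect_error(log_rank_test(1:3, c(1, 1, 1), rep("a", 3)), "2 groups")
})

test_that("Cox fit recovers a planted binary effect inside its own CI", {
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    x <- rbinom(400, 1, 0.5)
    time <- rexp(400, 0.1 * exp(0.7 * x))
    fit <- cox_fit(time, rep(1, 400), data.frame(x = x))
    fit$table$ci_lower[1] <= exp(0.7) && exp(0.7) <= fit$table$ci_upper[1]
  })
  expect_gte(sum(hits), 9)
})

test_that("Cox on a null covariate gives HR near 1 and matches the coxph surface", {
  set.seed(29)
  x <- rnorm(300)
  time <- rexp(300, 0.1)
  fit <- cox_fit(time, rbinom(300, 1, 0.8), data.frame(x = x))
  expect_lt(abs(fit$table$hr[1] - 1), 0.3)
  expect_equal(fit$table$hr, exp(fit$table$beta))
  expect_error(cox_fit(time, rep(1, 300), data.frame(x = rep(2, 300))),
               "constant")
})

test_that("Cox score test at beta = 0 equals the log-rank chi-square (tie-free)", {
  set.seed(83)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(0.5 * x))   # continuous: no ties
  event <- rbinom(n, 1, 0.8)
  fit <- cox_fit(time, event, data.frame(x = x))
  lr <- log_rank_test(time, event, x)
  expect_equal(fit$score_test, lr$chi_square, tolerance = 1e-6)
})

test_that("backward selection keeps planted effects and empties a null model", {
  recovered <- sapply(1:10, function(s) {
    set.seed(500 + s)
    n <- 500
    z <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
    time <- rexp(n, 0.05 * exp(0.6 * z[, 1] + 0.6 * z[, 2]))
    sel <- cox_backward_select(time, rep(1, n), as.data.frame(z),
                               alpha = 0.05)
    all(c("c1", "c2") %in% sel$selected)
  })
  expect_gte(sum(recovered), 8)

  emptied <- sapply(1:10, function(s) {
    set.seed(600 + s)
    n <- 300
    z <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("c", 1:4)))
    sel <- cox_backward_select(rexp(n, 0.1), rbinom(n, 1, 0.7),
                               as.data.frame(z), alpha = 0.05)
    length(sel$selected) == 0
  })
  expect_gte(sum(emptied), 6)

  # alpha = 1: nothing is ever removed
  set.seed(71)
  z <- data.frame(a = rnorm(100), b = rnorm(100))
  sel1 <- cox_backward_select(rexp(100, 0.1), rep(1, 100), z, alpha = 1)
  expect_setequal(sel1$selected, c("a", "b"))
  expect_null(sel1$removal_trace)

  # univariate prescreen drops covariates that never show marginal signal
  set.seed(72)
  n <- 400
  strong <- rnorm(n)
  time <- rexp(n, 0.05 * exp(0.8 * strong))
  sel2 <- cox_backward_select(time, rep(1, n),
                              data.frame(strong = strong, weak = rnorm(n)),
                              alpha = 0.05, univariate_alpha = 0.05)
  expect_true("strong" %in% sel2$selected)
  expect_false("weak" %in% sel2$selected)
})
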