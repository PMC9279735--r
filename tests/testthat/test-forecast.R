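test_that("the linear model reproduces exact trends and refuses short series", {
  # constant series: zero slope, all four predictions equal
  tr <- fit_predict(rep(20, 5))
  expect_equal(tr$predictions$pdp_sum, rep(20, 4))
  # exact line DP(f) = 19 + 0.3 f observed to f = 8: extrapolation is exact
  f <- 1:8
  tr2 <- fit_predict(19 + 0.3 * f)
  expect_equal(tr2$predictions$fraction, 9:12)
  expect_equal(tr2$predictions$pdp_sum, c(21.7, 22.0, 22.3, 22.6),
               tolerance = 1e-12)
  # fewer than five observations: refused with a reason code
  tr3 <- fit_predict(c(1, 2, 3, 4))
  expect_null(tr3$predictions)
  expect_equal(tr3$reason, "insufficient_fractions")
  expect_error(predict(tr3, 5), "insufficient")
})

test_that("OLS coefficients match the closed-form normal equations", {
  set.seed(77)
  f <- 1:10
  y <- 30 - 0.4 * f + rnorm(10, 0, 0.1)
  tr <- fit_predict(y)
  # independent oracle: 2x2 normal equations solved directly
  X <- cbind(1, f)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(tr$coefficients["intercept"]), beta[1], tolerance = 1e-9)
  expect_equal(unname(tr$coefficients["slope"]), beta[2], tolerance = 1e-9)
  expect_true(all(abs(tr$predictions$pdp_sum - (30 - 0.4 * (11:14))) < 0.3))
})

test_that("prediction is consistent under index shifts", {
  y <- c(5, 5.5, 6.4, 7.1, 7.8, 8.6)
  a <- fit_predict(y, fractions = 1:6)
  b <- fit_predict(y, fractions = 11:16)
  expect_equal(a$predictions$pdp_sum, b$predictions$pdp_sum, tolerance = 1e-10)
  expect_equal(b$predictions$fraction, 17:20)
})

test_that("prediction accuracy follows the anchored-difference definition", {
  # all series exactly linear through their crossing: differences vanish
  lin <- lapply(c(0.5, 0.8, 1.2), function(s)
    list(observed = 10 + s * (1:12), fx = 10L))
  acc <- eval_accuracy(lin)
  expect_equal(acc$mean_diff, rep(0, 4), tolerance = 1e-10)
  # a single series: plain arithmetic, no confidence interval
  one <- list(list(observed = c(20, 21, 22, 23, 24, 25.2, 26.9, 26.0), fx = 8L))
  acc1 <- eval_accuracy(one)
  a1 <- acc1[acc1$lookahead == 1, ]
  tr <- fit_predict(one[[1]]$observed[1:7])
  expect_equal(a1$mean_diff, predict(tr, 8) - 26.0, tolerance = 1e-10)
  expect_true(is.na(a1$ci95_half))
  # series crossing before fraction 5 are excluded entirely
  acc0 <- eval_accuracy(list(list(observed = 1:6, fx = 4L)))
  expect_equal(acc0$n, rep(0L, 4))
})

test_that("accuracy evaluation equals a brute-force recomputation on a cohort", {
  set.seed(55)
  cohort <- lapply(1:20, function(i) {
    k <- sample(10:16, 1)
    y <- 15 + runif(1, 0.3, 0.9) * (1:k) + rnorm(k, 0, 0.3)
    list(observed = y, fx = sample(7:k, 1))
  })
  acc <- eval_accuracy(cohort)
  # independent loop-based oracle
  for (i in 4:1) {
    diffs <- c()
    for (s in cohort) {
      if (s$fx < 5 || s$fx - i < 5) next
      anchor <- s$fx - i
      X <- cbind(1, seq_len(anchor))
      beta <- solve(t(X) %*% X, t(X) %*% s$observed[seq_len(anchor)])
      diffs <- c(diffs, beta[1] + beta[2] * s$fx - s$observed[s$fx])
    }
    row <- acc[acc$lookahead == i, ]
    expect_equal(row$n, length(diffs))
    expect_equal(row$mean_diff, mean(diffs), tolerance = 1e-10)
    expect_equal(row$ci95_half, qt(0.975, length(diffs) - 1) * sd(diffs) /
                   sqrt(length(diffs)), tolerance = 1e-10)
  }
})

test_that("predicted crossings locate the first violating forecast fraction", {
  spec <- rtflow:::endpoint_row("pg", "Dmean", "upper_bound", 20, 22, "Gy")
  tr <- fit_predict(c(14, 15, 16, 17, 18))  # slope 1: pdp = 19, 20, 21, 22
  expect_equal(predicted_crossing(tr, spec, "warning"), 8)   # first pdp > 20
  expect_true(is.na(predicted_crossing(tr, spec, "adaptation")))  # 22 not > 22
  tr2 <- fit_predict(c(15, 16, 17, 18, 19))
  expect_equal(predicted_crossing(tr2, spec, "adaptation"), 9)
  flat <- fit_predict(rep(15, 6))
  expect_true(is.na(predicted_crossing(flat, spec, "warning")))
})
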