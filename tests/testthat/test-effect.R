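test_that("single-trial log odds ratios match hand arithmetic", {
  # symmetric table -> null effect
  e <- trial_log_or(5, 10, 5, 10)
  expect_equal(e$log_or, 0)

  # 10/20 vs 5/20: OR = (10*15)/(10*5) = 3
  e <- trial_log_or(10, 20, 5, 20)
  expect_equal(e$log_or, log(3), tolerance = 1e-12)
  expect_equal(e$se, sqrt(1 / 10 + 1 / 10 + 1 / 5 + 1 / 15),
               tolerance = 1e-12)
  expect_equal(round(e$se, 4), 0.6831)

  # zero cell: 0.5 added to all four cells
  e <- trial_log_or(0, 10, 5, 10)
  expect_equal(e$log_or, log(0.5 * 5.5 / (10.5 * 5.5)), tolerance = 1e-12)
  expect_equal(round(e$log_or, 4), -3.0445)
  expect_equal(e$se, sqrt(1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5),
               tolerance = 1e-12)
  expect_equal(round(e$se, 4), 1.5681)
})

test_that("inestimable tables signal exclusion, invalid arms error", {
  expect_null(trial_log_or(0, 10, 0, 15))
  expect_null(trial_log_or(10, 10, 15, 15))
  expect_error(trial_log_or(0, 0, 5, 10), "at least 1")
  expect_error(trial_log_or(-1, 10, 5, 10))
})

test_that("log OR is antisymmetric under arm exchange, se invariant", {
  set.seed(11)
  for (i in 1:50) {
    t <- random_tables(1)
    a <- trial_log_or(t$r1, t$n1, t$r0, t$n0)
    b <- trial_log_or(t$r0, t$n0, t$r1, t$n1)
    if (is.null(a)) { expect_null(b); next }
    expect_equal(a$log_or, -b$log_or, tolerance = 1e-12)
    expect_equal(a$se, b$se, tolerance = 1e-12)
  }
})

test_that("pooling reproduces closed-form hand cases", {
  # single estimate is returned unchanged
  p <- pool(0.4, se = 0.2, method = "dl")
  expect_equal(p$log_or, 0.4)
  expect_equal(p$se, 0.2)
  expect_equal(p$Q, 0)
  expect_equal(p$tau2, 0)

  # equal weights -> mean, se = 1/sqrt(2)
  p <- pool(c(0, 2), se = c(1, 1), method = "fixed")
  expect_equal(p$log_or, 1)
  expect_equal(p$se, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(p$tau2, 0)

  # DerSimonian-Laird on the same input: Q = 2, C = 1, tau2 = 1
  p <- pool(c(0, 2), se = c(1, 1), method = "dl")
  expect_equal(p$Q, 2)
  expect_equal(p$tau2, 1)
  expect_equal(p$log_or, 1)
  expect_equal(p$se, 1, tolerance = 1e-12)

  expect_error(pool(list()), "no estimable")
  expect_error(pool(numeric(0), se = numeric(0)), "no estimable")
})

test_that("pooling properties hold on random inputs", {
  set.seed(22)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    y <- rnorm(k)
    s <- runif(k, 0.1, 1)
    f <- pool(y, se = s, method = "fixed")
    r <- pool(y, se = s, method = "dl")
    # pooled estimate within the range of the inputs
    expect_gte(f$log_or, min(y)); expect_lte(f$log_or, max(y))
    expect_gte(r$log_or, min(y)); expect_lte(r$log_or, max(y))
    # random-effects se is never smaller; methods coincide when Q <= k-1
    expect_gte(r$se, f$se - 1e-12)
    if (f$Q <= k - 1) {
      expect_equal(r$tau2, 0)
      expect_equal(r$log_or, f$log_or, tolerance = 1e-12)
      expect_equal(r$se, f$se, tolerance = 1e-12)
    }
    # CI invariant: recomputation from log_or and se
    expect_equal(r$ci_low, exp(r$log_or - 1.96 * r$se), tolerance = 1e-12)
    expect_equal(r$ci_high, exp(r$log_or + 1.96 * r$se), tolerance = 1e-12)
  }
})

test_that("DerSimonian-Laird pooling agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(33)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    y <- rnorm(k)
    s <- runif(k, 0.1, 1)
    r <- pool(y, se = s, method = "dl")
    m <- metafor::rma(yi = y, sei = s, method = "DL")
    expect_equal(r$log_or, as.numeric(m$beta), tolerance = 1e-8)
    expect_equal(r$se, m$se, tolerance = 1e-8)
    expect_equal(r$tau2, m$tau2, tolerance = 1e-8)
    f <- pool(y, se = s, method = "fixed")
    mf <- metafor::rma(yi = y, sei = s, method = "FE")
    expect_equal(f$log_or, as.numeric(mf$beta), tolerance = 1e-8)
    expect_equal(f$se, mf$se, tolerance = 1e-8)
  }
})

test_that("pooling refuses mixed orientations but accepts excluded trials", {
  e1 <- effect_estimate(0.2, 0.3, orientation = "BvA")
  e2 <- effect_estimate(0.5, 0.4, orientation = "CvA")
  expect_error(pool(list(e1, e2)), "mixed orientations")
  e3 <- effect_estimate(0.1, 0.2, orientation = "BvA")
  p <- pool(list(e1, NULL, e3), method = "fixed")
  expect_equal(p$k_trials, 2L)
})

test_that("pooled event rate is the aggregate proportion", {
  expect_equal(pooled_event_rate(48, 100), 0.48)
  expect_equal(pooled_event_rate(c(10, 20), c(50, 50)), 0.30)
  expect_error(pooled_event_rate(numeric(0), numeric(0)), "no arms")
  expect_error(pooled_event_rate(5, 4))
})
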