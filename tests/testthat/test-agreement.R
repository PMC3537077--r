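test_that("Bland-Altman matches the hand oracle", {
  b <- bland_altman(c(1, 2), c(1, 2))
  expect_equal(b$mean_diff, 0)
  expect_equal(b$sd_diff, 0)
  expect_equal(c(b$loa_low, b$loa_high), c(0, 0))

  # diffs (1, 2, 2): mean 5/3, sd = sqrt(1/3)
  b <- bland_altman(c(3, 4, 5), c(2, 2, 3))
  expect_equal(b$mean_diff, 5 / 3, tolerance = 1e-12)
  expect_equal(b$sd_diff, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(round(b$loa_low, 3), 0.535)
  expect_equal(round(b$loa_high, 3), 2.798)
  expect_equal(round(b$mean_diff_ci_low, 3), 1.013)
  expect_equal(round(b$mean_diff_ci_high, 3), 2.320)

  expect_error(bland_altman(1, 1), "at least 2")
  # t-based interval is wider than the normal approximation at small n
  bt <- bland_altman(c(3, 4, 5), c(2, 2, 3), ci = "t")
  expect_lt(bt$mean_diff_ci_low, b$mean_diff_ci_low)
})

test_that("Bland-Altman is antisymmetric and nests the mean CI in the LoA", {
  set.seed(66)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    s1 <- runif(n, 1, 5); s2 <- runif(n, 1, 5)
    a <- bland_altman(s1, s2)
    b <- bland_altman(s2, s1)
    expect_equal(a$mean_diff, mean(s1 - s2), tolerance = 1e-12)
    expect_equal(a$mean_diff, -b$mean_diff, tolerance = 1e-12)
    expect_equal(a$sd_diff, b$sd_diff, tolerance = 1e-12)
    expect_lte(a$loa_low, a$mean_diff_ci_low + 1e-12)
    expect_gte(a$loa_high, a$mean_diff_ci_high - 1e-12)
  }
})

test_that("quantile grouping partitions values at type-7 cut points", {
  qg <- quantile_groups(1:8, 4)
  expect_equal(as.vector(table(qg$groups)), rep(2, 4))
  expect_equal(qg$cuts, unname(quantile(1:8, c(0.25, 0.5, 0.75))))

  set.seed(77)
  x <- runif(94, 1, 5)
  qg <- quantile_groups(x, 4)
  expect_false(anyNA(qg$groups))          # every value in exactly one group
  expect_equal(length(qg$groups), 94)
  # membership by <= on the upper bound
  expect_true(all(x[qg$groups == qg$labels[1]] <= qg$cuts[1]))
  expect_true(all(x[qg$groups == qg$labels[4]] > qg$cuts[3]))

  expect_warning(qg <- quantile_groups(rep(2, 10), 4), "single effective")
  expect_equal(nlevels(qg$groups), 1)
  expect_error(quantile_groups(1:10, 1), "at least 2")
  expect_error(quantile_groups(1:3, 4), "at least as many")
})

test_that("subgroup chi-square equals the brute-force Pearson statistic", {
  r <- subgroup_difference_test(c(5, 5), c(20, 20))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 1)

  set.seed(88)
  for (i in 1:50) {
    g <- sample(2:6, 1)
    tot <- sample(10:40, g, replace = TRUE)
    sig <- rbinom(g, tot, runif(1, 0.1, 0.5))
    if (sum(sig) == 0 || sum(sig) == sum(tot)) next
    r <- subgroup_difference_test(sig, tot)
    # independent oracle: sum (O - E)^2 / E over the 2 x g table
    O <- rbind(sig, tot - sig)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(r$statistic, sum((O - E)^2 / E), tolerance = 1e-10)
    expect_equal(r$df, g - 1)
    expect_equal(r$p, pchisq(r$statistic, g - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    # invariant to reordering the groups
    o <- sample(g)
    expect_equal(subgroup_difference_test(sig[o], tot[o])$statistic,
                 r$statistic, tolerance = 1e-12)
  }
  expect_error(subgroup_difference_test(1, 10), "at least 2")
  expect_error(subgroup_difference_test(c(1, 0), c(10, 0)), "positive total")
})

test_that("score-vs-discrepancy association handles exact and degenerate cases", {
  s <- 1:10 / 2
  r <- score_discrepancy_association(s, s)
  expect_true(r$defined)
  expect_equal(r$pearson$r, 1, tolerance = 1e-12)
  expect_equal(r$spearman$rho, 1, tolerance = 1e-12)

  r <- score_discrepancy_association(runif(10, 1, 5), rep(0.4, 10))
  expect_false(r$defined)
  expect_true(is.na(r$pearson$r))
  expect_equal(nrow(r$pairs), 10)

  expect_error(score_discrepancy_association(1:2, 1:2), "at least 3")
})

test_that("independently generated scores show null-level correlation", {
  # with |w| independent of the scores, |r| < 2/sqrt(n) in about 95% of
  # draws; check the long-run fraction at n = 94
  set.seed(99)
  inside <- replicate(200, {
    r <- score_discrepancy_association(runif(94, 1, 5), abs(rnorm(94)))
    abs(r$pearson$r) < 2 / sqrt(94)
  })
  expect_gt(mean(inside), 0.85)
  expect_lte(mean(inside), 1)
})

test_that("subgroup tables tie grouping, counts and test together", {
  set.seed(111)
  scores <- runif(94, 1, 5)
  sig <- runif(94) < 0.17
  st <- subgroup_table(scores, sig, k = 4)
  expect_equal(sum(st$table$n_total), 94)
  expect_equal(sum(st$table$n_significant), sum(sig))
  expect_s3_class(st$table, "data.frame")
  expect_true(!is.null(st$test))
  expect_equal(st$test$df, 3)
})
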