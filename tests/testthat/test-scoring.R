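test_that("instrument aggregation rules pass exact hand-computed cases", {
  expect_equal(overall_instrument_score(c(3, 4, 5)), 4.0)
  expect_equal(overall_instrument_score(2.5), 2.5)
  expect_equal(overall_instrument_score(c(3.42, 4.17, 4.00)),
               mean(c(3.42, 4.17, 4.00)))
  expect_error(overall_instrument_score(numeric(0)), "no item")
  expect_error(overall_instrument_score(c(3, 6)), "1-5")

  expect_equal(weighted_quality(4, 100), 4.0)
  expect_equal(weighted_quality(c(4, 2), c(100, 300)), 2.5)
  expect_equal(weighted_quality(c(3, 4.5), c(70, 70)), mean(c(3, 4.5)))
  expect_error(weighted_quality(numeric(0), numeric(0)), "no trials")
  expect_error(weighted_quality(c(4, 2), c(100, 0)), "positive")

  expect_equal(qsa_score(4.0, 4.0), 5.0)
  expect_equal(qsa_score(4.5, 2.5), 3.0)
  expect_equal(qsa_score(5.0, 1.0), 1.0)  # maximal difference clips
  expect_error(qsa_score(0.5, 3), "1-5")

  expect_equal(combine_assessors(3, 4), 3.5)
  expect_equal(combine_assessors(4.2, 4.2), 4.2)
  expect_equal(combine_assessors(1, 5), 3.0)

  expect_equal(min_item_score(c(3.5, 2.0, 4.0)), 2.0)
  expect_equal(min_item_score(c(3, 3, 3)), 3.0)
  expect_equal(min_item_score(c(4, 2.25), c(3, 1.75)), 1.75)
  expect_error(min_item_score(), "no item")
})

test_that("aggregation outputs stay on the 1-5 scale and obey symmetries", {
  set.seed(55)
  for (i in 1:100) {
    items <- runif(sample(1:6, 1), 1, 5)
    o <- overall_instrument_score(items)
    expect_gte(o, 1); expect_lte(o, 5)
    expect_lte(min_item_score(items), o)

    q <- runif(3, 1, 5); n <- sample(20:500, 3)
    wq <- weighted_quality(q, n)
    expect_gte(wq, 1); expect_lte(wq, 5)
    # splitting a trial into two halves with the same quality is a no-op
    expect_equal(weighted_quality(c(q, q[1]), c(n[1] / 2, n[2], n[3],
                                                n[1] / 2)),
                 wq, tolerance = 1e-12)

    s <- runif(2, 1, 5)
    expect_equal(combine_assessors(s[1], s[2]), combine_assessors(s[2], s[1]))
    expect_gte(qsa_score(s[1], s[2]), 1)
    expect_lte(qsa_score(s[1], s[2]), 5)
  }
})

test_that("the ECA-vs-TSA ordering check warns but does not error", {
  expect_silent(r <- validate_eca_vs_tsa(3.63, 3.85))
  expect_true(r$ok)
  expect_silent(r <- validate_eca_vs_tsa(3.0, 3.0))
  expect_true(r$ok)
  expect_warning(r <- validate_eca_vs_tsa(4.0, 3.5, review_id = "rev9"),
                 "exceeds")
  expect_false(r$ok)
  expect_match(r$message, "rev9")
})

test_that("per-review derived scores combine assessors and instruments", {
  sc <- rbind(make_scores(instrument = "TSA",
                          items = c(participants = 3, interventions = 4,
                                    outcomes = 4), shift_a1 = 0.5),
              make_scores(instrument = "ECA",
                          items = c(participants = 3, interventions = 3,
                                    outcomes = 3.5)))
  d <- score_reviews(sc)
  # TSA: A1 mean (3.5+4.5+4.5)/3, A2 mean 11/3; combined by simple average
  expect_equal(d$tsa_overall, (mean(c(3.5, 4.5, 4.5)) + mean(c(3, 4, 4))) / 2)
  expect_equal(d$eca_overall, mean(c(3, 3, 3.5)))
  # minimum over assessor-combined TSA and ECA item scores
  expect_equal(d$min_item, 3)
  expect_true(is.na(d$qsa))

  # QSA from quality inputs routed through the evidence table
  arms <- make_complete_arms()
  ev <- list(rev1 = evidence_table(arms[-1], "rev1"))
  qual <- data.frame(review_id = "rev1",
                     trial_id = c("rev1_t1", "rev1_t2"),
                     quality_score = c(4.5, 2.5), n_patients = c(100, 100))
  d2 <- score_reviews(sc, quality = qual, evidence = ev)
  expect_equal(d2$qsa, qsa_score(4.5, 2.5))

  # an ECA > TSA review triggers the ordering warning
  sc_bad <- rbind(make_scores(instrument = "TSA",
                              items = c(participants = 3)),
                  make_scores(instrument = "ECA",
                              items = c(participants = 4)))
  expect_warning(score_reviews(sc_bad), "exceeds")
})
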