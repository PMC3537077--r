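# Fixture builders shared across the test files.  All evidence is built in
# code; nothing is read from disk except files the tests write themselves.

# Arm-level rows for one complete three-set network (one trial per set).
make_complete_arms <- function(review_id = "rev1",
                               events = c(10, 12, 9, 15, 11, 14),
                               totals = rep(50, 6)) {
  data.frame(
    review_id = review_id,
    trial_id = rep(paste0(review_id, c("_t1", "_t2", "_t3")), each = 2),
    comparison = rep(c("AvB", "AvC", "BvC"), each = 2),
    treatment = c("A", "B", "A", "C", "B", "C"),
    events = events, total = totals,
    stringsAsFactors = FALSE)
}

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Minimal well-formed score sheet: `items` named scores, replicated for two
# assessors with an optional shift for assessor A1.
make_scores <- function(review_id = "rev1", instrument = "TSA",
                        items = c(participants = 3, interventions = 4,
                                  outcomes = 5),
                        shift_a1 = 0) {
  rbind(
    data.frame(review_id = review_id, assessor_id = "A1",
               instrument = instrument, item = names(items),
               score = unname(items) + shift_a1, stringsAsFactors = FALSE),
    data.frame(review_id = review_id, assessor_id = "A2",
               instrument = instrument, item = names(items),
               score = unname(items), stringsAsFactors = FALSE))
}

# Random estimable 2x2 table set (k trials) for property tests: moderate
# event probabilities so exclusions are rare but possible.
random_tables <- function(k, n_range = c(20, 80)) {
  n1 <- sample(seq(n_range[1], n_range[2]), k, replace = TRUE)
  n0 <- sample(seq(n_range[1], n_range[2]), k, replace = TRUE)
  p1 <- runif(k, 0.1, 0.9)
  p0 <- runif(k, 0.1, 0.9)
  list(r1 = rbinom(k, n1, p1), n1 = n1, r0 = rbinom(k, n0, p0), n0 = n0)
}

# Independent brute-force reference for fixed / DL pooling of log ORs from
# raw 2x2 tables, written directly from the closed forms (with the same
# continuity and exclusion conventions) and kept free of package code.
brute_pool_tables <- function(tab, method) {
  y <- s <- numeric(0)
  for (i in seq_along(tab$r1)) {
    a <- tab$r1[i]; b <- tab$n1[i] - tab$r1[i]
    c0 <- tab$r0[i]; d <- tab$n0[i] - tab$r0[i]
    if ((a == 0 && c0 == 0) || (b == 0 && d == 0)) next
    if (a == 0 || b == 0 || c0 == 0 || d == 0) {
      a <- a + 0.5; b <- b + 0.5; c0 <- c0 + 0.5; d <- d + 0.5
    }
    y <- c(y, log(a * d / (b * c0)))
    s <- c(s, sqrt(1 / a + 1 / b + 1 / c0 + 1 / d))
  }
  if (!length(y)) return(NULL)
  w <- 1 / s^2
  yf <- sum(w * y) / sum(w)
  if (method == "fixed" || length(y) == 1L)
    return(list(y = yf, se = sqrt(1 / sum(w))))
  Q <- sum(w * (y - yf)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (length(y) - 1)) / C)
  ws <- 1 / (s^2 + tau2)
  list(y = sum(ws * y) / sum(ws), se = sqrt(1 / sum(ws)))
}
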