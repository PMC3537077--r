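# Per-trial effect estimation and pairwise meta-analytic pooling.

Z95 <- 1.96  # normal quantile used for all 95% intervals, by design

#' Construct an effect estimate on the log odds ratio scale
#'
#' The basic container for a treatment effect: a natural-log odds ratio, its
#' standard error, and the implied 95% confidence interval on the odds-ratio
#' scale (computed with the quantile 1.96 exactly). The `orientation` field
#' records which comparison the estimate refers to, as `"<active>v<ref>"`
#' (e.g. `"BvA"` for the odds of the event under B relative to A); functions
#' that combine estimates refuse to guess a missing orientation.
#'
#' @param log_or Natural-log odds ratio.
#' @param se Positive standard error of `log_or`.
#' @param orientation Comparison label, `"<active>v<ref>"`, or `NA`.
#' @param source One of `"single-trial"`, `"direct-pooled"`, `"indirect"`.
#' @param k_trials Number of trials the estimate is based on.
#' @return An object of class `tseca_effect`: a list with elements `log_or`,
#'   `se`, `ci_low`, `ci_high` (odds-ratio scale), `orientation`, `source`,
#'   `k_trials`.
#' @examples
#' effect_estimate(log(2), 0.3, orientation = "BvA")
#' @export
effect_estimate <- function(log_or, se, orientation = NA_character_,
                            source = "single-trial", k_trials = 1L) {
  stopifnot(is.numeric(log_or), length(log_or) == 1L, is.finite(log_or),
            is.numeric(se), length(se) == 1L, is.finite(se), se > 0)
  source <- match.arg(source, c("single-trial", "direct-pooled", "indirect"))
  structure(
    list(log_or = log_or, se = se,
         ci_low = exp(log_or - Z95 * se), ci_high = exp(log_or + Z95 * se),
         orientation = as.character(orientation), source = source,
         k_trials = as.integer(k_trials)),
    class = "tseca_effect")
}

#' @export
print.tseca_effect <- function(x, digits = 3, ...) {
  cat(sprintf("%s effect (%s, k = %d): OR = %.*f, 95%% CI = %.*f to %.*f, log OR = %.*f (SE %.*f)\n",
              if (is.na(x$orientation)) "unoriented" else x$orientation,
              x$source, x$k_trials,
              digits, exp(x$log_or), digits, x$ci_low, digits, x$ci_high,
              digits, x$log_or, digits, x$se))
  invisible(x)
}

# Vectorised log OR with 0.5 continuity correction on tables containing any
# zero cell.  Double-zero / double-total tables are inestimable and returned
# as NA (the caller drops them).  Arguments are the event counts and totals
# of the active and control arms.
.log_or_vec <- function(r1, n1, r0, n0) {
  stopifnot(all(n1 >= 1), all(n0 >= 1),
            all(r1 >= 0), all(r0 >= 0), all(r1 <= n1), all(r0 <= n0))
  excl <- (r1 == 0 & r0 == 0) | (r1 == n1 & r0 == n0)
  a <- r1; b <- n1 - r1; c0 <- r0; d <- n0 - r0
  zero <- a == 0 | b == 0 | c0 == 0 | d == 0
  cc <- ifelse(zero, 0.5, 0)
  a <- a + cc; b <- b + cc; c0 <- c0 + cc; d <- d + cc
  y <- log(a * d / (b * c0))
  s <- sqrt(1 / a + 1 / b + 1 / c0 + 1 / d)
  y[excl] <- NA_real_; s[excl] <- NA_real_
  list(log_or = y, se = s, excluded = excl)
}

#' Log odds ratio of a single two-arm trial
#'
#' Computes the log odds ratio of the event for the active arm relative to
#' the control arm, with standard error
#' \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}} from the 2x2 cell counts. When any
#' cell of the table is zero, 0.5 is added to all four cells before the
#' calculation (the usual continuity correction). Tables with zero events in
#' both arms, or all events in both arms, carry no information about the
#' odds ratio: these return `NULL`, signalling that the trial is to be
#' excluded from pooling.
#'
#' @param events_active,total_active Events and sample size of the active arm.
#' @param events_control,total_control Events and sample size of the control
#'   arm.
#' @param orientation Optional comparison label stored on the result.
#' @return A [effect_estimate()] (`source = "single-trial"`), or `NULL` for
#'   an inestimable (double-zero / double-total) table.
#' @examples
#' trial_log_or(10, 20, 5, 20)             # log OR = log(3)
#' trial_log_or(0, 10, 5, 10)              # continuity-corrected
#' is.null(trial_log_or(0, 10, 0, 10))     # TRUE: excluded
#' @export
trial_log_or <- function(events_active, total_active,
                         events_control, total_control,
                         orientation = NA_character_) {
  if (total_active < 1 || total_control < 1)
    stop("arm sample sizes must be at least 1")
  v <- .log_or_vec(events_active, total_active, events_control, total_control)
  if (v$excluded) return(NULL)
  effect_estimate(v$log_or, v$se, orientation = orientation,
                  source = "single-trial", k_trials = 1L)
}

# Closed-form fixed / DerSimonian-Laird pooling on (y, se) vectors.
.pool_vec <- function(y, se, method) {
  w <- 1 / se^2
  yf <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yf)^2)
  k <- length(y)
  if (method == "fixed" || k == 1L) {
    tau2 <- 0
    yp <- yf
    sp <- 1 / sqrt(sum(w))
  } else {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / C)
    ws <- 1 / (se^2 + tau2)
    yp <- sum(ws * y) / sum(ws)
    sp <- 1 / sqrt(sum(ws))
  }
  list(log_or = yp, se = sp, Q = Q, tau2 = tau2, k = k)
}

#' Pool effect estimates across trials
#'
#' Inverse-variance pooling of log odds ratios, either fixed-effect or
#' random-effects with the DerSimonian-Laird moment estimator of the
#' between-trial variance: \eqn{\tau^2 = \max\{0, (Q - (k-1))/C\}} with
#' \eqn{C = \sum w - \sum w^2 / \sum w} and fixed-effect weights
#' \eqn{w = 1/se^2}. A single estimate is returned unchanged with
#' \eqn{Q = 0}, \eqn{\tau^2 = 0}.
#'
#' @param estimates A list of [effect_estimate()] objects (entries that are
#'   `NULL` — excluded trials — are dropped), or a numeric vector of log
#'   odds ratios (then `se` must be given).
#' @param se Standard errors, when `estimates` is a numeric vector.
#' @param method `"dl"` (DerSimonian-Laird random effects, the default) or
#'   `"fixed"`.
#' @param source Source tag for the pooled estimate.
#' @return An object of classes `tseca_pool` and `tseca_effect` with the
#'   extra elements `Q`, `tau2`, `method`.
#' @examples
#' pool(c(0, 2), se = c(1, 1), method = "fixed")   # mean 1, se 1/sqrt(2)
#' pool(c(0, 2), se = c(1, 1), method = "dl")      # tau2 = 1, se 1
#' @export
pool <- function(estimates, se = NULL, method = c("dl", "fixed"),
                 source = "direct-pooled") {
  method <- match.arg(method)
  if (is.list(estimates)) {
    estimates <- Filter(Negate(is.null), estimates)
    if (length(estimates) == 0L) stop("no estimable trials to pool")
    orient <- unique(vapply(estimates, function(e) e$orientation, ""))
    if (length(orient) > 1L)
      stop("cannot pool estimates with mixed orientations: ",
           paste(orient, collapse = ", "))
    y <- vapply(estimates, function(e) e$log_or, 0)
    s <- vapply(estimates, function(e) e$se, 0)
  } else {
    if (is.null(se)) stop("'se' is required when pooling raw log ORs")
    y <- estimates; s <- se
    orient <- NA_character_
    if (length(y) == 0L) stop("no estimable trials to pool")
  }
  stopifnot(length(y) == length(s), all(is.finite(y)), all(s > 0))
  p <- .pool_vec(y, s, method)
  out <- effect_estimate(p$log_or, p$se, orientation = orient,
                         source = source, k_trials = p$k)
  out$Q <- p$Q; out$tau2 <- p$tau2; out$method <- method
  class(out) <- c("tseca_pool", "tseca_effect")
  out
}

#' Pooled event rate of a set of arms
#'
#' Simple aggregate proportion across arms: total events divided by total
#' sample size. Used to compare baseline (e.g. placebo) response rates
#' between the trial sets of an indirect comparison, where a difference
#' flags a potential effect modifier.
#'
#' @param events,totals Integer vectors of per-arm event counts and sizes.
#' @return A proportion in \[0, 1\].
#' @examples
#' pooled_event_rate(c(10, 20), c(50, 50))  # 0.30
#' @export
pooled_event_rate <- function(events, totals) {
  stopifnot(length(events) == length(totals))
  if (length(events) == 0L) stop("no arms supplied")
  stopifnot(all(events >= 0), all(totals >= 1), all(events <= totals))
  sum(events) / sum(totals)
}
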