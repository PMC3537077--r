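# Bucher adjusted indirect comparison and the direct-vs-indirect
# inconsistency statistic (log ratio of odds ratios).

.split_orientation <- function(orientation) {
  if (is.na(orientation)) return(NULL)
  parts <- strsplit(orientation, "v", fixed = TRUE)[[1]]
  if (length(parts) != 2L || any(!nzchar(parts))) return(NULL)
  parts
}

#' Standard error of a log odds ratio from a printed confidence interval
#'
#' Back-calculates the standard error from a reported 95% interval:
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.96)`. This lets published
#' summary estimates (an OR with its CI) be fed into [bucher_indirect()] and
#' [inconsistency_test()] without access to the trial-level data.
#'
#' @param or_point Point estimate (odds ratio), positive.
#' @param ci_low,ci_high Positive 95% interval bounds with
#'   `ci_low <= or_point <= ci_high`.
#' @return The standard error on the log odds ratio scale.
#' @examples
#' se_from_ci(0.55, 0.33, 0.91)
#' @export
se_from_ci <- function(or_point, ci_low, ci_high) {
  if (any(c(or_point, ci_low, ci_high) <= 0))
    stop("odds ratio and interval bounds must be positive")
  if (ci_low > or_point || or_point > ci_high)
    stop("require ci_low <= or_point <= ci_high")
  (log(ci_high) - log(ci_low)) / (2 * Z95)
}

#' Effect estimate from a printed odds ratio and confidence interval
#'
#' Convenience constructor composing [se_from_ci()] with
#' [effect_estimate()], so that a published summary like
#' "OR = 0.55; 95% CI = 0.33-0.91" can enter the analysis directly.
#'
#' @inheritParams se_from_ci
#' @inheritParams effect_estimate
#' @return An [effect_estimate()].
#' @export
effect_from_ci <- function(or_point, ci_low, ci_high,
                           orientation = NA_character_,
                           source = "direct-pooled", k_trials = 1L) {
  effect_estimate(log(or_point), se_from_ci(or_point, ci_low, ci_high),
                  orientation = orientation, source = source,
                  k_trials = k_trials)
}

#' Bucher adjusted indirect comparison
#'
#' Forms the indirect estimate of B versus C from the two A-anchored
#' comparisons: `log OR(BvC) = log OR(BvA) - log OR(CvA)` with
#' `se = sqrt(se_ba^2 + se_ca^2)`. Both inputs must carry explicit
#' orientations sharing the common comparator as reference; the direction is
#' never guessed.
#'
#' @param est_ba Effect of B versus the common comparator A (orientation
#'   `"BvA"` or generally `"<b>v<a>"`).
#' @param est_ca Effect of C versus the same comparator (`"CvA"`).
#' @return An [effect_estimate()] with `source = "indirect"` and orientation
#'   `"BvC"` (first active treatment versus the second).
#' @examples
#' ba <- effect_estimate(0.5, 0.2, orientation = "BvA")
#' ca <- effect_estimate(-0.3, 0.3, orientation = "CvA")
#' bucher_indirect(ba, ca)   # OR ~ 2.23, CI ~ 1.10 to 4.51
#' @export
bucher_indirect <- function(est_ba, est_ca) {
  stopifnot(inherits(est_ba, "tseca_effect"), inherits(est_ca, "tseca_effect"))
  o1 <- .split_orientation(est_ba$orientation)
  o2 <- .split_orientation(est_ca$orientation)
  if (is.null(o1) || is.null(o2))
    stop("both estimates must carry an explicit '<active>v<ref>' orientation")
  if (o1[2] != o2[2])
    stop("estimates do not share a common comparator: reference arms are '",
         o1[2], "' and '", o2[2], "'")
  if (o1[1] == o2[1])
    stop("the two estimates compare the same active treatment '", o1[1], "'")
  effect_estimate(est_ba$log_or - est_ca$log_or,
                  sqrt(est_ba$se^2 + est_ca$se^2),
                  orientation = paste0(o1[1], "v", o2[1]),
                  source = "indirect",
                  k_trials = est_ba$k_trials + est_ca$k_trials)
}

#' Test of inconsistency between direct and indirect estimates
#'
#' Quantifies the discrepancy between a direct head-to-head estimate and the
#' adjusted indirect estimate of the same comparison as the log ratio of
#' odds ratios `w = log OR(direct) - log OR(indirect)`, with
#' `se_w = sqrt(se_direct^2 + se_indirect^2)`, and tests `w = 0` with the
#' normal deviate `z = w / se_w` (two-sided). The ratio of odds ratios
#' `ROR = exp(w)` equals 1 under perfect consistency; `|w|` is the absolute
#' discrepancy on the log scale. Significance at level `alpha` coincides
#' with the ROR interval (built from the same 1.96 quantile when
#' `alpha = 0.05`) excluding 1.
#'
#' @param direct,indirect [effect_estimate()] objects for the same
#'   comparison, identically oriented (orientations must match when both are
#'   present; a missing orientation on either is an error).
#' @param alpha Two-sided significance level, default 0.05.
#' @return An object of class `tseca_inconsistency`: a list with `w`,
#'   `se_w`, `ror`, `ror_ci_low`, `ror_ci_high`, `z`, `p`, `significant`,
#'   `abs_discrepancy`, `alpha`.
#' @examples
#' d <- effect_from_ci(0.55, 0.33, 0.91, orientation = "BvC")
#' i <- effect_from_ci(2.68, 1.31, 5.46, orientation = "BvC",
#'                     source = "indirect")
#' inconsistency_test(d, i)   # z ~ -3.55, significant
#' @export
inconsistency_test <- function(direct, indirect, alpha = 0.05) {
  stopifnot(inherits(direct, "tseca_effect"),
            inherits(indirect, "tseca_effect"),
            is.numeric(alpha), alpha > 0, alpha < 1)
  if (is.na(direct$orientation) || is.na(indirect$orientation))
    stop("both estimates must carry an explicit orientation")
  if (direct$orientation != indirect$orientation)
    stop("direct and indirect estimates are oriented differently: '",
         direct$orientation, "' vs '", indirect$orientation, "'")
  w <- direct$log_or - indirect$log_or
  se_w <- sqrt(direct$se^2 + indirect$se^2)
  z <- w / se_w
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(w = w, se_w = se_w, ror = exp(w),
         ror_ci_low = exp(w - Z95 * se_w), ror_ci_high = exp(w + Z95 * se_w),
         z = z, p = p, significant = p < alpha, abs_discrepancy = abs(w),
         alpha = alpha, orientation = direct$orientation),
    class = "tseca_inconsistency")
}

#' @export
print.tseca_inconsistency <- function(x, digits = 3, ...) {
  cat(sprintf("Direct vs indirect inconsistency (%s):\n", x$orientation))
  cat(sprintf("  ROR = %.*f, 95%% CI = %.*f to %.*f\n",
              digits, x$ror, digits, x$ror_ci_low, digits, x$ror_ci_high))
  cat(sprintf("  w (log ROR) = %.*f, SE = %.*f, z = %.*f, p = %.4g%s\n",
              digits, x$w, digits, x$se_w, digits, x$z, x$p,
              if (x$significant) sprintf("  [significant at alpha = %g]", x$alpha)
              else ""))
  invisible(x)
}
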