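# Interassessor agreement (Bland-Altman) and the score-vs-inconsistency
# association analyses: quantile subgroups with a chi-square test, and
# correlation of scores with the absolute discrepancy |w|.

#' Bland-Altman agreement between two assessors
#'
#' Computes the paired differences `d = s1 - s2`, their mean and standard
#' deviation, the 95% limits of agreement `mean_diff +/- 1.96 * sd`, and a
#' confidence interval for the mean difference. The default interval is the
#' normal approximation `mean_diff +/- 1.96 * sd / sqrt(n)`; a t-based
#' interval is available with `ci = "t"`.
#'
#' @param s1,s2 Paired score vectors of equal length (n >= 2).
#' @param ci `"normal"` (default) or `"t"` for the mean-difference CI.
#' @return An object of class `tseca_bland_altman`: a list with `n`,
#'   `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `mean_diff_ci_low`,
#'   `mean_diff_ci_high`, `differences`.
#' @examples
#' bland_altman(c(3, 4, 5), c(2, 2, 3))
#' @export
bland_altman <- function(s1, s2, ci = c("normal", "t")) {
  ci <- match.arg(ci)
  stopifnot(length(s1) == length(s2))
  n <- length(s1)
  if (n < 2L) stop("at least 2 pairs are required")
  d <- s1 - s2
  m <- mean(d)
  s <- stats::sd(d)
  q <- if (ci == "normal") Z95 else stats::qt(0.975, n - 1)
  structure(
    list(n = n, mean_diff = m, sd_diff = s,
         loa_low = m - Z95 * s, loa_high = m + Z95 * s,
         mean_diff_ci_low = m - q * s / sqrt(n),
         mean_diff_ci_high = m + q * s / sqrt(n),
         ci = ci, differences = d),
    class = "tseca_bland_altman")
}

#' @export
print.tseca_bland_altman <- function(x, digits = 3, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference = %.*f, 95%% CI = %.*f to %.*f\n",
              x$n, digits, x$mean_diff, digits, x$mean_diff_ci_low,
              digits, x$mean_diff_ci_high))
  cat(sprintf("  limits of agreement: %.*f to %.*f (sd of differences %.*f)\n",
              digits, x$loa_low, digits, x$loa_high, digits, x$sd_diff))
  invisible(x)
}

#' Partition values into quantile subgroups
#'
#' Splits a vector at its k-1 empirical quantile cut points (linear
#' interpolation between order statistics, quantile type 7) into k ordered
#' groups, with membership by "less than or equal to" on the upper bound:
#' the groups are labelled `<=c1`, `>c1 & <=c2`, ..., `>c(k-1)`. When ties
#' make some cut points coincide, the degenerate (empty) groups are
#' collapsed with a warning.
#'
#' @param values Numeric vector (n >= k).
#' @param k Number of groups, default 4 (quartiles).
#' @return A list with `groups` (factor of length n), `cuts` (the k-1 cut
#'   points) and `labels`.
#' @examples
#' quantile_groups(1:8, 4)
#' @export
quantile_groups <- function(values, k = 4) {
  if (k < 2) stop("at least 2 groups are required")
  n <- length(values)
  if (n < k) stop("need at least as many values as groups")
  cuts <- stats::quantile(values, probs = seq_len(k - 1) / k, type = 7,
                          names = FALSE)
  ucuts <- unique(cuts)
  if (min(values) == max(values)) {
    warning("all values equal; a single effective group", call. = FALSE)
    labels <- "all"
    groups <- factor(rep("all", n), levels = labels)
    return(list(groups = groups, cuts = cuts, labels = labels))
  }
  if (length(ucuts) < length(cuts))
    warning("tied quantile cut points; ", k - length(ucuts) - 1L,
            " degenerate group(s) collapsed", call. = FALSE)
  fmt <- function(x) format(x, digits = 4, trim = TRUE)
  b <- length(ucuts)
  labels <- c(paste0("<=", fmt(ucuts[1])),
              if (b > 1) paste0(">", fmt(ucuts[-b]), " & <=", fmt(ucuts[-1])),
              paste0(">", fmt(ucuts[b])))
  idx <- findInterval(values, ucuts, left.open = TRUE) + 1L
  groups <- factor(labels[idx], levels = labels)
  list(groups = groups, cuts = cuts, labels = labels)
}

#' Chi-square test for a difference in proportions between subgroups
#'
#' Pearson chi-square (no continuity correction) on the groups x
#' {significant, not significant} contingency table, with
#' `df = groups - 1` and an upper-tail p-value.
#'
#' @param n_significant Per-group counts of reviews with statistically
#'   significant inconsistency.
#' @param n_total Per-group totals (all > 0).
#' @return A list with `statistic`, `df`, `p`, and the input `table`.
#' @examples
#' subgroup_difference_test(c(4, 2, 8, 2), c(25, 22, 25, 22))
#' @export
subgroup_difference_test <- function(n_significant, n_total) {
  stopifnot(length(n_significant) == length(n_total))
  if (length(n_total) < 2L) stop("at least 2 groups are required")
  if (any(n_total <= 0)) stop("every group must have a positive total")
  if (any(n_significant < 0) || any(n_significant > n_total))
    stop("counts must satisfy 0 <= n_significant <= n_total")
  tab <- cbind(significant = n_significant,
               not_significant = n_total - n_significant)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Association between assessment scores and absolute discrepancy
#'
#' Correlates per-review scores with the absolute discrepancy `|w|` (in log
#' ratio of odds ratios) between direct and indirect estimates, reporting
#' both Pearson and Spearman coefficients with two-sided p-values. If
#' either vector has zero variance the correlation is undefined and
#' reported as such rather than silently set to zero. The paired values are
#' returned for scatter plotting.
#'
#' @param scores,abs_w Numeric vectors of equal length (n >= 3); pairs with
#'   missing values are dropped.
#' @return A list with `n`, `defined`, `pearson` (list `r`, `p`),
#'   `spearman` (list `rho`, `p`) and `pairs` (data frame `score`,
#'   `abs_w`).
#' @export
score_discrepancy_association <- function(scores, abs_w) {
  stopifnot(length(scores) == length(abs_w))
  keep <- is.finite(scores) & is.finite(abs_w)
  scores <- scores[keep]; abs_w <- abs_w[keep]
  n <- length(scores)
  if (n < 3L) stop("at least 3 complete pairs are required")
  pairs <- data.frame(score = scores, abs_w = abs_w)
  if (stats::sd(scores) == 0 || stats::sd(abs_w) == 0)
    return(list(n = n, defined = FALSE,
                pearson = list(r = NA_real_, p = NA_real_),
                spearman = list(rho = NA_real_, p = NA_real_),
                pairs = pairs))
  pe <- stats::cor.test(scores, abs_w, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(scores, abs_w, method = "spearman"))
  list(n = n, defined = TRUE,
       pearson = list(r = unname(pe$estimate), p = pe$p.value),
       spearman = list(rho = unname(sp$estimate), p = sp$p.value),
       pairs = pairs)
}

#' Quantile-subgroup table of significant inconsistency
#'
#' Builds the per-instrument summary relating a score to significant
#' inconsistency: reviews are split into `k` quantile groups of the score,
#' and the proportion with significant inconsistency is compared between
#' groups with [subgroup_difference_test()].
#'
#' @param scores Per-review score vector.
#' @param significant Logical vector, same length.
#' @param k Number of quantile groups, default 4.
#' @return A list with `table` (data frame `group`, `n_significant`,
#'   `n_total`, `proportion`), `cuts`, and `test` (the chi-square result,
#'   or `NULL` when the grouping is degenerate).
#' @export
subgroup_table <- function(scores, significant, k = 4) {
  stopifnot(length(scores) == length(significant))
  keep <- is.finite(scores) & !is.na(significant)
  scores <- scores[keep]; significant <- significant[keep]
  qg <- quantile_groups(scores, k)
  tot <- tapply(significant, qg$groups, length)
  sig <- tapply(significant, qg$groups, sum)
  tot[is.na(tot)] <- 0; sig[is.na(sig)] <- 0
  tab <- data.frame(group = names(tot), n_significant = as.integer(sig),
                    n_total = as.integer(tot),
                    proportion = ifelse(tot > 0, sig / tot, NA_real_),
                    stringsAsFactors = FALSE)
  nonempty <- tab$n_total > 0
  test <- if (sum(nonempty) >= 2L)
    subgroup_difference_test(tab$n_significant[nonempty],
                             tab$n_total[nonempty])
  else NULL
  list(table = tab, cuts = qg$cuts, test = test)
}
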