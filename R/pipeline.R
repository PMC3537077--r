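# End-to-end study pipeline: per-review effects -> Bucher indirect
# comparison -> inconsistency test -> score aggregation -> agreement and
# association summaries.

# Core per-review analysis on raw 2x2 tables.  Each set is a list of
# parallel vectors (r1, n1, r0, n0): active-arm vs reference-arm counts,
# where the active arm is B in AvB, C in AvC and B in BvC.  Returns NULL
# when any set loses all its trials to the double-zero exclusion rule.
.analyse_tables <- function(ab, ac, bc, pooling, alpha) {
  v_ab <- .log_or_vec(ab$r1, ab$n1, ab$r0, ab$n0)
  v_ac <- .log_or_vec(ac$r1, ac$n1, ac$r0, ac$n0)
  v_bc <- .log_or_vec(bc$r1, bc$n1, bc$r0, bc$n0)
  n_excluded <- sum(v_ab$excluded, v_ac$excluded, v_bc$excluded)
  if (all(v_ab$excluded) || all(v_ac$excluded) || all(v_bc$excluded))
    return(NULL)
  pool_set <- function(v, orientation, source) {
    ok <- !v$excluded
    p <- .pool_vec(v$log_or[ok], v$se[ok], pooling)
    out <- effect_estimate(p$log_or, p$se, orientation = orientation,
                           source = source, k_trials = p$k)
    out$Q <- p$Q; out$tau2 <- p$tau2; out$method <- pooling
    class(out) <- c("tseca_pool", "tseca_effect")
    out
  }
  est_ba <- pool_set(v_ab, "BvA", "direct-pooled")
  est_ca <- pool_set(v_ac, "CvA", "direct-pooled")
  direct <- pool_set(v_bc, "BvC", "direct-pooled")
  indirect <- bucher_indirect(est_ba, est_ca)
  list(est_ba = est_ba, est_ca = est_ca, direct = direct,
       indirect = indirect,
       incons = inconsistency_test(direct, indirect, alpha = alpha),
       n_excluded = n_excluded)
}

# Extract the three (r1, n1, r0, n0) sets from a validated arm data frame.
.arms_to_tables <- function(arms) {
  one_set <- function(comparison, active) {
    a <- arms[arms$comparison == comparison, , drop = FALSE]
    if (!nrow(a)) return(NULL)
    act <- a[a$treatment == active, , drop = FALSE]
    ref <- a[a$treatment != active, , drop = FALSE]
    ref <- ref[match(act$trial_id, ref$trial_id), , drop = FALSE]
    list(r1 = act$events, n1 = act$total, r0 = ref$events, n0 = ref$total)
  }
  list(ab = one_set("AvB", "B"), ac = one_set("AvC", "C"),
       bc = one_set("BvC", "B"))
}

#' Analyse one evidence network
#'
#' Runs the full direct-vs-indirect comparison for a single review: pools
#' the per-trial log odds ratios of each comparison set (B vs A, C vs A,
#' and direct B vs C), forms the Bucher indirect estimate, and tests the
#' inconsistency between the direct and indirect B-vs-C estimates.
#'
#' @param evidence An [evidence_table()] (must be a complete network).
#' @param pooling `"dl"` (DerSimonian-Laird, default) or `"fixed"`.
#' @param alpha Significance level of the inconsistency test.
#' @return A list with the pooled `est_ba`, `est_ca`, `direct` and
#'   `indirect` effects, the `incons` ([inconsistency_test()]) result and
#'   `n_excluded` (trials dropped by the double-zero rule), or `NULL` when
#'   a whole comparison set is inestimable.
#' @export
analyse_network <- function(evidence, pooling = c("dl", "fixed"),
                            alpha = 0.05) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(evidence, "tseca_evidence"))
  if (!evidence$complete)
    stop("review '", evidence$review_id, "' is not a complete network")
  tabs <- .arms_to_tables(evidence$arms)
  .analyse_tables(tabs$ab, tabs$ac, tabs$bc, pooling, alpha)
}

.review_row <- function(review_id, res) {
  data.frame(
    review_id = review_id,
    k_ab = res$est_ba$k_trials, k_ac = res$est_ca$k_trials,
    k_bc = res$direct$k_trials, n_excluded = res$n_excluded,
    or_direct = exp(res$direct$log_or),
    direct_ci_low = res$direct$ci_low, direct_ci_high = res$direct$ci_high,
    or_indirect = exp(res$indirect$log_or),
    indirect_ci_low = res$indirect$ci_low,
    indirect_ci_high = res$indirect$ci_high,
    ror = res$incons$ror,
    ror_ci_low = res$incons$ror_ci_low,
    ror_ci_high = res$incons$ror_ci_high,
    w = res$incons$w, se_w = res$incons$se_w, z = res$incons$z,
    p = res$incons$p, significant = res$incons$significant,
    abs_w = res$incons$abs_discrepancy,
    stringsAsFactors = FALSE)
}

#' Run the full study pipeline
#'
#' Orchestrates the whole analysis over a collection of reviews: per-review
#' direct and Bucher-indirect estimates with the inconsistency test;
#' derived TSA/QSA/ECA scores per review; quantile-subgroup tables of
#' significant inconsistency per instrument; Bland-Altman interassessor
#' agreement per instrument item; and score-vs-|w| association statistics.
#' Reviews with incomplete networks, or score sheets referencing unknown
#' reviews, are excluded with a warning. With no score data the
#' inconsistency analysis still runs and the score sections are `NULL`.
#'
#' @param evidence Path to an evidence CSV, an arm-level data frame, or a
#'   list of [evidence_table()]s.
#' @param scores Optional path to a score CSV or a score data frame.
#' @param quality Optional path to a quality CSV or data frame.
#' @param pooling `"dl"` or `"fixed"`.
#' @param alpha Significance level, default 0.05.
#' @param quantiles Number of quantile subgroups, default 4.
#' @param output_dir Optional directory; when given, writes
#'   `per_review.csv`, `summary.csv`, `subgroups.csv`, `agreement.csv`,
#'   `association.csv` and the plot-data files `scatter.csv` (score vs
#'   |w|) and `score_distributions.csv`.
#' @return An object of class `tseca_study`: a list with `per_review`
#'   (data frame), `scores` (derived per-review scores or `NULL`),
#'   `summary` (n analysed / n significant / proportion), `subgroups`
#'   (per-instrument [subgroup_table()] results), `agreement`
#'   (per instrument x item [bland_altman()] results), `association`
#'   (per-instrument [score_discrepancy_association()] results) and
#'   `excluded` (review ids excluded, with reasons).
#' @export
run_study <- function(evidence, scores = NULL, quality = NULL,
                      pooling = c("dl", "fixed"), alpha = 0.05,
                      quantiles = 4, output_dir = NULL) {
  pooling <- match.arg(pooling)
  if (is.character(evidence)) evidence <- read_evidence(evidence)
  if (is.data.frame(evidence)) {
    df <- evidence
    evidence <- lapply(split(df, factor(df$review_id,
                                        unique(df$review_id))),
                       function(g) evidence_table(
                         g[setdiff(names(g), "review_id")], g$review_id[1]))
  }
  stopifnot(length(evidence) > 0,
            all(vapply(evidence, inherits, TRUE, "tseca_evidence")))
  names(evidence) <- vapply(evidence, function(e) e$review_id, "")
  if (is.character(scores)) scores <- read_scores(scores)
  if (!is.null(scores) && nrow(scores) == 0L) scores <- NULL
  if (is.character(quality)) quality <- read_quality(quality)

  excluded <- data.frame(review_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  rows <- list()
  for (ev in evidence) {
    if (!ev$complete) {
      warning("review '", ev$review_id,
              "' has an incomplete network; excluded", call. = FALSE)
      excluded <- rbind(excluded, data.frame(review_id = ev$review_id,
                                             reason = "incomplete network"))
      next
    }
    res <- analyse_network(ev, pooling = pooling, alpha = alpha)
    if (is.null(res)) {
      warning("review '", ev$review_id,
              "' has an inestimable comparison set; excluded",
              call. = FALSE)
      excluded <- rbind(excluded,
                        data.frame(review_id = ev$review_id,
                                   reason = "inestimable comparison set"))
      next
    }
    rows[[ev$review_id]] <- .review_row(ev$review_id, res)
  }
  if (!length(rows))
    stop("no complete, estimable evidence network in the input")
  per_review <- do.call(rbind, rows)
  rownames(per_review) <- NULL

  derived <- NULL; subgroups <- NULL; agreement <- NULL; association <- NULL
  if (!is.null(scores)) {
    scores <- validate_scores(scores)
    unknown <- setdiff(unique(scores$review_id), names(evidence))
    if (length(unknown)) {
      warning("score sheets reference unknown review(s): ",
              paste(unknown, collapse = ", "), "; excluded", call. = FALSE)
      scores <- scores[!scores$review_id %in% unknown, , drop = FALSE]
    }
    if (nrow(scores)) {
      derived <- score_reviews(scores, quality = quality,
                               evidence = evidence)
      m <- merge(derived, per_review[c("review_id", "significant",
                                       "abs_w")], by = "review_id")
      score_cols <- c(tsa_overall = "tsa_overall", qsa = "qsa",
                      eca_overall = "eca_overall", min_item = "min_item")
      subgroups <- lapply(score_cols, function(col) {
        x <- m[[col]]
        if (sum(is.finite(x)) >= quantiles)
          subgroup_table(x, m$significant, k = quantiles) else NULL
      })
      association <- lapply(score_cols, function(col) {
        x <- m[[col]]
        if (sum(is.finite(x) & is.finite(m$abs_w)) >= 3)
          score_discrepancy_association(x, m$abs_w) else NULL
      })
      # Bland-Altman per instrument x item over reviews scored by exactly
      # two assessors
      agreement <- list()
      for (instr in unique(scores$instrument)) {
        si <- scores[scores$instrument == instr, , drop = FALSE]
        for (it in unique(si$item)) {
          sit <- si[si$item == it, , drop = FALSE]
          wide <- stats::reshape(sit[c("review_id", "assessor_id", "score")],
                                 idvar = "review_id",
                                 timevar = "assessor_id",
                                 direction = "wide")
          vals <- wide[setdiff(names(wide), "review_id")]
          if (ncol(vals) == 2L) {
            cc <- stats::complete.cases(vals)
            if (sum(cc) >= 2L)
              agreement[[paste(instr, it, sep = ".")]] <-
                bland_altman(vals[cc, 1], vals[cc, 2])
          }
        }
      }
    }
  }

  summary <- list(n_analysed = nrow(per_review),
                  n_significant = sum(per_review$significant),
                  prop_significant = mean(per_review$significant),
                  alpha = alpha, pooling = pooling)
  out <- structure(list(per_review = per_review, scores = derived,
                        summary = summary, subgroups = subgroups,
                        agreement = agreement, association = association,
                        excluded = excluded),
                   class = "tseca_study")
  if (!is.null(output_dir)) .write_study(out, output_dir)
  out
}

.write_study <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_results(x$per_review, file.path(dir, "per_review.csv"))
  write_results(
    data.frame(n_analysed = x$summary$n_analysed,
               n_significant = x$summary$n_significant,
               prop_significant = x$summary$prop_significant,
               alpha = x$summary$alpha, pooling = x$summary$pooling),
    file.path(dir, "summary.csv"))
  if (!is.null(x$subgroups)) {
    sub <- do.call(rbind, lapply(names(x$subgroups), function(nm) {
      s <- x$subgroups[[nm]]
      if (is.null(s)) return(NULL)
      cbind(instrument = nm, s$table,
            chisq_p = if (is.null(s$test)) NA_real_ else s$test$p)
    }))
    if (!is.null(sub)) write_results(sub, file.path(dir, "subgroups.csv"))
  }
  if (!is.null(x$agreement) && length(x$agreement)) {
    agr <- do.call(rbind, lapply(names(x$agreement), function(nm) {
      b <- x$agreement[[nm]]
      data.frame(item = nm, n = b$n, mean_diff = b$mean_diff,
                 ci_low = b$mean_diff_ci_low, ci_high = b$mean_diff_ci_high,
                 loa_low = b$loa_low, loa_high = b$loa_high)
    }))
    write_results(agr, file.path(dir, "agreement.csv"))
  }
  if (!is.null(x$association)) {
    ass <- do.call(rbind, lapply(names(x$association), function(nm) {
      a <- x$association[[nm]]
      if (is.null(a)) return(NULL)
      data.frame(instrument = nm, n = a$n, defined = a$defined,
                 pearson_r = a$pearson$r, pearson_p = a$pearson$p,
                 spearman_rho = a$spearman$rho, spearman_p = a$spearman$p)
    }))
    if (!is.null(ass)) write_results(ass, file.path(dir, "association.csv"))
    sc <- do.call(rbind, lapply(names(x$association), function(nm) {
      a <- x$association[[nm]]
      if (is.null(a)) return(NULL)
      cbind(instrument = nm, a$pairs)
    }))
    if (!is.null(sc)) write_results(sc, file.path(dir, "scatter.csv"))
  }
  if (!is.null(x$scores))
    write_results(x$scores, file.path(dir, "score_distributions.csv"))
  invisible(dir)
}

#' @export
print.tseca_study <- function(x, ...) {
  cat(sprintf("Direct vs indirect comparison study: %d reviews analysed (%s pooling)\n",
              x$summary$n_analysed, x$summary$pooling))
  cat(sprintf("  significant inconsistency (alpha = %g): %d of %d (%.1f%%)\n",
              x$summary$alpha, x$summary$n_significant,
              x$summary$n_analysed, 100 * x$summary$prop_significant))
  if (nrow(x$excluded))
    cat(sprintf("  excluded: %d review(s)\n", nrow(x$excluded)))
  if (is.null(x$scores))
    cat("  score sections: absent (no score sheets supplied)\n")
  invisible(x)
}
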