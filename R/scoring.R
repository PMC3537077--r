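# Quantitative aggregation rules of the TSECA instruments (TSA, QSA, ECA).
# These implement the scoring arithmetic only; the item scores themselves
# encode human judgement and arrive as data.

.check_scale <- function(x, what = "score") {
  if (any(!is.finite(x)) || any(x < 1) || any(x > 5))
    stop(what, " must lie on the 1-5 assessment scale", call. = FALSE)
  x
}

#' Overall instrument score from item scores
#'
#' The overall score of a TSA or ECA sheet is the unweighted arithmetic
#' mean of its item scores (the clinical domains: participants,
#' interventions, outcome measures, plus any extra items).
#'
#' @param items Numeric vector of item scores in \[1, 5\] (may be named).
#' @return The mean, in \[1, 5\].
#' @examples
#' overall_instrument_score(c(participants = 3, interventions = 4,
#'                            outcomes = 5))
#' @export
overall_instrument_score <- function(items) {
  if (length(items) == 0L) stop("no item scores supplied")
  mean(.check_scale(items, "item scores"))
}

#' Patient-weighted average trial quality
#'
#' Averages per-trial quality scores (1-5) weighted by the number of
#' patients in each trial: `sum(quality * n) / sum(n)`.
#'
#' @param quality Numeric vector of per-trial quality scores in \[1, 5\].
#' @param n_patients Positive per-trial patient counts.
#' @return Weighted mean quality, in \[1, 5\].
#' @examples
#' weighted_quality(c(4, 2), c(100, 300))  # 2.5
#' @export
weighted_quality <- function(quality, n_patients) {
  if (length(quality) == 0L) stop("no trials supplied")
  stopifnot(length(quality) == length(n_patients))
  .check_scale(quality, "quality scores")
  if (any(!is.finite(n_patients)) || any(n_patients <= 0))
    stop("n_patients must be positive", call. = FALSE)
  sum(quality * n_patients) / sum(n_patients)
}

#' Quality similarity (QSA) score from two set-level mean qualities
#'
#' Maps the absolute difference between the patient-weighted mean quality
#' of the AvB and AvC trial sets onto the 1-5 similarity scale:
#' `5 - |q_ab - q_ac|`, clipped to \[1, 5\]. Identical quality (however
#' high or low) gives the maximal score 5; the maximal possible difference
#' of 4 clips to the scale minimum 1.
#'
#' @param mean_q_ab,mean_q_ac Mean quality of the two trial sets, in
#'   \[1, 5\].
#' @return QSA score in \[1, 5\].
#' @examples
#' qsa_score(4.5, 2.5)  # 3
#' @export
qsa_score <- function(mean_q_ab, mean_q_ac) {
  .check_scale(c(mean_q_ab, mean_q_ac), "mean quality scores")
  min(5, max(1, 5 - abs(mean_q_ab - mean_q_ac)))
}

#' Combine the scores of two independent assessors
#'
#' When the two assessors' final scores differ, the combined score is their
#' simple average. Vectorised and symmetric in its arguments.
#'
#' @param score_1,score_2 Scores in \[1, 5\].
#' @return The arithmetic mean.
#' @examples
#' combine_assessors(3, 4)  # 3.5
#' @export
combine_assessors <- function(score_1, score_2) {
  .check_scale(c(score_1, score_2))
  (score_1 + score_2) / 2
}

#' Minimum item-specific score across instruments
#'
#' A difference in a single variable can be enough to violate the
#' similarity or consistency assumption, so averaging items can conceal the
#' key threat. The minimum item score over all instruments of a review is
#' the conservative summary used in that exploratory analysis.
#'
#' @param ... Numeric vectors of item scores (e.g. the TSA and ECA item
#'   scores of one review), each in \[1, 5\].
#' @return The global minimum.
#' @examples
#' min_item_score(c(4, 2.25), c(3, 1.75))  # 1.75
#' @export
min_item_score <- function(...) {
  items <- unlist(list(...), use.names = FALSE)
  if (length(items) == 0L) stop("no item scores supplied")
  min(.check_scale(items, "item scores"))
}

#' Check the ECA-vs-TSA ordering
#'
#' In principle the overall evidence consistency (ECA) score should not
#' exceed the overall trial similarity (TSA) score: consistency between
#' direct and indirect evidence presupposes similarity within the indirect
#' evidence. A violation is reported as a warning record, not an error,
#' since the ordering is a plausibility check rather than a hard constraint.
#'
#' @param eca_overall,tsa_overall Overall scores in \[1, 5\].
#' @param review_id Optional identifier used in the warning message.
#' @return A list with `ok` (logical) and `message` (`NA` when `ok`); a
#'   warning is emitted when the ordering is violated.
#' @examples
#' validate_eca_vs_tsa(3.63, 3.85)  # ok
#' @export
validate_eca_vs_tsa <- function(eca_overall, tsa_overall,
                                review_id = NA_character_) {
  .check_scale(c(eca_overall, tsa_overall))
  if (eca_overall > tsa_overall) {
    msg <- sprintf("ECA overall score (%.3g) exceeds TSA overall score (%.3g)%s",
                   eca_overall, tsa_overall,
                   if (is.na(review_id)) "" else paste0(" in review '",
                                                        review_id, "'"))
    warning(msg, call. = FALSE)
    list(ok = FALSE, message = msg)
  } else {
    list(ok = TRUE, message = NA_character_)
  }
}

#' Derived instrument scores per review
#'
#' Aggregates a long score-sheet table (see [read_scores()]) and optional
#' per-trial quality inputs into one row per review: the assessor-combined
#' overall TSA and ECA scores, the QSA score, and the minimum item score.
#' Per assessor, the overall score of an instrument is the unweighted mean
#' of its items; the two assessors are then combined by simple averaging.
#' The QSA score is computed from the quality inputs (patient-weighted mean
#' quality per trial set, mapped by [qsa_score()]) when `quality` and
#' `evidence` are supplied; otherwise from QSA instrument sheets when
#' present. ECA > TSA orderings are reported via [validate_eca_vs_tsa()].
#'
#' @param scores Score-sheet data frame ([read_scores()] schema).
#' @param quality Optional quality-input data frame ([read_quality()]
#'   schema).
#' @param evidence Optional list of [evidence_table()]s, needed to assign
#'   quality trials to their comparison sets.
#' @return A data frame with columns `review_id`, `tsa_overall`, `qsa`,
#'   `eca_overall`, `min_item`.
#' @export
score_reviews <- function(scores, quality = NULL, evidence = NULL) {
  scores <- validate_scores(scores)
  overall <- function(g, instr) {
    g <- g[g$instrument == instr, , drop = FALSE]
    if (!nrow(g)) return(NA_real_)
    per_assessor <- tapply(g$score, g$assessor_id, mean)
    mean(per_assessor)
  }
  combined_items <- function(g) {
    g <- g[g$instrument %in% c("TSA", "ECA"), , drop = FALSE]
    if (!nrow(g)) return(numeric(0))
    tapply(g$score, paste(g$instrument, g$item, sep = "\r"), mean)
  }
  rows <- lapply(split(scores, factor(scores$review_id,
                                      unique(scores$review_id))),
                 function(g) {
    rid <- g$review_id[1]
    tsa <- overall(g, "TSA")
    eca <- overall(g, "ECA")
    qsa <- NA_real_
    if (!is.null(quality) && !is.null(evidence)) {
      q <- quality[quality$review_id == rid, , drop = FALSE]
      ev <- evidence[[rid]]
      if (nrow(q) && !is.null(ev)) {
        cmp <- ev$arms$comparison[match(q$trial_id, ev$arms$trial_id)]
        qa <- q[which(cmp == "AvB"), , drop = FALSE]
        qc <- q[which(cmp == "AvC"), , drop = FALSE]
        if (nrow(qa) && nrow(qc))
          qsa <- qsa_score(weighted_quality(qa$quality_score, qa$n_patients),
                           weighted_quality(qc$quality_score, qc$n_patients))
      }
    }
    if (is.na(qsa)) qsa <- overall(g, "QSA")
    items <- combined_items(g)
    if (!is.na(tsa) && !is.na(eca))
      validate_eca_vs_tsa(eca, tsa, review_id = rid)
    data.frame(review_id = rid, tsa_overall = tsa, qsa = qsa,
               eca_overall = eca,
               min_item = if (length(items)) min(items) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
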