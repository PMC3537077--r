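# Data model and CSV I/O for three-set evidence networks and assessor
# score sheets.  All files are comma-separated UTF-8 with a header row.

COMPARISONS <- c("AvB", "AvC", "BvC")
INSTRUMENTS <- c("TSA", "QSA", "ECA")

# Treatments allowed in each comparison set (A is the common comparator).
.comparison_arms <- list(AvB = c("A", "B"), AvC = c("A", "C"),
                         BvC = c("B", "C"))

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("malformed ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
}

# Validate arm-level rows of one review.  `line` gives the source file line
# of each row (header = line 1) for error messages; defaults to row order.
.validate_arms <- function(arms, review_id, line = NULL) {
  if (is.null(line)) line <- seq_len(nrow(arms)) + 1L
  err <- function(rows, msg)
    stop(sprintf("review '%s': %s (line %s)", review_id, msg,
                 paste(line[rows], collapse = ", ")), call. = FALSE)
  arms$events <- as.numeric(arms$events)
  arms$total <- as.numeric(arms$total)
  bad <- !arms$comparison %in% COMPARISONS
  if (any(bad)) err(which(bad), paste0("unknown comparison label '",
                                       arms$comparison[which(bad)[1]], "'"))
  bad <- is.na(arms$total) | arms$total < 1 | arms$total != round(arms$total)
  if (any(bad)) err(which(bad), "total must be a positive integer")
  bad <- is.na(arms$events) | arms$events < 0 |
    arms$events != round(arms$events)
  if (any(bad)) err(which(bad), "events must be a non-negative integer")
  bad <- arms$events > arms$total
  if (any(bad))
    err(which(bad), paste0("events exceed total in trial '",
                           arms$trial_id[which(bad)[1]], "'"))
  # two arms per trial, distinct treatments matching the comparison
  for (tid in unique(arms$trial_id)) {
    rows <- which(arms$trial_id == tid)
    trt <- sort(arms$treatment[rows])
    cmp <- unique(arms$comparison[rows])
    if (length(cmp) != 1L)
      err(rows, paste0("trial '", tid, "' is assigned to several comparisons"))
    if (length(rows) != 2L || !identical(trt, .comparison_arms[[cmp]]))
      err(rows, paste0("trial '", tid, "' must have exactly two arms with ",
                       "treatments ", paste(.comparison_arms[[cmp]],
                                            collapse = " and ")))
  }
  arms
}

#' Construct a validated evidence table for one review
#'
#' An evidence table holds the two-arm binary-outcome trials of one review,
#' partitioned into the three comparison sets of an indirect comparison:
#' AvB and AvC (sharing the common comparator A) and the head-to-head BvC
#' trials. A network is *complete* when all three sets contain at least one
#' trial; incomplete networks are representable (e.g. for a single pairwise
#' meta-analysis) but are excluded from the joint direct/indirect analysis.
#'
#' @param arms Data frame with columns `trial_id`, `comparison` (one of
#'   `"AvB"`, `"AvC"`, `"BvC"`), `treatment` (`"A"`, `"B"` or `"C"`),
#'   `events`, `total`, and optionally `label` (free-text treatment name).
#' @param review_id Review identifier.
#' @param outcome_name Free-text outcome description.
#' @param direction `"harmful"` if the event is undesirable (the default) or
#'   `"beneficial"`; carried as metadata so the orientation of odds ratios
#'   is never silently flipped.
#' @return An object of class `tseca_evidence`: a list with `review_id`,
#'   `outcome_name`, `direction`, `arms` (validated data frame) and
#'   `complete` (logical).
#' @examples
#' arms <- data.frame(
#'   trial_id = rep(c("t1", "t2", "t3"), each = 2),
#'   comparison = rep(c("AvB", "AvC", "BvC"), each = 2),
#'   treatment = c("A", "B", "A", "C", "B", "C"),
#'   events = c(10, 12, 9, 15, 11, 14), total = rep(50, 6))
#' evidence_table(arms, "rev1")
#' @export
evidence_table <- function(arms, review_id, outcome_name = NA_character_,
                           direction = c("harmful", "beneficial")) {
  direction <- match.arg(direction)
  .require_columns(arms, c("trial_id", "comparison", "treatment",
                           "events", "total"), "evidence table")
  if (is.null(arms$label)) arms$label <- NA_character_
  arms <- .validate_arms(as.data.frame(arms), review_id)
  present <- COMPARISONS %in% arms$comparison
  structure(list(review_id = as.character(review_id),
                 outcome_name = outcome_name, direction = direction,
                 arms = arms, complete = all(present)),
            class = "tseca_evidence")
}

#' @export
print.tseca_evidence <- function(x, ...) {
  k <- table(factor(x$arms$comparison[!duplicated(x$arms$trial_id)],
                    levels = COMPARISONS))
  cat(sprintf("Evidence table '%s' (%s network): %s\n", x$review_id,
              if (x$complete) "complete" else "incomplete",
              paste(sprintf("%d %s", k, names(k)), collapse = ", ")))
  invisible(x)
}

#' Read evidence tables from a CSV file
#'
#' Expects columns `review_id`, `trial_id`, `comparison`, `treatment`,
#' `events`, `total` (plus optional `label`, `outcome_name`, `direction`),
#' one row per trial arm. Rows are grouped by review and validated;
#' malformed rows are reported with their file line numbers.
#'
#' @param path Path to a CSV file.
#' @return A named list of [evidence_table()] objects, one per review.
#' @seealso [write_results()], [run_study()]
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("review_id", "trial_id", "comparison", "treatment",
                         "events", "total"), "evidence file")
  df$.line <- seq_len(nrow(df)) + 1L
  out <- lapply(split(df, factor(df$review_id, unique(df$review_id))),
                function(g) {
    arms <- g[setdiff(names(g), c(".line", "review_id",
                                  "outcome_name", "direction"))]
    arms <- .validate_arms(arms, g$review_id[1], line = g$.line)
    evidence_table(arms, g$review_id[1],
                   outcome_name = if (!is.null(g$outcome_name))
                     g$outcome_name[1] else NA_character_,
                   direction = if (!is.null(g$direction)) g$direction[1]
                   else "harmful")
  })
  out
}

#' Read assessor score sheets from a CSV file
#'
#' Expects columns `review_id`, `assessor_id`, `instrument` (`"TSA"`,
#' `"QSA"` or `"ECA"`), `item`, `score`, one row per scored item. Scores
#' must lie on the 1-5 assessment scale (half or quarter points allowed);
#' duplicate (review, assessor, instrument, item) rows are an error.
#'
#' @param path Path to a CSV file.
#' @return A data frame of the validated rows, of class `tseca_scores`.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_scores(df)
}

#' Validate a score-sheet data frame
#'
#' @param df Data frame with columns `review_id`, `assessor_id`,
#'   `instrument`, `item`, `score`.
#' @return The validated data frame, of class `tseca_scores`.
#' @export
validate_scores <- function(df) {
  .require_columns(df, c("review_id", "assessor_id", "instrument", "item",
                         "score"), "score sheet")
  df <- as.data.frame(df)
  bad <- !df$instrument %in% INSTRUMENTS
  if (any(bad))
    stop("unknown instrument '", df$instrument[which(bad)[1]],
         "' (row ", which(bad)[1], ")", call. = FALSE)
  df$score <- as.numeric(df$score)
  bad <- is.na(df$score) | df$score < 1 | df$score > 5
  if (any(bad))
    stop("score out of the 1-5 range (row ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  key <- paste(df$review_id, df$assessor_id, df$instrument, df$item,
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (review, assessor, instrument, item) rows: ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  class(df) <- c("tseca_scores", "data.frame")
  df
}

#' Read per-trial quality inputs from a CSV file
#'
#' Expects columns `review_id`, `trial_id`, `quality_score` (1-5 composite
#' covering randomisation method, allocation concealment, blinding, and
#' reported dropouts) and `n_patients`. These feed the patient-weighted
#' average quality per trial set and the quality similarity (QSA) score.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame.
#' @export
read_quality <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("review_id", "trial_id", "quality_score",
                         "n_patients"), "quality file")
  df$quality_score <- as.numeric(df$quality_score)
  df$n_patients <- as.numeric(df$n_patients)
  bad <- is.na(df$quality_score) | df$quality_score < 1 | df$quality_score > 5
  if (any(bad))
    stop("quality_score out of the 1-5 range (row ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  bad <- is.na(df$n_patients) | df$n_patients < 1
  if (any(bad))
    stop("n_patients must be positive (row ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  df
}

#' Write a results table to CSV
#'
#' Writes a data frame of results with a stable column order (the order of
#' the input) and full double precision (up to 15 significant digits, via
#' the standard decimal formatting of [utils::write.csv()]), so that a
#' write-then-read round trip reproduces values to within 1e-12 relative
#' error. An empty result set yields a header-only file.
#'
#' @param results A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  utils::write.csv(results, path, row.names = FALSE, na = "")
  invisible(path)
}
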