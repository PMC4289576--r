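#' faindex: dual risk/resource functional-ability screening
#'
#' The Functional Ability (FA) index screens community-dwelling seniors by
#' self-report. Eleven questionnaire items yield six frailty-risk indicators
#' (weight loss, changed ways of walking / climbing stairs / getting in and
#' out of a car or bus, infrequent outside walking, falls) and six
#' robustness-resource indicators (walking 500 m without difficulty,
#' frequent outside walking, moderate and strenuous activity, paid or
#' volunteer work, no fear-of-falling limitation). One question — how often
#' the respondent walks outside — carries double weight: a low frequency
#' counts as a risk, a high frequency as a resource. The two counts
#' cross-classify respondents into Robust, postRobust, preFrail and Frail.
#'
#' @keywords internal
"_PACKAGE"

# controlled vocabulary -------------------------------------------------------

#' FA questionnaire data dictionary
#'
#' Column names, answer vocabularies and the risk/resource indicators each
#' item feeds. Input CSVs use exactly these column names; answers are the
#' controlled string tokens listed here; a missing answer is an empty cell
#' (read as `NA`).
#'
#' @return data.frame with one row per question: `column`, `type`
#'   (`yes_no`, `freq4`, `walk500`), `levels` (comma-separated tokens), and
#'   `feeds` (which indicators the item drives).
#' @examples
#' fa_questions()
#' @export
fa_questions <- function() {
  data.frame(
    column = c("weight_loss_5kg", "changed_walk_1km", "changed_climb_10steps",
               "changed_car_bus", "walk_outside_freq", "falls_12mo",
               "walk_500m", "moderate_activity_freq", "strenuous_activity_freq",
               "work_or_volunteer_7d", "fear_falling_limits"),
    type = c("yes_no", "yes_no", "yes_no", "yes_no", "freq4", "yes_no",
             "walk500", "freq4", "freq4", "yes_no", "yes_no"),
    levels = c(rep("no,yes", 4), "never,1-2,3-4,5-7", "no,yes",
               "yes,with_difficulty,no", "never,1-2,3-4,5-7",
               "never,1-2,3-4,5-7", "no,yes", "no,yes"),
    feeds = c("risk_1", "risk_2", "risk_3", "risk_4", "risk_5+resource_2",
              "risk_6", "resource_1", "resource_3", "resource_4",
              "resource_5", "resource_6"),
    stringsAsFactors = FALSE
  )
}

.fa_freq_levels  <- c("never", "1-2", "3-4", "5-7")
.fa_walk500_levels <- c("yes", "with_difficulty", "no")
.fa_yesno_levels <- c("no", "yes")

#' FA class labels
#'
#' @param pooled if `TRUE`, return the three pooled labels (postRobust and
#'   preFrail merged into Transient), otherwise the four class labels.
#' @return character vector of labels in severity order.
#' @export
fa_levels <- function(pooled = FALSE) {
  if (pooled) c("Robust", "Transient", "Frail")
  else c("Robust", "postRobust", "preFrail", "Frail")
}

# token validation: returns logical matrix of "invalid (non-missing) token"
.fa_check_tokens <- function(df) {
  qs <- fa_questions()
  for (i in seq_len(nrow(qs))) {
    lv <- strsplit(qs$levels[i], ",", fixed = TRUE)[[1]]
    x <- df[[qs$column[i]]]
    x[!is.na(x) & x == ""] <- NA
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) {
      fa_stop(sprintf("invalid answer token(s) in '%s': %s (allowed: %s)",
                      qs$column[i],
                      paste(unique(x[bad]), collapse = ", "),
                      qs$levels[i]))
    }
  }
  invisible(TRUE)
}

# indicators ------------------------------------------------------------------

#' Derive risk and resource indicators from questionnaire answers
#'
#' Maps raw answers to the six risk and six resource indicators and sums
#' them into the frailty-risk score and robustness-resource score. The
#' outside-walking frequency feeds both `risk_5` (never or 1-2 days/week)
#' and `resource_2` (3-4 or 5-7 days/week), with exactly one of the two
#' firing for any non-missing answer. A record with any missing answer is
#' flagged unscorable (complete-case rule); its indicators and scores are
#' `NA`, never imputed.
#'
#' @param records data.frame with the 11 question columns of
#'   [fa_questions()] (extra columns are ignored). Empty strings are treated
#'   as missing.
#' @return data.frame, row-aligned with `records`: 12 indicator columns
#'   (`risk_1`..`risk_6`, `resource_1`..`resource_6`), `risk_score`,
#'   `resource_score`, and logical `unscorable`.
#' @examples
#' rec <- data.frame(weight_loss_5kg = "no", changed_walk_1km = "no",
#'   changed_climb_10steps = "no", changed_car_bus = "no",
#'   walk_outside_freq = "5-7", falls_12mo = "no", walk_500m = "yes",
#'   moderate_activity_freq = "3-4", strenuous_activity_freq = "1-2",
#'   work_or_volunteer_7d = "yes", fear_falling_limits = "no")
#' fa_indicators(rec)
#' @export
fa_indicators <- function(records) {
  qs <- fa_questions()
  check_columns(records, qs$column, "questionnaire table")
  if (nrow(records) == 0L) {
    out <- as.data.frame(matrix(integer(0), nrow = 0, ncol = 12))
    names(out) <- c(paste0("risk_", 1:6), paste0("resource_", 1:6))
    out$risk_score <- integer(0)
    out$resource_score <- integer(0)
    out$unscorable <- logical(0)
    return(out)
  }
  .fa_check_tokens(records)
  get <- function(col) {
    x <- as.character(records[[col]])
    x[!is.na(x) & x == ""] <- NA
    x
  }
  walk <- get("walk_outside_freq")
  ind <- data.frame(
    risk_1 = as.integer(get("weight_loss_5kg") == "yes"),
    risk_2 = as.integer(get("changed_walk_1km") == "yes"),
    risk_3 = as.integer(get("changed_climb_10steps") == "yes"),
    risk_4 = as.integer(get("changed_car_bus") == "yes"),
    risk_5 = as.integer(walk %in% c("never", "1-2") & !is.na(walk)),
    risk_6 = as.integer(get("falls_12mo") == "yes"),
    resource_1 = as.integer(get("walk_500m") == "yes"),
    resource_2 = as.integer(walk %in% c("3-4", "5-7") & !is.na(walk)),
    resource_3 = as.integer(get("moderate_activity_freq") != "never"),
    resource_4 = as.integer(get("strenuous_activity_freq") != "never"),
    resource_5 = as.integer(get("work_or_volunteer_7d") == "yes"),
    resource_6 = as.integer(get("fear_falling_limits") == "no")
  )
  # walk-frequency NA must propagate into both derived indicators
  ind$risk_5[is.na(walk)] <- NA_integer_
  ind$resource_2[is.na(walk)] <- NA_integer_
  unscorable <- apply(is.na(ind), 1L, any)
  ind[unscorable, ] <- NA_integer_
  ind$risk_score <- rowSums(ind[, paste0("risk_", 1:6)])
  ind$resource_score <- rowSums(ind[, paste0("resource_", 1:6)])
  ind$unscorable <- unscorable
  ind
}

# classification --------------------------------------------------------------

#' Classify risk/resource score pairs into the four FA classes
#'
#' The 2x2 grid on (risk 0-2 vs 3-6) x (resource 3-6 vs 0-2): few risks and
#' many resources is Robust; many of both is postRobust; few of both is
#' preFrail; many risks and few resources is Frail.
#'
#' @param risk_score integer vector in 0..6 (NA allowed, propagates).
#' @param resource_score integer vector in 0..6, same length.
#' @return factor with levels `Robust`, `postRobust`, `preFrail`, `Frail`.
#' @examples
#' fa_classify(c(0, 3, 2, 6), c(6, 3, 2, 0))
#' @export
fa_classify <- function(risk_score, resource_score) {
  if (length(risk_score) != length(resource_score)) {
    fa_stop("risk_score and resource_score must have equal length")
  }
  ok <- !is.na(risk_score) & !is.na(resource_score)
  rng <- function(x) any(x[!is.na(x)] < 0 | x[!is.na(x)] > 6 |
                           x[!is.na(x)] != floor(x[!is.na(x)]))
  if (rng(risk_score) || rng(resource_score)) {
    fa_stop("scores must be integers in 0..6")
  }
  lab <- rep(NA_character_, length(risk_score))
  hi_risk <- risk_score >= 3
  hi_res  <- resource_score >= 3
  lab[ok & !hi_risk & hi_res]  <- "Robust"
  lab[ok & hi_risk  & hi_res]  <- "postRobust"
  lab[ok & !hi_risk & !hi_res] <- "preFrail"
  lab[ok & hi_risk  & !hi_res] <- "Frail"
  factor(lab, levels = fa_levels())
}

#' Pool the four FA classes into three
#'
#' postRobust and preFrail are merged into a single Transient class, the
#' grouping used for transition analyses where the two middle classes are
#' individually too small for stable estimates.
#'
#' @param fa_class factor or character vector of 4-level class labels.
#' @return factor with levels `Robust`, `Transient`, `Frail`.
#' @export
fa_pool <- function(fa_class) {
  x <- as.character(fa_class)
  bad <- !is.na(x) & !(x %in% fa_levels())
  if (any(bad)) {
    fa_stop(sprintf("unknown class label(s): %s", paste(unique(x[bad]), collapse = ", ")))
  }
  x[x %in% c("postRobust", "preFrail")] <- "Transient"
  factor(x, levels = fa_levels(pooled = TRUE))
}

#' Ordinal encoding of the FA class
#'
#' Robust = 0, postRobust = 1, preFrail = 2, Frail = 3 — the severity order
#' in which adverse-outcome prevalences increase across the classes. Used
#' for rank correlations of the index with health measures.
#'
#' @param fa_class factor or character vector of 4-level labels.
#' @return integer vector in 0..3.
#' @export
fa_ordinal <- function(fa_class) {
  match(as.character(fa_class), fa_levels()) - 1L
}

# cohort scoring --------------------------------------------------------------

#' Score a cohort of questionnaire records
#'
#' Derives indicators, scores and class labels for every record, preserving
#' row order. Unscorable records (any missing answer) carry `NA` scores and
#' no class, and are excluded from the class-share denominators
#' (complete-case rule).
#'
#' @param records data.frame with the 11 question columns; an `id` column
#'   and any other columns are carried through.
#' @return data.frame: carried-through columns, the 12 indicators, the two
#'   scores, `fa_class`, `pooled_class` and `unscorable`. The class-count
#'   summary is attached as attribute `"class_table"` (see
#'   [fa_class_table()]).
#' @examples
#' recs <- fa_example_records()        # one engineered record per class
#' scored <- fa_score_cohort(recs)
#' attr(scored, "class_table")
#' @export
fa_score_cohort <- function(records) {
  ind <- fa_indicators(records)
  keep <- records[, setdiff(names(records), names(ind)), drop = FALSE]
  out <- cbind(keep, ind)
  out$fa_class <- fa_classify(ind$risk_score, ind$resource_score)
  out$pooled_class <- fa_pool(out$fa_class)
  rownames(out) <- NULL
  attr(out, "class_table") <- fa_class_table(out$fa_class)
  out
}

#' Class counts and shares of scorable respondents
#'
#' @param fa_class factor of 4-level class labels (NA = unscorable).
#' @return data.frame with `class`, `n`, and `percent` of scorable records
#'   (one decimal, half away from zero); attribute `"n_scorable"` and
#'   `"n_unscorable"` give the denominators.
#' @examples
#' fa_class_table(fa_classify(c(0, 3, 2, 6, NA), c(6, 3, 2, 0, NA)))
#' @export
fa_class_table <- function(fa_class) {
  fa_class <- factor(as.character(fa_class), levels = fa_levels())
  n <- as.integer(table(fa_class))
  denom <- sum(n)
  out <- data.frame(class = fa_levels(), n = n,
                    percent = pct(n, denom), stringsAsFactors = FALSE)
  attr(out, "n_scorable") <- denom
  attr(out, "n_unscorable") <- sum(is.na(fa_class))
  out
}

#' Engineered example records, one per FA class
#'
#' Four complete questionnaire records constructed to land in Robust,
#' postRobust, preFrail and Frail respectively. Useful for demos and as a
#' scoring smoke test.
#'
#' @return data.frame of four records with an `id` column.
#' @export
fa_example_records <- function() {
  base <- data.frame(
    id = c("robust", "postrobust", "prefrail", "frail"),
    weight_loss_5kg = c("no", "yes", "no", "yes"),
    changed_walk_1km = c("no", "yes", "no", "yes"),
    changed_climb_10steps = c("no", "yes", "no", "yes"),
    changed_car_bus = c("no", "no", "no", "yes"),
    walk_outside_freq = c("5-7", "3-4", "never", "never"),
    falls_12mo = c("no", "no", "no", "yes"),
    walk_500m = c("yes", "yes", "with_difficulty", "no"),
    moderate_activity_freq = c("3-4", "1-2", "never", "never"),
    strenuous_activity_freq = c("1-2", "1-2", "never", "never"),
    work_or_volunteer_7d = c("yes", "no", "no", "no"),
    fear_falling_limits = c("no", "no", "yes", "yes"),
    stringsAsFactors = FALSE
  )
  base
}

#' Write a scored cohort to CSV
#'
#' Emits the audit layout: respondent id, wave, the 12 indicator columns,
#' the two scores and both class labels.
#'
#' @param scored output of [fa_score_cohort()].
#' @param path file path.
#' @param wave wave number recorded in the output (default 1).
#' @return `path`, invisibly.
#' @export
fa_write_scores <- function(scored, path, wave = 1L) {
  cols <- c(paste0("risk_", 1:6), paste0("resource_", 1:6),
            "risk_score", "resource_score", "fa_class", "pooled_class")
  check_columns(scored, cols, "scored cohort")
  id <- if ("id" %in% names(scored)) scored$id else seq_len(nrow(scored))
  out <- cbind(data.frame(id = id, wave = wave), scored[, cols])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
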