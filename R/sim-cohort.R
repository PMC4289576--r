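# Synthetic-cohort generator.
#
# A single latent frailty trait z ~ N(0,1) drives all eleven questionnaire
# items through logistic models; records are then scored exactly like real
# data, so class membership is emergent and the full scoring path is
# exercised. Conditional on the scored class, the generator draws age, sex
# and covariates; event times for death and nursing-care need; wave-2
# outcome categories; and, for wave-2 participants, a second questionnaire
# consistent with the drawn destination class.

# draw the 11 answer-token columns given latent z
.fa_sample_items <- function(z, item_model, freq_splits) {
  n <- length(z)
  im <- item_model
  out <- vector("list", nrow(im))
  names(out) <- im$column
  frail <- matrix(NA, n, nrow(im))
  for (i in seq_len(nrow(im))) {
    frail[, i] <- stats::runif(n) < stats::plogis(im$a[i] + im$b[i] * z)
  }
  colnames(frail) <- im$column
  pick <- function(n_i, split) {
    if (n_i == 0L) return(character(0))
    sample(names(split), n_i, replace = TRUE, prob = split)
  }
  for (cn in im$column) {
    f <- frail[, cn]
    if (cn %in% names(freq_splits)) {
      sp <- freq_splits[[cn]]
      x <- character(n)
      x[f] <- pick(sum(f), sp$frail)
      x[!f] <- pick(sum(!f), sp$robust)
    } else if (cn == "work_or_volunteer_7d") {
      x <- ifelse(f, "no", "yes")
    } else {
      # risk-style yes/no items and fear_falling_limits: frail answer = yes
      x <- ifelse(f, "yes", "no")
    }
    out[[cn]] <- x
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# truncated-normal ages by rejection within [min, max]
.fa_sample_age <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  x <- numeric(0)
  while (length(x) < n) {
    cand <- stats::rnorm(2L * (n - length(x)) + 10L, mean, sd)
    x <- c(x, cand[cand >= lo & cand <= hi])
  }
  round(x[seq_len(n)], 1)
}

#' Draw wave-2 outcome categories from the transition matrix
#'
#' One categorical draw per respondent from the transition row of their
#' pooled wave-1 class. The outcomes `dead`, `lost` and `refused` terminate
#' the trajectory; the class outcomes mean a scorable wave-2 questionnaire.
#'
#' @param class_w1 vector of pooled wave-1 class labels
#'   (Robust/Transient/Frail).
#' @param transition_model 3x6 row-stochastic matrix as in
#'   [fa_sim_config()].
#' @return character vector of outcome categories.
#' @export
fa_sample_wave2 <- function(class_w1, transition_model) {
  cls <- as.character(class_w1)
  bad <- !(cls %in% rownames(transition_model))
  if (any(bad)) {
    fa_stop("unknown class label(s) for transition draw: ",
            paste(unique(cls[bad]), collapse = ", "))
  }
  out <- character(length(cls))
  for (g in unique(cls)) {
    i <- cls == g
    out[i] <- sample(colnames(transition_model), sum(i), replace = TRUE,
                     prob = transition_model[g, ])
  }
  out
}

# accept-reject wave-2 questionnaires whose scored pooled class matches the
# drawn destination; z2 is correlated with the wave-1 trait
.fa_sample_wave2_records <- function(z1, target_pooled, config, max_rounds = 2000L) {
  n <- length(z1)
  im <- config$item_model
  rho <- config$wave2_model$z_autocorrelation
  rec <- .fa_sample_items(rep(0, n), im, config$freq_splits)[0, , drop = FALSE]
  rec[seq_len(n), ] <- NA
  z2 <- rep(NA_real_, n)
  todo <- seq_len(n)
  rounds <- 0L
  while (length(todo) > 0L) {
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      fa_stop("wave-2 record resampling failed to match destination classes (",
              length(todo), " left after ", max_rounds, " rounds)")
    }
    zc <- rho * z1[todo] + sqrt(1 - rho^2) * stats::rnorm(length(todo))
    cand <- .fa_sample_items(zc, im, config$freq_splits)
    sc <- fa_indicators(cand)
    pooled <- as.character(fa_pool(fa_classify(sc$risk_score, sc$resource_score)))
    hit <- pooled == target_pooled[todo]
    if (any(hit)) {
      rec[todo[hit], ] <- cand[hit, ]
      z2[todo[hit]] <- zc[hit]
      todo <- todo[!hit]
    }
  }
  list(records = rec, z2 = z2)
}

.fa_empty_cohort <- function(config) {
  items <- fa_questions()$column
  cols <- c("id", "z", items,
            paste0("risk_", 1:6), paste0("resource_", 1:6),
            "risk_score", "resource_score", "unscorable", "fa_class",
            "pooled_class", "age", "sex", "living_alone", "health_fairpoor",
            "chronic_pain", "depressed", "poor_vision",
            "death_time_true", "care_time_true", "censor_time",
            "censor_reason", "time_death", "event_death", "time_care",
            "event_care", "w2_raw_draw", "w2_outcome", "w2_z",
            paste0("w2_", items), "w2_fa_class", "w2_pooled_class",
            "w2_falls", "w2_adl", "w2_care")
  df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
  names(df) <- cols
  df
}

#' Generate a synthetic cohort
#'
#' Runs the full generative model: latent traits and wave-1 questionnaires,
#' scoring, class-conditional demographics and covariates (with MCAR
#' missingness), death and nursing-care event times over the follow-up
#' horizon, wave-2 outcome categories (death from the hazard model takes
#' priority over the categorical transition draw, which is retained in
#' `w2_raw_draw` for audit), and wave-2 questionnaires for participants.
#' Output is byte-identical for identical `(config, seed)`; independent
#' RNG substreams per stage keep the stages individually reproducible.
#'
#' Observed follow-up columns: `time_death`/`event_death` censor at loss to
#' follow-up or the administrative horizon; `time_care`/`event_care`
#' additionally censor nursing-care follow-up at death. Nobody has
#' nursing-care need at wave 1 (all event times are positive).
#'
#' @param config an [fa_sim_config()]. If `config$calibrate` is `TRUE` and
#'   the item model has not been calibrated yet, [fa_calibrate_items()] is
#'   applied first.
#' @return data.frame with one row per respondent: wave-1 items and scores,
#'   demographics, covariates, true and observed event times, censoring
#'   time and reason, wave-2 outcome and (for participants) wave-2 items,
#'   scores and health outcomes. The resolved config is attached as
#'   attribute `"config"`.
#' @examples
#' cohort <- fa_generate_cohort(fa_sim_config(n = 300, seed = 42))
#' table(cohort$fa_class)
#' @export
fa_generate_cohort <- function(config) {
  fa_validate_config(config)
  if (isTRUE(config$calibrate) && !isTRUE(attr(config$item_model, "calibrated"))) {
    config <- fa_calibrate_items(config)
  }
  n <- config$n
  if (n == 0L) {
    out <- .fa_empty_cohort(config)
    attr(out, "config") <- config
    return(out)
  }
  set.seed(config$seed)
  ss <- sample.int(.Machine$integer.max, 8L)
  horizon <- config$horizon_months
  wave2 <- config$wave2_month

  # stage 1: latent traits and wave-1 items, then scoring
  set.seed(ss[1L])
  z <- stats::rnorm(n)
  items <- .fa_sample_items(z, config$item_model, config$freq_splits)
  scored <- fa_score_cohort(cbind(id = seq_len(n), items))
  scored$z <- z
  cls <- as.character(scored$fa_class)
  ci <- match(cls, fa_levels())

  # stage 2: class-conditional demographics and covariates
  set.seed(ss[2L])
  am <- config$age_model
  age <- numeric(n); sex <- character(n)
  for (k in seq_len(4L)) {
    i <- which(ci == k)
    age[i] <- .fa_sample_age(length(i), am$mean[k], am$sd[k], am$min[k], am$max[k])
    sex[i] <- ifelse(stats::runif(length(i)) < config$sex_model$p_female[k],
                     "female", "male")
  }
  prev <- config$covariate_model$prevalence
  mrate <- config$covariate_model$missing_rate
  covs <- setdiff(names(prev), "class")
  for (cv in covs) {
    x <- as.integer(stats::runif(n) < prev[[cv]][ci])
    x[stats::runif(n) < mrate[[cv]]] <- NA_integer_
    scored[[cv]] <- x
  }
  scored$age <- age
  scored$sex <- sex

  # stage 3: true event times (death, nursing-care need)
  set.seed(ss[3L])
  hz <- config$hazard_model
  death_t <- care_t <- numeric(n)
  for (k in seq_len(4L)) {
    i <- which(ci == k)
    death_t[i] <- .fa_rtime(length(i), hz$death_fraction[k], horizon, hz$shape)
    care_t[i] <- .fa_rtime(length(i), hz$care_fraction[k], horizon, hz$shape)
  }

  # stage 4: wave-2 outcome category; hazard deaths override the raw draw
  set.seed(ss[4L])
  pooled <- as.character(scored$pooled_class)
  raw <- fa_sample_wave2(pooled, config$transition_model)
  outcome <- character(n)
  dead <- death_t <= horizon
  outcome[dead] <- "dead"
  cen <- config$censoring_model
  p_dead_cls <- hz$death_fraction
  u <- stats::runif(n)
  alive <- which(!dead)
  p_lost_c <- cen$p_lost[ci] / (1 - p_dead_cls[ci])
  p_ref_c <- cen$p_refused[ci] / (1 - p_dead_cls[ci])
  outcome[alive[u[alive] < p_lost_c[alive]]] <- "lost"
  sel <- alive[u[alive] >= p_lost_c[alive] &
                 u[alive] < (p_lost_c + p_ref_c)[alive]]
  outcome[sel] <- "refused"
  part <- which(outcome == "")
  if (length(part) > 0L) {
    tm <- config$transition_model
    for (g in rownames(tm)) {
      i <- part[pooled[part] == g]
      if (length(i) == 0L) next
      pr <- tm[g, c("Robust", "Transient", "Frail")]
      if (sum(pr) <= 0) {
        fa_stop("transition row '", g, "' leaves survivors with no class destination")
      }
      outcome[i] <- sample(c("Robust", "Transient", "Frail"), length(i),
                           replace = TRUE, prob = pr / sum(pr))
    }
  }
  censor_time <- rep(horizon, n)
  reason <- rep("admin", n)
  lost_i <- which(outcome == "lost")
  censor_time[lost_i] <- stats::runif(length(lost_i), 0, wave2)
  reason[lost_i] <- "lost"
  reason[outcome == "refused"] <- "refused"

  # stage 5: wave-2 questionnaires for participants
  set.seed(ss[5L])
  is_part <- outcome %in% c("Robust", "Transient", "Frail")
  w2_items <- .fa_sample_items(numeric(0), config$item_model, config$freq_splits)
  w2_items[seq_len(n), ] <- NA
  w2_z <- rep(NA_real_, n)
  if (any(is_part)) {
    res <- .fa_sample_wave2_records(z[is_part], outcome[is_part], config)
    w2_items[is_part, ] <- res$records
    w2_z[is_part] <- res$z2
  }
  names(w2_items) <- paste0("w2_", names(w2_items))
  w2_sc <- fa_indicators(stats::setNames(w2_items, sub("^w2_", "", names(w2_items))))
  w2_class <- fa_classify(w2_sc$risk_score, w2_sc$resource_score)

  # stage 6: wave-2 health outcomes among participants
  set.seed(ss[6L])
  w2m <- config$wave2_model
  w2_falls <- rep(NA_character_, n)
  w2_adl <- rep(NA_integer_, n)
  w2_care <- rep(NA_integer_, n)
  if (any(is_part)) {
    i <- which(is_part)
    p1 <- w2m$falls$p_once[ci[i]]; pm <- w2m$falls$p_multi[ci[i]]
    uu <- stats::runif(length(i))
    w2_falls[i] <- ifelse(uu < pm, "multi", ifelse(uu < pm + p1, "once", "none"))
    w2_adl[i] <- as.integer(stats::runif(length(i)) < w2m$p_adl[ci[i]])
    w2_care[i] <- as.integer(care_t[i] <= wave2)
  }

  # observed follow-up
  time_death <- pmin(death_t, censor_time)
  event_death <- as.integer(death_t <= censor_time)
  cens_care <- pmin(death_t, censor_time)
  time_care <- pmin(care_t, cens_care)
  event_care <- as.integer(care_t <= cens_care)

  out <- cbind(
    scored[, c("id", "z", fa_questions()$column,
               paste0("risk_", 1:6), paste0("resource_", 1:6),
               "risk_score", "resource_score", "unscorable",
               "fa_class", "pooled_class", "age", "sex", covs)],
    data.frame(
      death_time_true = death_t, care_time_true = care_t,
      censor_time = censor_time, censor_reason = reason,
      time_death = time_death, event_death = event_death,
      time_care = time_care, event_care = event_care,
      w2_raw_draw = raw, w2_outcome = outcome, w2_z = w2_z,
      stringsAsFactors = FALSE),
    w2_items,
    data.frame(w2_fa_class = as.character(w2_class),
               w2_pooled_class = as.character(fa_pool(w2_class)),
               w2_falls = w2_falls, w2_adl = w2_adl, w2_care = w2_care,
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  attr(out, "config") <- config
  out
}

#' Export a cohort's event histories in long format
#'
#' One row per respondent and endpoint (`death`, `nursing_care`) with the
#' observed follow-up time, event flag, class and adjustment covariates —
#' the layout survival tooling consumes.
#'
#' @param cohort output of [fa_generate_cohort()].
#' @param path optional CSV path; when given the table is also written.
#' @return the events data.frame (invisibly when `path` is given).
#' @export
fa_events <- function(cohort, path = NULL) {
  check_columns(cohort, c("id", "time_death", "event_death", "time_care",
                          "event_care", "fa_class", "age", "sex",
                          "health_fairpoor"), "cohort")
  mk <- function(endpoint, tim, ev) {
    data.frame(id = cohort$id, endpoint = endpoint,
               time_months = tim, event = ev,
               group = as.character(cohort$fa_class),
               age = cohort$age, sex = cohort$sex,
               health_fairpoor = cohort$health_fairpoor,
               stringsAsFactors = FALSE)
  }
  ev <- rbind(mk("death", cohort$time_death, cohort$event_death),
              mk("nursing_care", cohort$time_care, cohort$event_care))
  if (!is.null(path)) {
    utils::write.csv(ev, path, row.names = FALSE, na = "")
    return(invisible(ev))
  }
  ev
}
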