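# Simulation configuration: all generator parameters in one validated list.
#
# Default values encode the published structure of the cohort the index was
# validated in: four-class mixture, class-specific age/sex/covariate
# distributions, class-specific 93-month death fractions and wave-2
# loss/refusal fractions, and the pooled-class transition matrix. Counts are
# stored as count/denominator pairs so derived probabilities are exact.

.fa_class4 <- function() fa_levels()
.fa_class3 <- function() fa_levels(pooled = TRUE)

.fa_default_item_model <- function() {
  # One row per distinct question (the outside-walk item appears once and
  # drives both risk_5 and resource_2). `a` is the baseline log-odds of the
  # frail-direction answer at latent frailty z = 0, `b` its loading on z.
  # Frail-direction means: the answer that fires a risk indicator, or fails
  # to fire a resource indicator. Baselines are plausible marginals for a
  # largely robust urban cohort of 60+ year olds; calibration (see
  # fa_calibrate_items) shifts risk and resource intercepts and rescales
  # loadings so the scored class mixture hits `class_mixture`.
  m <- data.frame(
    column = c("weight_loss_5kg", "changed_walk_1km", "changed_climb_10steps",
               "changed_car_bus", "walk_outside_freq", "falls_12mo",
               "walk_500m", "moderate_activity_freq", "strenuous_activity_freq",
               "work_or_volunteer_7d", "fear_falling_limits"),
    role = c(rep("risk", 6), rep("resource", 5)),
    a = c(-2.44, -1.39, -1.27, -1.73, -1.10, -1.10,
          -1.39, -1.10, 0.41, 0.85, -1.73),
    b = c(0.8, 1.3, 1.3, 1.2, 1.2, 0.9,
          1.5, 1.1, 0.8, 0.6, 1.2),
    stringsAsFactors = FALSE
  )
  attr(m, "calibrated") <- FALSE
  m
}

.fa_default_freq_splits <- function() {
  # Conditional category splits for the 4-level frequency items and the
  # 3-level 500 m walk item, given the binary frail/robust direction drawn
  # from the logistic item model.
  list(
    walk_outside_freq = list(frail = c(never = 0.40, `1-2` = 0.60),
                             robust = c(`3-4` = 0.45, `5-7` = 0.55)),
    moderate_activity_freq = list(frail = c(never = 1),
                                  robust = c(`1-2` = 0.40, `3-4` = 0.35, `5-7` = 0.25)),
    strenuous_activity_freq = list(frail = c(never = 1),
                                   robust = c(`1-2` = 0.60, `3-4` = 0.30, `5-7` = 0.10)),
    walk_500m = list(frail = c(with_difficulty = 0.70, no = 0.30),
                     robust = c(yes = 1))
  )
}

.fa_default_age_model <- function() {
  data.frame(
    class = .fa_class4(),
    mean = c(70.0, 74.4, 75.2, 77.7),
    sd   = c(6.2, 7.5, 7.8, 7.8),
    min  = c(61.2, 61.7, 61.5, 61.4),
    max  = c(91.9, 93.7, 94.0, 96.8),
    stringsAsFactors = FALSE
  )
}

.fa_default_sex_model <- function() {
  data.frame(class = .fa_class4(),
             p_female = c(579 / 1022, 153 / 220, 123 / 172, 188 / 265),
             stringsAsFactors = FALSE)
}

.fa_default_covariate_model <- function() {
  # Per-class prevalences of the five binary health/demographic covariates,
  # plus the marginal rate at which each covariate is missing (MCAR),
  # reproducing the shifting complete-case denominators of real survey data.
  list(
    prevalence = data.frame(
      class = .fa_class4(),
      living_alone    = c(287 / 1005, 91 / 212, 69 / 165, 141 / 256),
      health_fairpoor = c(167 / 1006, 95 / 217, 74 / 168, 174 / 260),
      chronic_pain    = c(199 / 986, 96 / 210, 39 / 156, 119 / 243),
      depressed       = c(91 / 971, 34 / 212, 25 / 156, 61 / 243),
      poor_vision     = c(182 / 1014, 70 / 216, 57 / 170, 113 / 258),
      stringsAsFactors = FALSE
    ),
    missing_rate = c(living_alone = 41 / 1679, health_fairpoor = 28 / 1679,
                     chronic_pain = 84 / 1679, depressed = 97 / 1679,
                     poor_vision = 21 / 1679)
  )
}

.fa_default_hazard_model <- function() {
  # Cumulative event fractions at the follow-up horizon, per wave-1 class.
  # Death fractions are the observed 93-month class-specific mortality;
  # nursing-care fractions are loose, order-preserving targets taken from
  # the wave-2 care prevalences (the source tables do not report
  # class-specific care incidence directly). shape = 1 gives constant
  # (exponential) hazards; other Weibull shapes are an extension hook.
  list(
    death_fraction = c(Robust = 97 / 1022, postRobust = 49 / 220,
                       preFrail = 47 / 172, Frail = 95 / 265),
    care_fraction = c(Robust = 0.025, postRobust = 0.036,
                      preFrail = 0.107, Frail = 0.225),
    shape = 1
  )
}

.fa_default_censoring_model <- function() {
  # Wave-2 loss-to-follow-up and refusal probabilities per wave-1 class
  # (unconditional fractions of the class). Refusal here means wave-2
  # questionnaire non-response, so the nine wave-2 returns that could not
  # be scored are folded into the Robust refusal count.
  data.frame(
    class = .fa_class4(),
    p_lost = c(33 / 1022, 10 / 220, 10 / 172, 14 / 265),
    p_refused = c(115 / 1022, 21 / 220, 31 / 172, 45 / 265),
    stringsAsFactors = FALSE
  )
}

.fa_default_transition_model <- function() {
  # Pooled-class wave-1 -> wave-2 outcome matrix, row-stochastic, built
  # from the published destination counts.
  m <- rbind(
    Robust    = c(519, 152, 106, 97, 33, 115) / 1022,
    Transient = c(48, 71, 105, 96, 20, 52) / 392,
    Frail     = c(9, 15, 87, 95, 14, 45) / 265
  )
  colnames(m) <- c("Robust", "Transient", "Frail", "dead", "lost", "refused")
  m
}

.fa_default_wave2_model <- function() {
  # Wave-2 health outcomes among wave-2 participants, by wave-1 class.
  list(
    falls = data.frame(
      class = .fa_class4(),
      p_once = c(104 / 767, 28 / 132, 17 / 82, 28 / 109),
      p_multi = c(53 / 767, 25 / 132, 11 / 82, 25 / 109),
      stringsAsFactors = FALSE
    ),
    p_adl = c(Robust = 17 / 774, postRobust = 10 / 135,
              preFrail = 13 / 83, Frail = 25 / 110),
    z_autocorrelation = 0.5
  )
}

#' Build a synthetic-cohort simulation configuration
#'
#' Assembles (and validates) every generator parameter. Defaults reproduce
#' the statistical structure of the validation cohort: the four-class
#' mixture 60.9/13.1/10.2/15.8%, class-specific age, sex and covariate
#' distributions, class-specific 93-month death fractions
#' (9.5/22.3/27.3/35.8%), wave-2 loss and refusal fractions, and the
#' pooled-class six-year transition matrix. Class membership is emergent:
#' items are generated from a latent-frailty logistic model and scored with
#' [fa_score_cohort()]; `class_mixture` is the calibration target for that
#' item model, not a direct class draw.
#'
#' @param n cohort size (default 1679).
#' @param seed integer RNG seed; required, no default randomness.
#' @param class_mixture length-4 probability vector over
#'   Robust/postRobust/preFrail/Frail (sums to 1).
#' @param item_model data.frame of per-item intercepts `a` and loadings `b`
#'   on the latent frailty trait (see the default for the layout).
#' @param calibrate if `TRUE` (default) the item model is calibrated to
#'   `class_mixture` before generation (see [fa_calibrate_items()]).
#' @param freq_splits conditional category splits for the multi-level items.
#' @param age_model per-class truncated-normal age parameters (years).
#' @param sex_model per-class probability of being female.
#' @param covariate_model per-class covariate prevalences and MCAR
#'   missing-data rates.
#' @param hazard_model cumulative 93-month death and nursing-care fractions
#'   per class, plus a Weibull `shape` (1 = exponential).
#' @param censoring_model per-class wave-2 loss and refusal probabilities.
#' @param transition_model 3x6 row-stochastic matrix over pooled wave-1
#'   class x wave-2 outcome.
#' @param wave2_model wave-2 health-outcome probabilities by wave-1 class
#'   and the latent-trait autocorrelation between waves.
#' @param horizon_months follow-up length (default 93).
#' @param wave2_month months from wave 1 to the wave-2 questionnaire
#'   (default 72, i.e. six years).
#' @return object of class `fa_sim_config` (a validated named list).
#' @examples
#' cfg <- fa_sim_config(n = 500, seed = 1, calibrate = FALSE)
#' str(cfg, max.level = 1)
#' @export
fa_sim_config <- function(n = 1679L,
                          seed,
                          class_mixture = c(Robust = 1022, postRobust = 220,
                                            preFrail = 172, Frail = 265) / 1679,
                          item_model = .fa_default_item_model(),
                          calibrate = TRUE,
                          freq_splits = .fa_default_freq_splits(),
                          age_model = .fa_default_age_model(),
                          sex_model = .fa_default_sex_model(),
                          covariate_model = .fa_default_covariate_model(),
                          hazard_model = .fa_default_hazard_model(),
                          censoring_model = .fa_default_censoring_model(),
                          transition_model = .fa_default_transition_model(),
                          wave2_model = .fa_default_wave2_model(),
                          horizon_months = 93,
                          wave2_month = 72) {
  if (missing(seed)) fa_stop("a seed is required: the generator has no default randomness")
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    class_mixture = class_mixture, item_model = item_model,
    calibrate = isTRUE(calibrate), freq_splits = freq_splits,
    age_model = age_model, sex_model = sex_model,
    covariate_model = covariate_model, hazard_model = hazard_model,
    censoring_model = censoring_model, transition_model = transition_model,
    wave2_model = wave2_model,
    horizon_months = horizon_months, wave2_month = wave2_month
  )
  class(cfg) <- "fa_sim_config"
  fa_validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks structural invariants: the class mixture and every transition row
#' sum to 1, probabilities lie in \\[0, 1\\], event fractions are below 1
#' (a fraction of exactly 1 would need an infinite hazard), the horizon is
#' positive, and per-class tables cover all four classes.
#'
#' @param config an `fa_sim_config` (or plain list with the same fields).
#' @return `config`, invisibly, or an error describing the violation.
#' @export
fa_validate_config <- function(config) {
  need <- c("n", "seed", "class_mixture", "item_model", "freq_splits",
            "age_model", "sex_model", "covariate_model", "hazard_model",
            "censoring_model", "transition_model", "wave2_model",
            "horizon_months", "wave2_month")
  miss <- setdiff(need, names(config))
  if (length(miss)) fa_stop("config is missing field(s): ", paste(miss, collapse = ", "))
  if (config$n < 0) fa_stop("n must be >= 0")
  if (length(config$seed) != 1L || is.na(config$seed)) fa_stop("seed must be a single integer")
  cm <- config$class_mixture
  if (length(cm) != 4L || any(cm < 0) || abs(sum(cm) - 1) > 1e-6) {
    fa_stop("class_mixture must be 4 nonnegative probabilities summing to 1")
  }
  tm <- config$transition_model
  if (!is.matrix(tm) || nrow(tm) != 3L || ncol(tm) != 6L) {
    fa_stop("transition_model must be a 3x6 matrix (pooled class x outcome)")
  }
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-6)) {
    fa_stop("every transition_model row must be nonnegative and sum to 1")
  }
  hz <- config$hazard_model
  for (fld in c("death_fraction", "care_fraction")) {
    f <- hz[[fld]]
    if (length(f) != 4L || any(f < 0) || any(f >= 1)) {
      fa_stop(fld, " must be 4 fractions in [0, 1)")
    }
  }
  if (hz$shape <= 0) fa_stop("hazard shape must be positive")
  if (config$horizon_months <= 0) fa_stop("horizon_months must be positive")
  if (config$wave2_month <= 0 || config$wave2_month > config$horizon_months) {
    fa_stop("wave2_month must lie in (0, horizon_months]")
  }
  cen <- config$censoring_model
  if (any(cen$p_lost < 0) || any(cen$p_refused < 0) ||
      any(cen$p_lost + cen$p_refused +
            config$hazard_model$death_fraction > 1 + 1e-9)) {
    fa_stop("per-class death + lost + refused fractions must not exceed 1")
  }
  im <- config$item_model
  if (!all(c("column", "role", "a", "b") %in% names(im)) ||
      !setequal(im$column, fa_questions()$column)) {
    fa_stop("item_model must have columns (column, role, a, b) covering all 11 questions")
  }
  invisible(config)
}

#' @export
print.fa_sim_config <- function(x, ...) {
  cat("FA synthetic-cohort configuration\n")
  cat(sprintf("  n = %d, seed = %d, horizon = %g months (wave 2 at %g)\n",
              x$n, x$seed, x$horizon_months, x$wave2_month))
  cat("  target class mixture: ",
      paste(sprintf("%s %.1f%%", fa_levels(), 100 * x$class_mixture), collapse = ", "), "\n")
  cat(sprintf("  item model %scalibrated; death fractions %s\n",
              if (isTRUE(attr(x$item_model, "calibrated"))) "" else "not yet ",
              paste(sprintf("%.1f%%", 100 * x$hazard_model$death_fraction), collapse = "/")))
  invisible(x)
}

# serialization ---------------------------------------------------------------

.fa_config_known_keys <- function() {
  c("n", "seed", "class_mixture", "item_model", "calibrate", "freq_splits",
    "age_model", "sex_model", "covariate_model", "hazard_model",
    "censoring_model", "transition_model", "wave2_model",
    "horizon_months", "wave2_month")
}

#' Write a simulation configuration to YAML or JSON
#'
#' @param config an `fa_sim_config`.
#' @param path output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
fa_write_config <- function(config, path) {
  ser <- unclass(config)
  ser$item_model <- as.list(as.data.frame(ser$item_model))
  ser$transition_model <- list(rows = rownames(config$transition_model),
                               cols = colnames(config$transition_model),
                               values = unname(apply(config$transition_model, 1, c, simplify = FALSE)))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(ser, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    fa_stop("config path must end in .yaml, .yml or .json")
  }
  invisible(path)
}

#' Read and validate a simulation configuration
#'
#' Unknown top-level keys are rejected by name, so typos fail loudly rather
#' than silently falling back to defaults.
#'
#' @param path YAML or JSON file written by [fa_write_config()], or any
#'   subset of its keys; omitted keys take the package defaults.
#' @return a validated `fa_sim_config`.
#' @export
fa_read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    fa_stop("config path must end in .yaml, .yml or .json")
  }
  unknown <- setdiff(names(raw), .fa_config_known_keys())
  if (length(unknown)) {
    fa_stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(raw$seed)) fa_stop("config must provide a seed")
  args <- list(seed = raw$seed)
  for (k in setdiff(names(raw), "seed")) args[[k]] <- raw[[k]]
  if (!is.null(args$item_model)) {
    args$item_model <- as.data.frame(args$item_model, stringsAsFactors = FALSE)
    attr(args$item_model, "calibrated") <- FALSE
  }
  if (!is.null(args$transition_model) && is.list(args$transition_model) &&
      !is.data.frame(args$transition_model)) {
    tmr <- args$transition_model
    m <- if (is.matrix(tmr$values)) tmr$values else
      do.call(rbind, lapply(tmr$values, unlist))
    rownames(m) <- unlist(tmr$rows); colnames(m) <- unlist(tmr$cols)
    args$transition_model <- m
  } else if (!is.null(args$transition_model)) {
    args$transition_model <- as.matrix(args$transition_model)
  }
  if (!is.null(args$class_mixture)) args$class_mixture <- unlist(args$class_mixture)
  do.call(fa_sim_config, args)
}
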