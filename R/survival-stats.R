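# Censored time-to-event analysis, built on the survival package: product-
# limit and actuarial survival estimates, the k-sample log-rank test, and
# proportional-hazards regression with a likelihood-ratio test for the FA
# class factor after covariate adjustment. Drop-outs enter as censored
# observations, never by deletion; administrative censoring at the
# follow-up horizon is part of the sample, not of these functions.

#' Kaplan-Meier (product-limit) survival estimate
#'
#' @param time positive follow-up times (months).
#' @param event 1 = event, 0 = censored.
#' @param group optional grouping factor (one curve per level).
#' @return object of class `fa_km`: `curves`, a data.frame with `group`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv` (the estimate starts
#'   at S(0) = 1 and drops only at event times), and `all_censored`, a
#'   named logical flagging groups without any event (their curve is
#'   identically 1, with a warning).
#' @examples
#' km <- fa_km(c(1, 2, 3, 4, 5), c(1, 1, 0, 0, 0))
#' km$curves
#' @export
fa_km <- function(time, event, group = NULL) {
  if (any(time <= 0)) fa_stop("follow-up times must be positive")
  if (is.null(group)) group <- rep("all", length(time))
  group <- factor(group)
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(group)[1L], length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, n_censor = sm$n.censor,
                       surv = sm$surv, stringsAsFactors = FALSE)
  all_cens <- tapply(df$event, df$group, function(e) sum(e) == 0L)
  if (any(all_cens)) {
    warning("group(s) with no events: survival curve is identically 1 for ",
            paste(names(all_cens)[all_cens], collapse = ", "), call. = FALSE)
  }
  structure(list(curves = curves, all_censored = all_cens),
            class = "fa_km")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km an [fa_km()] object.
#' @param t times at which to evaluate S(t).
#' @param group which curve (default: the first).
#' @return numeric vector S(t) (right-continuous step function, S(0) = 1).
#' @export
fa_km_surv <- function(km, t, group = NULL) {
  cur <- km$curves
  if (is.null(group)) group <- cur$group[1L]
  cur <- cur[cur$group == group, , drop = FALSE]
  if (nrow(cur) == 0L) fa_stop("no curve for group '", group, "'")
  sf <- stats::stepfun(cur$time, c(1, cur$surv), right = FALSE)
  sf(t)
}

#' @export
print.fa_km <- function(x, ...) {
  cat("Kaplan-Meier estimate:", length(unique(x$curves$group)), "curve(s),",
      nrow(x$curves), "time points\n")
  invisible(x)
}

#' Actuarial (interval-based) life table
#'
#' Classical life-table estimator on fixed intervals: withdrawals in an
#' interval contribute half an interval of exposure, so the effective
#' number at risk is `n - w/2`.
#'
#' @param time follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param breaks interval boundaries starting at 0 (e.g. `seq(0, 93, 3)`);
#'   times beyond the last break are carried as withdrawals at the end.
#' @return data.frame with one row per interval: `start`, `end`, `n_enter`,
#'   `n_event`, `n_withdraw`, `n_effective`, `q` (conditional event
#'   probability) and `surv` (cumulative survival to the interval end).
#' @export
fa_lifetable <- function(time, event, breaks) {
  if (breaks[1L] != 0) fa_stop("breaks must start at 0")
  if (is.unsorted(breaks, strictly = TRUE)) fa_stop("breaks must be strictly increasing")
  k <- length(breaks) - 1L
  n_enter <- n_event <- n_withdraw <- integer(k)
  alive <- rep(TRUE, length(time))
  out <- data.frame(start = breaks[-(k + 1L)], end = breaks[-1L])
  surv <- 1
  svec <- qvec <- neff <- numeric(k)
  for (j in seq_len(k)) {
    at_risk <- alive & time > breaks[j]
    in_int <- alive & time > breaks[j] & time <= breaks[j + 1L]
    n_enter[j] <- sum(at_risk)
    n_event[j] <- sum(in_int & event == 1)
    n_withdraw[j] <- sum(in_int & event == 0)
    neff[j] <- n_enter[j] - n_withdraw[j] / 2
    qvec[j] <- if (neff[j] > 0) n_event[j] / neff[j] else 0
    surv <- surv * (1 - qvec[j])
    svec[j] <- surv
    alive <- alive & !in_int
  }
  cbind(out, data.frame(n_enter = n_enter, n_event = n_event,
                        n_withdraw = n_withdraw, n_effective = neff,
                        q = qvec, surv = svec))
}

#' k-sample log-rank test
#'
#' Compares censored survival distributions across k groups: at every event
#' time, expected events per group are proportional to the numbers at risk;
#' the statistic is the quadratic form of observed-minus-expected counts
#' against their covariance, referred to chi-square on k - 1 degrees of
#' freedom.
#'
#' @param time follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group grouping factor with at least two non-empty levels.
#' @return object of class `fa_logrank`: `statistic`, `df`, `p_value`,
#'   `observed` and `expected` per-group event counts.
#' @examples
#' set.seed(1)
#' g <- rep(c("a", "b"), each = 30)
#' t <- rexp(60, ifelse(g == "a", 0.02, 0.05))
#' fa_logrank(t, rep(1, 60), g)
#' @export
fa_logrank <- function(time, event, group) {
  if (!is.factor(group)) group <- factor(group)
  sizes <- table(group)
  if (length(sizes) < 2L) fa_stop("log-rank test needs at least 2 groups")
  if (any(sizes == 0L)) {
    fa_stop("group(s) with zero subjects: ",
            paste(names(sizes)[sizes == 0L], collapse = ", "))
  }
  if (sum(event) < 1L) fa_stop("log-rank test needs at least one event")
  df <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(sizes)
  structure(list(statistic = unname(sd$chisq), df = k - 1L,
                 p_value = stats::pchisq(sd$chisq, k - 1L, lower.tail = FALSE),
                 observed = stats::setNames(as.numeric(sd$obs), levels(group)),
                 expected = stats::setNames(as.numeric(sd$exp), levels(group))),
            class = "fa_logrank")
}

#' @export
print.fa_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g, %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(data.frame(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}

#' Proportional-hazards regression with an FA-class likelihood-ratio test
#'
#' Fits a Cox model of the event hazard on the FA class (entered as a
#' categorical factor, reference level first) plus optional adjustment
#' covariates, maximizing the partial likelihood with the Efron tie
#' correction by default. Reports the likelihood-ratio test of the model
#' with versus without the class factor — i.e. whether the class carries
#' prognostic information beyond the covariates.
#'
#' @param time follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group class factor (k levels gives k - 1 dummies and a k - 1 df
#'   likelihood-ratio test).
#' @param covariates optional data.frame of adjustment covariates (rows
#'   with missing values are dropped from both fits, complete-case).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `fa_coxph`: `coefficients` (log hazard ratios,
#'   standard errors, z, p), `loglik_full`, `loglik_reduced`, `lr_statistic`,
#'   `lr_df`, `lr_p`, `n`, `n_events`, and the underlying `fit`.
#' @export
fa_coxph <- function(time, event, group, covariates = NULL,
                     ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  group <- factor(group)
  if (sum(event) < 1L) fa_stop("proportional-hazards fit needs events")
  dat <- data.frame(.time = time, .event = event, .group = group)
  covnames <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covnames <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$.group <- droplevels(dat$.group)
  if (nlevels(dat$.group) < 2L) fa_stop("class factor must have at least 2 observed levels")
  rhs_red <- if (length(covnames)) paste(covnames, collapse = " + ") else "1"
  f_full <- stats::as.formula(paste("survival::Surv(.time, .event) ~ .group +", rhs_red))
  f_red <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs_red))
  fit_full <- withCallingHandlers(
    survival::coxph(f_full, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        fa_stop("proportional-hazards fit failed (", conditionMessage(w),
                "): likely complete separation or a monotone likelihood")
      }
      invokeRestart("muffleWarning")
    })
  if (any(is.na(stats::coef(fit_full)))) {
    fa_stop("collinear covariates: coefficient(s) not estimable: ",
            paste(names(stats::coef(fit_full))[is.na(stats::coef(fit_full))],
                  collapse = ", "))
  }
  fit_red <- survival::coxph(f_red, data = dat, ties = ties)
  ll_full <- fit_full$loglik[length(fit_full$loglik)]
  ll_red <- fit_red$loglik[length(fit_red$loglik)]
  lr <- 2 * (ll_full - ll_red)
  lr_df <- nlevels(dat$.group) - 1L
  co <- summary(fit_full)$coefficients
  coefs <- data.frame(term = sub("^\\.group", "class", rownames(co)),
                      loghr = co[, "coef"], hr = co[, "exp(coef)"],
                      se = co[, "se(coef)"], z = co[, "z"],
                      p = co[, "Pr(>|z|)"], row.names = NULL)
  structure(list(coefficients = coefs, loglik_full = ll_full,
                 loglik_reduced = ll_red, lr_statistic = lr, lr_df = lr_df,
                 lr_p = stats::pchisq(lr, lr_df, lower.tail = FALSE),
                 n = nrow(dat), n_events = sum(dat$.event),
                 ties = ties, fit = fit_full),
            class = "fa_coxph")
}

#' @export
print.fa_coxph <- function(x, ...) {
  cat(sprintf("Proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  print(transform(x$coefficients, loghr = round(loghr, 4), hr = round(hr, 4),
                  se = round(se, 4), z = round(z, 2), p = signif(p, 3)))
  cat(sprintf("Class likelihood ratio = %.4g, %d df, p = %.4g\n",
              x$lr_statistic, x$lr_df, x$lr_p))
  invisible(x)
}
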