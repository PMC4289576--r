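# Independent oracles, deliberately coded differently from the package
# implementations they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# classification oracle: direct cell lookup in a 7x7 matrix indexed by the
# raw scores, built cell by cell from the class-grid definition
oracle_class_grid <- local({
  g <- matrix(NA_character_, 7, 7,
              dimnames = list(risk = 0:6, resource = 0:6))
  for (r in 0:6) for (s in 0:6) {
    g[r + 1, s + 1] <- if (s >= 3) {
      if (r >= 3) "postRobust" else "Robust"
    } else {
      if (r >= 3) "Frail" else "preFrail"
    }
  }
  g
})

oracle_classify <- function(risk, resource) {
  oracle_class_grid[cbind(risk + 1L, resource + 1L)]
}

# brute-force product-limit estimator
oracle_km <- function(time, event, at) {
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  vapply(at, function(tt) {
    below <- ev_times <= tt
    if (!any(below)) 1 else surv[max(which(below))]
  }, numeric(1))
}

# brute-force k-sample log-rank: loop over event times, accumulate O, E and
# the hypergeometric covariance, then form the quadratic form on the first
# k-1 groups
oracle_logrank <- function(time, event, group) {
  group <- factor(group)
  k <- nlevels(group)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    nj <- vapply(levels(group), function(g) sum(at_risk & group == g), numeric(1))
    dj <- vapply(levels(group), function(g) sum(time == t & event == 1 & group == g),
                 numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      for (a in 1:k) for (b in 1:k) {
        kr <- if (a == b) 1 else 0
        V[a, b] <- V[a, b] + d * (nj[a] / n) * (kr - nj[b] / n) * (n - d) / (n - 1)
      }
    }
  }
  u <- (O - E)[-k]
  stat <- drop(t(u) %*% solve(V[-k, -k, drop = FALSE]) %*% u)
  list(statistic = stat, observed = O, expected = E)
}

# mid-rank Pearson correlation written out longhand
oracle_spearman <- function(x, y) {
  rk <- function(v) {
    sapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    })
  }
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Efron partial log-likelihood for a single covariate, maximized by
# 1-d optimization (independent route to the PH point estimate)
oracle_cox_efron <- function(time, event, x) {
  logpl <- function(beta) {
    eta <- beta * x
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      risk <- time >= t
      dset <- time == t & event == 1
      d <- sum(dset)
      sum_risk <- sum(exp(eta[risk]))
      sum_d <- sum(exp(eta[dset]))
      ll <- ll + sum(eta[dset])
      for (l in seq_len(d) - 1) {
        ll <- ll - log(sum_risk - (l / d) * sum_d)
      }
    }
    ll
  }
  stats::optimize(logpl, c(-5, 5), maximum = TRUE)$maximum
}

# complete "all good answers" and "all bad answers" questionnaire records
good_record <- function() {
  data.frame(weight_loss_5kg = "no", changed_walk_1km = "no",
             changed_climb_10steps = "no", changed_car_bus = "no",
             walk_outside_freq = "5-7", falls_12mo = "no", walk_500m = "yes",
             moderate_activity_freq = "1-2", strenuous_activity_freq = "1-2",
             work_or_volunteer_7d = "yes", fear_falling_limits = "no",
             stringsAsFactors = FALSE)
}

bad_record <- function() {
  data.frame(weight_loss_5kg = "yes", changed_walk_1km = "yes",
             changed_climb_10steps = "yes", changed_car_bus = "yes",
             walk_outside_freq = "never", falls_12mo = "yes", walk_500m = "no",
             moderate_activity_freq = "never", strenuous_activity_freq = "never",
             work_or_volunteer_7d = "no", fear_falling_limits = "yes",
             stringsAsFactors = FALSE)
}

# shared mid-size default cohort, generated once per test run
default_cohort <- local({
  cache <- NULL
  function(n = 20000L, seed = 4242L) {
    if (is.null(cache)) {
      cache <<- fa_generate_cohort(fa_sim_config(n = n, seed = seed))
    }
    cache
  }
})
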