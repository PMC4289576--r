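test_that("product-limit estimate matches hand arithmetic and flags no-event input", {
  # events at t=1 (1 of 5 at risk) then t=2 (1 of 4): S = 4/5, then 4/5*3/4
  km <- fa_km(1:5, c(1, 1, 0, 0, 0))
  expect_equal(fa_km_surv(km, c(0.5, 1, 1.5, 2, 10)), c(1, 0.8, 0.8, 0.6, 0.6))
  expect_warning(km0 <- fa_km(1:5, rep(0, 5)), "no events")
  expect_true(km0$all_censored[["all"]])
  expect_equal(fa_km_surv(km0, 1:5), rep(1, 5))
  expect_error(fa_km(c(0, 1), c(1, 1)), "positive")
})

test_that("product-limit estimate agrees with a brute-force oracle under censoring", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 40
    time <- round(rexp(n, 0.1), 1) + 0.1
    event <- rbinom(n, 1, 0.7)
    km <- fa_km(time, event)
    at <- sort(unique(time))
    expect_equal(fa_km_surv(km, at), oracle_km(time, event, at))
  }
})

test_that("without censoring the product-limit estimate is one minus the ECDF", {
  set.seed(8)
  time <- rexp(500, 0.05)
  km <- fa_km(time, rep(1, 500))
  at <- quantile(time, c(.1, .25, .5, .75, .9))
  expect_equal(fa_km_surv(km, at), 1 - ecdf(time)(at), tolerance = 1e-12)
})

test_that("the actuarial life table follows the half-withdrawal convention", {
  # worked example: 4 subjects, breaks (0,1,2,4)
  #  interval 1: 4 enter, 1 event           -> q = 1/4,  S = 0.75
  #  interval 2: 3 enter, 1 event, 1 w/d    -> n' = 2.5, q = .4, S = 0.45
  #  interval 3: 1 enters, 1 withdrawal     -> q = 0,    S = 0.45
  lt <- fa_lifetable(c(0.5, 1.5, 1.7, 3), c(1, 1, 0, 0), c(0, 1, 2, 4))
  expect_equal(lt$n_effective, c(4, 2.5, 0.5))
  expect_equal(lt$surv, c(0.75, 0.45, 0.45))
  expect_error(fa_lifetable(1, 1, c(1, 2)), "start at 0")
})

test_that("log-rank statistic is zero for symmetric groups and matches the oracle", {
  # identical event-time multisets in equally sized groups: O = E
  t0 <- c(1, 3, 5, 7)
  lr0 <- fa_logrank(c(t0, t0), rep(1, 8), rep(c("a", "b"), each = 4))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)

  # printed 6-subject fixture against the brute-force O/E/V computation
  time <- c(2, 4, 4, 6, 8, 9)
  event <- c(1, 1, 0, 1, 1, 0)
  grp <- c("a", "b", "a", "b", "a", "b")
  lr <- fa_logrank(time, event, grp)
  or <- oracle_logrank(time, event, grp)
  expect_equal(lr$statistic, or$statistic, tolerance = 1e-10)
  expect_equal(unname(lr$observed), unname(or$observed))
  expect_equal(unname(lr$expected), unname(or$expected), tolerance = 1e-10)
  expect_equal(sum(lr$observed), sum(lr$expected))

  # random censored datasets, two and three groups
  set.seed(17)
  for (k in c(2, 3)) {
    for (rep in 1:8) {
      n <- 15 * k
      time <- round(rexp(n, 0.1), 1) + 0.1
      event <- rbinom(n, 1, 0.8)
      grp <- sample(letters[1:k], n, replace = TRUE)
      if (length(unique(grp)) < k || sum(event) == 0) next
      lr <- fa_logrank(time, event, grp)
      or <- oracle_logrank(time, event, grp)
      expect_equal(lr$statistic, or$statistic, tolerance = 1e-8)
      expect_equal(lr$df, k - 1)
    }
  }
})

test_that("log-rank input contracts are enforced", {
  expect_error(fa_logrank(1:4, rep(1, 4), rep("a", 4)), "at least 2 groups")
  expect_error(fa_logrank(1:4, rep(1, 4), factor(c("a", "a", "b", "b"),
                                                 levels = c("a", "b", "c"))),
               "zero subjects")
  expect_error(fa_logrank(1:4, rep(0, 4), c("a", "a", "b", "b")),
               "at least one event")
})

test_that("log-rank is invariant under monotone time transformations", {
  set.seed(33)
  time <- rexp(80, 0.1) + 0.01
  event <- rbinom(80, 1, 0.7)
  grp <- rep(c("a", "b"), 40)
  s1 <- fa_logrank(time, event, grp)$statistic
  expect_equal(fa_logrank(time^2, event, grp)$statistic, s1, tolerance = 1e-12)
  expect_equal(fa_logrank(log(time + 1), event, grp)$statistic, s1, tolerance = 1e-12)
})

test_that("proportional-hazards fit recovers null and non-null hazard ratios", {
  set.seed(41)
  # null: common exponential, binary covariate
  g <- rep(0:1, each = 1000)
  t <- rexp(2000, 0.05)
  fit0 <- fa_coxph(t, rep(1, 2000), factor(g))
  expect_lt(abs(fit0$coefficients$loghr[1]), 0.15)

  # true hazard ratio 2
  t2 <- rexp(2000, ifelse(g == 1, 0.10, 0.05))
  fit2 <- fa_coxph(t2, rep(1, 2000), factor(g))
  # se(loghr) ~ sqrt(2/1000) = 0.045; allow 4 standard errors
  expect_lt(abs(fit2$coefficients$loghr[1] - log(2)), 0.18)
})

test_that("the partial-likelihood maximum agrees with a 1-d grid oracle", {
  set.seed(55)
  x <- rbinom(60, 1, 0.5)
  t <- rexp(60, 0.05 * exp(0.7 * x))
  ev <- rbinom(60, 1, 0.85)
  fit <- fa_coxph(t, ev, factor(x))
  expect_equal(fit$coefficients$loghr[1], oracle_cox_efron(t, ev, x),
               tolerance = 1e-4)
})

test_that("the class likelihood-ratio test is a nonnegative nested comparison", {
  co <- default_cohort()
  i <- seq_len(3000)
  fit <- fa_coxph(co$time_death[i], co$event_death[i], co$fa_class[i],
                  covariates = data.frame(age = co$age[i], sex = co$sex[i]))
  expect_equal(fit$lr_statistic,
               2 * (fit$loglik_full - fit$loglik_reduced))
  expect_gte(fit$lr_statistic, 0)
  expect_equal(fit$lr_df, 3L)
  # an irrelevant covariate has a small LR against its own reduced model
  expect_lt(fit$lr_p, 0.05)  # class is genuinely prognostic in this design
})

test_that("degenerate proportional-hazards designs error with diagnostics", {
  # complete separation: all events in one group before any in the other
  t <- c(1, 2, 3, 10, 11, 12)
  ev <- rep(1, 6)
  g <- factor(rep(c("a", "b"), each = 3))
  expect_error(fa_coxph(t, ev, g), "separation|monotone|failed")
  # collinear covariates
  set.seed(3)
  tt <- rexp(100, 0.1); x <- rnorm(100)
  expect_error(fa_coxph(tt, rep(1, 100), factor(rep(0:1, 50)),
                        covariates = data.frame(a = x, b = 2 * x)),
               "collinear|failed")
})

test_that("survival curves of the synthetic classes are ordered Robust above Frail", {
  co <- default_cohort()
  km <- fa_km(co$time_death, co$event_death, co$fa_class)
  s93 <- vapply(fa_levels(), function(g) fa_km_surv(km, 93, g), numeric(1))
  expect_true(s93[["Robust"]] > s93[["postRobust"]])
  expect_true(s93[["postRobust"]] > s93[["Frail"]])
  expect_true(s93[["preFrail"]] > s93[["Frail"]])
})
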