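test_that("rank correlation hits the exact extremes and handles ties via mid-ranks", {
  expect_equal(fa_spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(fa_spearman(1:10, rev(1:10))$rho, -1)
  expect_equal(fa_spearman(1:10, (1:10)^3)$p_value, 0)

  # tied fixture, n = 8: mid-rank Pearson computed longhand
  x <- c(1, 2, 2, 3, 3, 3, 4, 5)
  y <- c(2, 1, 3, 3, 4, 4, 5, 5)
  r <- fa_spearman(x, y)
  expect_equal(r$rho, oracle_spearman(x, y), tolerance = 1e-12)
  # and agrees with the reference implementation
  expect_equal(r$rho, unname(cor(x, y, method = "spearman")), tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-10)

  # complete-case pairs and degenerate input
  r2 <- fa_spearman(c(1, 2, 3, NA, 5), c(2, 1, NA, 4, 5))
  expect_equal(r2$n, 3L)
  expect_true(fa_spearman(rep(1, 5), 1:5)$degenerate)
  expect_error(fa_spearman(1:2, 1:2), "at least 3")
})

test_that("Fisher's exact test enumerates the diagonal 5x5 table to 1/126", {
  f <- fa_fisher(matrix(c(5, 0, 0, 5), 2))
  expect_equal(f$p_value, 1 / 126, tolerance = 1e-12)
  expect_equal(f$method, "enumeration")
  # identical rows are perfectly homogeneous
  expect_equal(fa_fisher(matrix(c(7, 7, 3, 3), 2))$p_value, 1)
  # empty margin: p = 1 by convention, flagged
  d <- fa_fisher(matrix(c(0, 0, 3, 4), 2))
  expect_equal(d$p_value, 1)
  expect_true(d$degenerate)
  expect_error(fa_fisher(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("2xk Monte-Carlo branch reproduces the enumerated p within its error", {
  tab <- matrix(c(8, 2, 5, 5, 3, 7, 1, 9), 2)   # 2x4, total 40
  exact <- fa_fisher(tab)
  expect_equal(exact$method, "enumeration")
  mc <- fa_fisher(tab, enum_limit = 0L, mc_draws = 2e5)
  expect_equal(mc$method, "monte_carlo")
  expect_lt(abs(mc$p_value - exact$p_value), 4 * mc$mc_se + 1e-5)
  # the Monte-Carlo substream does not disturb the global RNG state
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(fa_fisher(tab, enum_limit = 0L, mc_draws = 1e4))
  expect_equal(runif(1), before)
})

test_that("Welch t-test matches longhand arithmetic on a small fixture", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4)
  w <- fa_welch(x, y)
  # longhand Welch-Satterthwaite
  se2 <- var(x) / 5 + var(y) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 5)^2 / 4 + (var(y) / 5)^2 / 4)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-10)
  expect_equal(w$p_value, 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical groups
  expect_equal(fa_welch(x, x)$t, 0)
  # constant equal groups: p = 1, not an error
  expect_equal(fa_welch(rep(2, 5), rep(2, 4))$p_value, 1)
  # shifted distributions at large n: p tends to zero
  set.seed(6)
  expect_lt(fa_welch(rnorm(5000), rnorm(5000, 0.5))$p_value, 1e-10)
})

test_that("transition summary reproduces the printed row percentages", {
  w1 <- rep(c("Robust", "Transient", "Frail"), times = c(1022, 392, 265))
  w2 <- c(rep(c("Robust", "Transient", "Frail", "dead", "lost", "refused",
                "unscorable"), times = c(519, 152, 106, 97, 33, 106, 9)),
          rep(c("Robust", "Transient", "Frail", "dead", "lost", "refused"),
              times = c(48, 71, 105, 96, 20, 52)),
          rep(c("Robust", "Transient", "Frail", "dead", "lost", "refused"),
              times = c(9, 15, 87, 95, 14, 45)))
  tr <- fa_transition_summary(w1, w2)
  expect_equal(unname(tr$row_n), c(1022, 392, 265))
  expect_equal(unname(tr$percent["Robust", c("Robust", "Transient", "Frail", "dead")]),
               c(50.8, 14.9, 10.4, 9.5))
  expect_equal(tr$percent["Transient", "Frail"], 26.8)
  expect_equal(tr$percent["Transient", "dead"], 24.5)
  expect_equal(tr$percent["Frail", "dead"], 35.8)
  expect_equal(tr$percent["Frail", "Transient"], 5.7)
  expect_equal(tr$percent["Frail", "Robust"], 3.4)
  # row sums and percentage reproducibility from the counts
  expect_equal(unname(rowSums(tr$counts)), unname(tr$row_n))
  for (g in rownames(tr$counts)) {
    expect_equal(unname(tr$percent[g, ]), unname(pct(tr$counts[g, ], tr$row_n[[g]])))
    expect_lt(abs(sum(tr$percent[g, ]) - 100), 0.3)   # rounding slack only
  }
})

test_that("transition summary pools 4-level origins and rejects unknown tokens", {
  tr <- fa_transition_summary(c("postRobust", "preFrail"), c("dead", "Frail"))
  expect_equal(unname(tr$row_n), c(0, 2, 0))
  expect_error(fa_transition_summary("Robust", "vanished"),
               "unknown wave-2 outcome token.*vanished")
  expect_error(fa_transition_summary("Sturdy", "dead"), "unknown wave-1")
  # empty input: empty summary, not an error
  tr0 <- fa_transition_summary(character(0), character(0))
  expect_equal(sum(tr0$counts), 0L)
  expect_true(all(is.na(tr0$percent)))
})

test_that("class profile reports complete-case cases/n (%) cells", {
  n <- 1679
  cohort <- data.frame(
    fa_class = factor(rep(fa_levels(), times = c(1022, 220, 172, 265)),
                      levels = fa_levels()),
    age = 70, sex = rep(c("female", "male"), length.out = n),
    living_alone = c(rep(1L, 588), rep(0L, 1050), rep(NA, 41))
  )
  prof <- fa_class_profile(cohort)
  cell <- prof$covariates[prof$covariates$group == "ALL" &
                            prof$covariates$variable == "living_alone", ]
  expect_equal(cell$cases, 588)
  expect_equal(cell$n, 1638)
  expect_equal(cell$percent, 35.9)
  expect_equal(cell$cell, "588/1638 (35.9)")
  # all-missing covariate: denominator 0, cell NA
  cohort$poor_vision <- NA_integer_
  prof2 <- fa_class_profile(cohort)
  pv <- prof2$covariates[prof2$covariates$variable == "poor_vision" &
                           prof2$covariates$group == "ALL", ]
  expect_equal(pv$n, 0)
  expect_true(is.na(pv$percent))
})

test_that("generated per-class prevalences feed through the profile table", {
  co <- default_cohort()
  prof <- fa_class_profile(co)
  prev <- attr(co, "config")$covariate_model$prevalence
  for (k in seq_along(fa_levels())) {
    cell <- prof$covariates[prof$covariates$group == fa_levels()[k] &
                              prof$covariates$variable == "health_fairpoor", ]
    expect_lt(abs(cell$percent - 100 * prev$health_fairpoor[k]), 2)
  }
})

test_that("class-ordinal correlations with health measures are positive", {
  co <- default_cohort()
  cors <- fa_correlations(co)
  expect_true(all(cors$rho[cors$variable %in%
                             c("age", "health_fairpoor", "poor_vision")] > 0))
  expect_true(all(cors$n <= nrow(co)))
})
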