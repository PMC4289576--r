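test_that("constant-hazard calibration inverts the cumulative fraction exactly", {
  expect_equal(fa_calibrate_hazard(0, 50), 0)
  expect_equal(fa_calibrate_hazard(0.5, 93), log(2) / 93)
  expect_error(fa_calibrate_hazard(1, 93), "infinite hazard")
  expect_error(fa_calibrate_hazard(-0.1, 93))
  # simulated event fraction at the horizon matches the closed form
  set.seed(314)
  lam <- fa_calibrate_hazard(0.358, 93)
  t <- rexp(50000, lam)
  se <- sqrt(0.358 * (1 - 0.358) / 50000)
  expect_lt(abs(mean(t <= 93) - 0.358), 4 * se)
})

test_that("a degenerate item model with zero loadings yields an all-Robust cohort", {
  im <- fa_sim_config(n = 1, seed = 1, calibrate = FALSE)$item_model
  im$b <- 0
  im$a <- -20           # frail-direction probability ~ 0 for every item
  # with deterministic items only Robust wave-2 records are reachable, so
  # keep the survivors' transition destinations inside their own class
  tm <- cbind(diag(3), matrix(0, 3, 3))
  dimnames(tm) <- list(fa_levels(pooled = TRUE),
                       c(fa_levels(pooled = TRUE), "dead", "lost", "refused"))
  cfg <- fa_sim_config(n = 200, seed = 5, item_model = im, calibrate = FALSE,
                       transition_model = tm)
  co <- fa_generate_cohort(cfg)
  expect_true(all(co$fa_class == "Robust"))
  part <- co$w2_outcome %in% fa_levels(pooled = TRUE)
  expect_true(all(co$w2_outcome[part] == "Robust"))
})

test_that("an infeasible item model fails calibration with diagnostics", {
  im <- fa_sim_config(n = 1, seed = 1, calibrate = FALSE)$item_model
  im$b <- 0             # no latent dependence: mixture cells unreachable
  cfg <- fa_sim_config(n = 100, seed = 5, item_model = im, calibrate = TRUE)
  expect_error(fa_generate_cohort(cfg), "calibration failure")
})

test_that("an empty cohort is returned for n = 0, with all columns present", {
  co <- fa_generate_cohort(fa_sim_config(n = 0, seed = 9, calibrate = FALSE))
  expect_equal(nrow(co), 0L)
  expect_true(all(c("fa_class", "time_death", "w2_outcome") %in% names(co)))
  ct <- fa_class_table(co$fa_class)
  expect_equal(sum(ct$n), 0L)
})

test_that("generation is byte-identical for identical config and seed", {
  cfg <- fa_sim_config(n = 400, seed = 123)
  a <- fa_generate_cohort(cfg)
  b <- fa_generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- fa_generate_cohort(fa_sim_config(n = 400, seed = 124))
  expect_false(identical(a$z, c2$z))
})

test_that("scored class shares converge to the configured mixture", {
  co <- default_cohort()          # n = 20000 at the default configuration
  ct <- fa_class_table(co$fa_class)
  target <- c(60.9, 13.1, 10.2, 15.8)
  expect_true(all(abs(ct$percent - target) < 2))
})

test_that("risk and resource scores are negatively correlated", {
  co <- default_cohort()
  expect_lt(fa_spearman(co$risk_score, co$resource_score)$rho, 0)
})

test_that("per-class death fractions at the horizon match the hazard model", {
  co <- default_cohort()
  cfg <- attr(co, "config")
  for (k in seq_along(fa_levels())) {
    cls <- fa_levels()[k]
    i <- co$fa_class == cls
    target <- cfg$hazard_model$death_fraction[[cls]]
    se <- sqrt(target * (1 - target) / sum(i))
    expect_lt(abs(mean(co$death_time_true[i] <= 93) - target), 3 * se)
  }
})

test_that("wave-2 outcome draws follow the transition matrix rows", {
  tm <- fa_sim_config(n = 1, seed = 1, calibrate = FALSE)$transition_model
  # degenerate identity row
  tid <- tm; tid["Robust", ] <- c(1, 0, 0, 0, 0, 0)
  set.seed(77)
  expect_true(all(fa_sample_wave2(rep("Robust", 200), tid) == "Robust"))
  expect_error(fa_sample_wave2("Fragile", tm), "unknown class")
  # Monte-Carlo draws recover the configured fractions
  set.seed(78)
  rob <- fa_sample_wave2(rep("Robust", 50000), tm)
  expect_lt(abs(mean(rob == "Robust") - 519 / 1022), 3 * sqrt(0.508 * 0.492 / 50000))
  fr <- fa_sample_wave2(rep("Frail", 50000), tm)
  expect_lt(abs(mean(fr == "dead") - 95 / 265), 3 * sqrt(0.358 * 0.642 / 50000))
})

test_that("the generated cohort recovers the transition matrix end to end", {
  co <- default_cohort()
  cfg <- attr(co, "config")
  tr <- fa_transition_summary(as.character(co$pooled_class), co$w2_outcome)
  for (g in rownames(cfg$transition_model)) {
    got <- tr$counts[g, colnames(cfg$transition_model)] / tr$row_n[[g]]
    want <- cfg$transition_model[g, ]
    se <- sqrt(pmax(want * (1 - want), 1e-4) / tr$row_n[[g]])
    expect_true(all(abs(got - want) < 4 * se),
                info = paste("transition row", g))
  }
})

test_that("cohort-level consistency invariants hold", {
  co <- default_cohort()
  horizon <- attr(co, "config")$horizon_months
  # observed follow-up is the minimum of event, censoring and horizon
  expect_equal(co$time_death, pmin(co$death_time_true, co$censor_time, horizon))
  expect_true(all(co$event_death == (co$death_time_true <= pmin(co$censor_time, horizon))))
  # nursing-care follow-up additionally censors at death
  expect_true(all(co$time_care <= pmin(co$death_time_true, co$censor_time, horizon)))
  # nobody needs nursing care at wave 1
  expect_true(all(co$care_time_true > 0))
  # wave-2 record present iff the outcome is a class, and consistent with it
  is_class <- co$w2_outcome %in% fa_levels(pooled = TRUE)
  expect_equal(!is.na(co$w2_fa_class), is_class)
  expect_equal(co$w2_pooled_class[is_class], co$w2_outcome[is_class])
  expect_true(all(is.na(co$w2_weight_loss_5kg[!is_class])))
  # the raw transition draw is retained for audit
  expect_true(all(co$w2_raw_draw %in% colnames(attr(co, "config")$transition_model)))
  # hazard-model deaths override the raw draw
  expect_true(all(co$w2_outcome[co$death_time_true <= horizon] == "dead"))
})

test_that("class-conditional covariates and ages match the configuration", {
  co <- default_cohort()
  cfg <- attr(co, "config")
  prev <- cfg$covariate_model$prevalence
  am <- cfg$age_model
  for (k in seq_along(fa_levels())) {
    i <- co$fa_class == fa_levels()[k]
    expect_true(all(co$age[i] >= am$min[k] & co$age[i] <= am$max[k]))
    expect_lt(abs(mean(co$age[i]) - am$mean[k]), 1)
    p <- prev$health_fairpoor[k]
    expect_lt(abs(mean(co$health_fairpoor[i], na.rm = TRUE) - p),
              3 * sqrt(p * (1 - p) / sum(i)) + 0.005)
    pf <- cfg$sex_model$p_female[k]
    expect_lt(abs(mean(co$sex[i] == "female") - pf),
              3 * sqrt(pf * (1 - pf) / sum(i)))
  }
  # covariate missingness reproduces shifting denominators
  expect_gt(sum(is.na(co$depressed)), 0)
})

test_that("config serialization round-trips through YAML and JSON", {
  cfg <- fa_sim_config(n = 50, seed = 31, calibrate = FALSE)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    fa_write_config(cfg, path)
    back <- fa_read_config(path)
    expect_equal(back$n, cfg$n)
    expect_equal(back$seed, cfg$seed)
    expect_equal(unname(back$class_mixture), unname(cfg$class_mixture),
                 tolerance = 1e-6)
    expect_equal(unname(back$transition_model), unname(cfg$transition_model),
                 tolerance = 1e-6)
    expect_equal(back$item_model$a, cfg$item_model$a, tolerance = 1e-6)
  }
})

test_that("config validation rejects structural violations", {
  expect_error(fa_sim_config(n = 10, seed = 1, class_mixture = c(.5, .5, .1, .1)),
               "sum")
  cfg <- fa_sim_config(n = 10, seed = 1, calibrate = FALSE)
  cfg$transition_model[1, ] <- c(2, 0, 0, 0, 0, 0)
  expect_error(fa_validate_config(cfg), "sum to 1")
  cfg2 <- fa_sim_config(n = 10, seed = 1, calibrate = FALSE)
  cfg2$hazard_model$death_fraction[1] <- 1
  expect_error(fa_validate_config(cfg2), "fractions")
  expect_error(fa_sim_config(n = 10), "seed")
})
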