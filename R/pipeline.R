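# Pipeline: simulate -> score -> analyze -> report, with a run manifest so
# identical (config, seed) runs are verifiably identical, and an analysis
# log that records the complete-case exclusions behind every shifting
# denominator.

#' Simulate a cohort to disk
#'
#' Generates a cohort from a configuration and writes `cohort.csv`,
#' `events.csv`, the resolved `config.json` and a `manifest.json` with the
#' seed, config hash and per-file checksums. On failure, partial outputs
#' are removed.
#'
#' @param config an [fa_sim_config()], or a path to a YAML/JSON config.
#' @param out_dir output directory (created if needed).
#' @return invisible list: `cohort` and `manifest`.
#' @export
fa_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- fa_read_config(config)
  fa_validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("cohort.csv", "events.csv", "config.json",
                                "manifest.json"))
  names(paths) <- c("cohort", "events", "config", "manifest")
  ok <- FALSE
  on.exit(if (!ok) unlink(paths[file.exists(paths)]))
  cohort <- fa_generate_cohort(config)
  utils::write.csv(cohort, paths["cohort"], row.names = FALSE, na = "")
  fa_events(cohort, paths["events"])
  fa_write_config(attr(cohort, "config"), paths["config"])
  checksums <- tools::md5sum(paths[c("cohort", "events", "config")])
  names(checksums) <- basename(names(checksums))
  manifest <- list(
    package_version = as.character(utils::packageVersion("faindex")),
    seed = config$seed, n = config$n,
    config_hash = unname(tools::md5sum(paths["config"])),
    checksums = as.list(checksums),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(list(cohort = cohort, manifest = manifest))
}

#' Read a cohort CSV written by [fa_simulate()]
#'
#' @param path CSV path (empty cells become `NA`).
#' @return data.frame with class columns re-leveled.
#' @export
fa_read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if ("fa_class" %in% names(df)) df$fa_class <- factor(df$fa_class, fa_levels())
  if ("pooled_class" %in% names(df)) {
    df$pooled_class <- factor(df$pooled_class, fa_levels(pooled = TRUE))
  }
  df
}

#' Analyze a scored cohort
#'
#' Runs every analysis stage on a cohort table: class shares, the
#' demographic/covariate profile, rank correlations of the class with age
#' and health measures, per-class losses by cause, survival analyses for
#' death and nursing-care need (Kaplan-Meier curves, log-rank tests,
#' class-adjusted proportional-hazards fits), wave-2 health outcomes and
#' the wave-1 to wave-2 transition summary. Stages whose input columns are
#' absent, or that are degenerate (e.g. a single observed class makes a
#' log-rank test meaningless), are skipped with an explicit notice in
#' `$notes`; complete-case exclusions per stage are recorded in
#' `$exclusions`.
#'
#' @param cohort a cohort data.frame (e.g. from [fa_generate_cohort()] or
#'   [fa_read_cohort()]) or a path to `cohort.csv`. Must contain scored
#'   class columns; if only raw questionnaire columns are present it is
#'   scored first.
#' @param out_dir optional directory: every result table is also written
#'   as a tidy CSV plus a human-readable `report.txt`.
#' @return object of class `fa_analysis` (a named list of result objects,
#'   `notes` and `exclusions`).
#' @export
fa_analyze <- function(cohort, out_dir = NULL) {
  if (is.character(cohort)) cohort <- fa_read_cohort(cohort)
  if (!("fa_class" %in% names(cohort))) {
    check_columns(cohort, fa_questions()$column, "cohort")
    cohort <- fa_score_cohort(cohort)
  }
  notes <- character(0)
  excl <- list()
  res <- list()

  n_total <- nrow(cohort)
  scorable <- !is.na(cohort$fa_class)
  excl$scoring <- c(total = n_total, unscorable = sum(!scorable))
  res$class_table <- fa_class_table(cohort$fa_class)

  if ("age" %in% names(cohort)) {
    res$profile <- fa_class_profile(cohort)
    res$correlations <- fa_correlations(cohort)
    cls <- as.character(cohort$fa_class)
    if (all(c("Robust", "Frail") %in% cls)) {
      res$age_welch <- fa_welch(cohort$age[cls == "Robust" & !is.na(cls)],
                                cohort$age[cls == "Frail" & !is.na(cls)])
    }
  } else {
    notes <- c(notes, "no 'age' column: profile and correlation stages skipped")
  }

  scls <- droplevels(factor(cohort$fa_class[scorable]))
  for (ep in c("death", "care")) {
    tcol <- paste0("time_", ep); ecol <- paste0("event_", ep)
    if (!all(c(tcol, ecol) %in% names(cohort))) {
      notes <- c(notes, sprintf("no %s/%s columns: %s survival stage skipped",
                                tcol, ecol, ep))
      next
    }
    keep <- scorable & !is.na(cohort[[tcol]]) & !is.na(cohort[[ecol]])
    excl[[paste0("survival_", ep)]] <- c(total = n_total, excluded = sum(!keep))
    tt <- cohort[[tcol]][keep]; ee <- cohort[[ecol]][keep]
    gg <- droplevels(factor(cohort$fa_class[keep]))
    res[[paste0("km_", ep)]] <- fa_km(tt, ee, gg)
    if (nlevels(gg) < 2L) {
      notes <- c(notes, sprintf(
        "log-rank (%s) skipped: only one observed class (%s)", ep, levels(gg)))
    } else if (sum(ee) == 0L) {
      notes <- c(notes, sprintf("log-rank (%s) skipped: no events", ep))
    } else {
      res[[paste0("logrank_", ep)]] <- fa_logrank(tt, ee, gg)
      adj <- intersect(c("age", "sex", "health_fairpoor"), names(cohort))
      if (length(adj)) {
        covs <- cohort[keep, adj, drop = FALSE]
        fit <- try(fa_coxph(tt, ee, gg, covariates = covs), silent = TRUE)
        if (inherits(fit, "try-error")) {
          notes <- c(notes, sprintf("proportional-hazards (%s) failed: %s",
                                    ep, attr(fit, "condition")$message))
        } else {
          res[[paste0("coxph_", ep)]] <- fit
          excl[[paste0("coxph_", ep)]] <-
            c(total = sum(keep), excluded = sum(keep) - fit$n)
        }
      }
    }
  }

  if ("w2_outcome" %in% names(cohort)) {
    keep <- scorable & !is.na(cohort$w2_outcome)
    excl$transitions <- c(total = n_total, excluded = sum(!keep))
    res$transitions <- fa_transition_summary(
      as.character(cohort$pooled_class[keep]), cohort$w2_outcome[keep])
    w2cols <- intersect(c("w2_falls", "w2_adl", "w2_care"), names(cohort))
    if (length(w2cols)) {
      part <- keep & cohort$w2_outcome %in% fa_levels(pooled = TRUE)
      res$wave2_health <- do.call(rbind, lapply(fa_levels(), function(g) {
        i <- part & as.character(cohort$fa_class) == g
        row <- data.frame(class = g, n_participants = sum(i))
        if ("w2_falls" %in% w2cols) {
          nf <- sum(i & !is.na(cohort$w2_falls))
          row$falls_once <- pct(sum(cohort$w2_falls[i] == "once", na.rm = TRUE), nf)
          row$falls_multi <- pct(sum(cohort$w2_falls[i] == "multi", na.rm = TRUE), nf)
        }
        if ("w2_adl" %in% w2cols) {
          row$adl_dependent <- pct(sum(cohort$w2_adl[i], na.rm = TRUE),
                                   sum(i & !is.na(cohort$w2_adl)))
        }
        if ("w2_care" %in% w2cols) {
          row$nursing_care <- pct(sum(cohort$w2_care[i], na.rm = TRUE),
                                  sum(i & !is.na(cohort$w2_care)))
        }
        row
      }))
    }
  } else {
    notes <- c(notes, "no 'w2_outcome' column: transition stage skipped")
  }

  res$notes <- notes
  res$exclusions <- excl
  class(res) <- "fa_analysis"
  if (!is.null(out_dir)) fa_write_analysis(res, out_dir)
  res
}

#' Write an analysis bundle to disk
#'
#' Tidy CSV per result table plus a formatted `report.txt`.
#'
#' @param analysis an `fa_analysis` from [fa_analyze()].
#' @param out_dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
fa_write_analysis <- function(analysis, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, na = "")
    written <<- c(written, p)
  }
  put(analysis$class_table, "class_table")
  if (!is.null(analysis$profile)) {
    put(analysis$profile$age, "profile_age")
    put(analysis$profile$covariates, "profile_covariates")
  }
  if (!is.null(analysis$correlations)) put(analysis$correlations, "correlations")
  for (ep in c("death", "care")) {
    km <- analysis[[paste0("km_", ep)]]
    if (!is.null(km)) put(km$curves, paste0("km_", ep))
    lr <- analysis[[paste0("logrank_", ep)]]
    if (!is.null(lr)) {
      put(data.frame(statistic = lr$statistic, df = lr$df, p_value = lr$p_value),
          paste0("logrank_", ep))
    }
    cx <- analysis[[paste0("coxph_", ep)]]
    if (!is.null(cx)) put(cx$coefficients, paste0("coxph_", ep))
  }
  if (!is.null(analysis$transitions)) {
    tr <- analysis$transitions
    long <- expand.grid(origin = rownames(tr$counts),
                        destination = colnames(tr$counts),
                        stringsAsFactors = FALSE)
    long$count <- as.vector(tr$counts)
    long$row_n <- tr$row_n[long$origin]
    long$percent <- as.vector(tr$percent)
    put(long, "transitions")
  }
  if (!is.null(analysis$wave2_health)) put(analysis$wave2_health, "wave2_health")
  rep_path <- file.path(out_dir, "report.txt")
  writeLines(fa_report(analysis), rep_path)
  invisible(c(written, rep_path))
}

#' Render an analysis as a human-readable report
#'
#' @param analysis an `fa_analysis`.
#' @return character vector of report lines.
#' @export
fa_report <- function(analysis) {
  out <- utils::capture.output({
    cat("Functional Ability index: cohort analysis report\n")
    cat(strrep("=", 49), "\n\n")
    cat("Class shares (scorable respondents):\n")
    print(analysis$class_table, row.names = FALSE)
    ct <- analysis$class_table
    cat(sprintf("  scorable n = %d, unscorable excluded = %d\n\n",
                attr(ct, "n_scorable"), attr(ct, "n_unscorable")))
    if (!is.null(analysis$profile)) { print(analysis$profile); cat("\n") }
    if (!is.null(analysis$age_welch)) {
      w <- analysis$age_welch
      cat(sprintf("Age, Robust vs Frail (Welch): t = %.2f, df = %.1f, p = %.2g\n\n",
                  w$t, w$df, w$p_value))
    }
    if (!is.null(analysis$correlations)) {
      cat("Rank correlations of FA class (0-3) with:\n")
      print(transform(analysis$correlations, rho = round(rho, 4),
                      p_value = signif(p_value, 3)), row.names = FALSE)
      cat("\n")
    }
    for (ep in c("death", "care")) {
      lab <- if (ep == "death") "Mortality" else "Need of nursing care"
      lr <- analysis[[paste0("logrank_", ep)]]
      cx <- analysis[[paste0("coxph_", ep)]]
      if (!is.null(lr) || !is.null(cx)) cat(lab, ":\n", sep = "")
      if (!is.null(lr)) print(lr)
      if (!is.null(cx)) print(cx)
      if (!is.null(lr) || !is.null(cx)) cat("\n")
    }
    if (!is.null(analysis$transitions)) { print(analysis$transitions); cat("\n") }
    if (!is.null(analysis$wave2_health)) {
      cat("Wave-2 health outcomes among participants, % by wave-1 class:\n")
      print(analysis$wave2_health, row.names = FALSE)
      cat("\n")
    }
    if (length(analysis$notes)) {
      cat("Notices:\n")
      for (nt in analysis$notes) cat("  -", nt, "\n")
      cat("\n")
    }
    if (length(analysis$exclusions)) {
      cat("Complete-case exclusions per stage:\n")
      for (nm in names(analysis$exclusions)) {
        e <- analysis$exclusions[[nm]]
        cat(sprintf("  %-16s %s\n", nm,
                    paste(names(e), e, sep = " = ", collapse = ", ")))
      }
    }
  })
  out
}

#' @export
print.fa_analysis <- function(x, ...) {
  cat(fa_report(x), sep = "\n")
  invisible(x)
}

#' Built-in consistency checks
#'
#' Sweeps every reachable indicator vector through the classifier against
#' an inline lookup of the class grid, and re-derives small closed-form
#' statistical fixtures (product-limit arithmetic, the 5x5 diagonal exact
#' test, perfect rank correlations). Stops on the first failure.
#'
#' @return `TRUE`, invisibly, if all checks pass.
#' @export
fa_selftest <- function() {
  checks <- 0L
  ok <- function(cond, what) {
    if (!isTRUE(cond)) fa_stop("selftest failed: ", what)
    checks <<- checks + 1L
  }
  grid_lookup <- function(risk, resource) {
    if (risk <= 2 && resource >= 3) "Robust"
    else if (risk >= 3 && resource >= 3) "postRobust"
    else if (risk <= 2 && resource <= 2) "preFrail"
    else "Frail"
  }
  # every reachable (risk, resource) pair: 10 free indicators plus the
  # shared outside-walk item contributing to exactly one of the two sums
  free <- expand.grid(rep(list(0:1), 10L))
  for (w in 0:1) {
    risk <- rowSums(free[, 1:5]) + w
    res <- rowSums(free[, 6:10]) + (1L - w)
    got <- as.character(fa_classify(risk, res))
    want <- mapply(grid_lookup, risk, res)
    ok(all(got == want), "classification grid sweep")
  }
  km <- fa_km(c(1, 2, 3, 4, 5), c(1, 1, 0, 0, 0))
  ok(isTRUE(all.equal(fa_km_surv(km, c(1, 2)), c(0.8, 0.6))),
     "product-limit arithmetic")
  f <- fa_fisher(matrix(c(5, 0, 0, 5), 2))
  ok(isTRUE(all.equal(f$p_value, 1 / 126)), "exact-test enumeration")
  ok(isTRUE(all.equal(fa_spearman(1:5, 1:5)$rho, 1)) &&
       isTRUE(all.equal(fa_spearman(1:5, 5:1)$rho, -1)),
     "rank-correlation extremes")
  message("selftest: ", checks, " checks passed")
  invisible(TRUE)
}
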