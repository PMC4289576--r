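# Non-survival statistics: Spearman rank correlations with mid-ranks for
# ties, Fisher's exact tests (2x2 and 2xk), Welch t-tests, per-class
# prevalence profiles, and the wave-1 -> wave-2 transition summary. All
# tests are complete-case: rows with missing values drop out of that
# analysis's denominator only.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' n - 2 degrees of freedom, two-sided. Pairs with a missing value in
#' either vector are excluded.
#'
#' @param x,y paired ordinal/numeric vectors.
#' @return list: `rho`, `n` (complete pairs), `p_value`, and `degenerate`
#'   (`TRUE`, with `rho = NA`, when either vector has zero variance).
#' @examples
#' fa_spearman(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
#' @export
fa_spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) fa_stop("Spearman correlation needs at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = NA_real_, n = n, p_value = NA_real_, degenerate = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, n = n, p_value = p, degenerate = FALSE)
}

#' Fisher's exact test for 2x2 and 2xk tables
#'
#' Two-sided p by summation of table probabilities no larger than the
#' observed one (the standard convention). 2x2 tables are enumerated via
#' the hypergeometric distribution; 2xk tables are enumerated exactly when
#' the total count is at most `enum_limit`, otherwise an exact Monte-Carlo
#' p-value is computed on a fixed substream with its simulation error
#' reported.
#'
#' @param tab matrix of nonnegative integer counts with 2 rows.
#' @param enum_limit largest total for full enumeration of 2xk tables
#'   (default 200).
#' @param mc_draws Monte-Carlo replicates beyond the limit (default 1e6).
#' @param mc_seed substream seed for the Monte-Carlo branch.
#' @return list: `p_value`, `method` (`"enumeration"` or `"monte_carlo"`),
#'   `mc_se` (NA unless Monte-Carlo), `degenerate` (`TRUE` with p = 1 when
#'   a margin is empty).
#' @examples
#' fa_fisher(matrix(c(5, 0, 0, 5), 2))   # 1/126
#' @export
fa_fisher <- function(tab, enum_limit = 200L, mc_draws = 1e6, mc_seed = 271828L) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L) fa_stop("fa_fisher expects a table with 2 rows")
  if (any(tab < 0) || any(tab != floor(tab))) fa_stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p_value = 1, method = "degenerate", mc_se = NA_real_,
                degenerate = TRUE))
  }
  if (ncol(tab) == 2L || sum(tab) <= enum_limit) {
    p <- stats::fisher.test(tab)$p.value
    list(p_value = min(p, 1), method = "enumeration", mc_se = NA_real_,
         degenerate = FALSE)
  } else {
    p <- withr_seed(mc_seed, stats::fisher.test(tab, simulate.p.value = TRUE,
                                                B = mc_draws)$p.value)
    list(p_value = p, method = "monte_carlo",
         mc_se = sqrt(p * (1 - p) / mc_draws), degenerate = FALSE)
  }
}

# evaluate expr under a temporary seed, restoring the RNG state after
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#' The degenerate case — both groups constant with equal means — returns
#' p = 1 instead of an error.
#'
#' @param x,y numeric samples (missing values dropped; at least 2 each).
#' @return list: `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
fa_welch <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) fa_stop("each group needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = NA_real_, p_value = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    }
    return(list(t = Inf * sign(mean(x) - mean(y)), df = NA_real_, p_value = 0,
                mean_x = mean(x), mean_y = mean(y)))
  }
  tt <- stats::t.test(x, y)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Wave-1 to wave-2 transition summary
#'
#' Cross-tabulates pooled wave-1 classes against wave-2 outcome categories
#' and reports counts with row percentages (one decimal, half away from
#' zero).
#'
#' @param w1_classes pooled wave-1 class labels (Robust/Transient/Frail);
#'   4-level labels are pooled automatically.
#' @param w2_outcomes outcome tokens: `Robust`, `Transient`, `Frail`,
#'   `dead`, `lost`, `refused`, `unscorable`. Any other token is an error
#'   naming the offending value.
#' @return object of class `fa_transition_summary`: integer matrix `counts`
#'   (3 x 7), matrix `percent`, vector `row_n`.
#' @examples
#' fa_transition_summary(c("Robust", "Robust", "Frail"),
#'                       c("Robust", "dead", "Transient"))
#' @export
fa_transition_summary <- function(w1_classes, w2_outcomes) {
  if (length(w1_classes) != length(w2_outcomes)) {
    fa_stop("wave-1 and wave-2 vectors must be aligned (equal length)")
  }
  w1 <- as.character(w1_classes)
  w1[w1 %in% c("postRobust", "preFrail")] <- "Transient"
  bad1 <- !is.na(w1) & !(w1 %in% fa_levels(pooled = TRUE))
  if (any(bad1)) {
    fa_stop("unknown wave-1 class token(s): ", paste(unique(w1[bad1]), collapse = ", "))
  }
  dest <- c(fa_levels(pooled = TRUE), "dead", "lost", "refused", "unscorable")
  w2 <- as.character(w2_outcomes)
  bad2 <- !is.na(w2) & !(w2 %in% dest)
  if (any(bad2)) {
    fa_stop("unknown wave-2 outcome token(s): ", paste(unique(w2[bad2]), collapse = ", "))
  }
  counts <- table(factor(w1, levels = fa_levels(pooled = TRUE)),
                  factor(w2, levels = dest))
  counts <- matrix(as.integer(counts), nrow = 3L,
                   dimnames = list(fa_levels(pooled = TRUE), dest))
  row_n <- rowSums(counts)
  percent <- counts
  for (i in seq_len(3L)) percent[i, ] <- pct(counts[i, ], row_n[i])
  structure(list(counts = counts, percent = percent, row_n = row_n),
            class = "fa_transition_summary")
}

#' @export
print.fa_transition_summary <- function(x, ...) {
  cat("Wave-1 class -> wave-2 outcome (counts, row % in brackets)\n")
  disp <- matrix(sprintf("%d (%s)", x$counts,
                         ifelse(is.na(x$percent), "NA", sprintf("%.1f", x$percent))),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(noquote(disp))
  invisible(x)
}

#' Per-class demographic and covariate profile
#'
#' The prevalence-table analogue: per class (plus the pooled Transient
#' column and the whole cohort), age mean/sd/min/max and, for each binary
#' covariate, complete-case cases/n and the percentage. Denominators shift
#' per cell because each covariate's missing values are excluded only from
#' its own row.
#'
#' @param cohort scored cohort with columns `fa_class`, `age`, `sex` and
#'   any of the binary covariate columns (0/1/NA): `living_alone`,
#'   `health_fairpoor`, `chronic_pain`, `depressed`, `poor_vision`.
#' @return object of class `fa_class_profile`: `age`, a data.frame of
#'   per-group age summaries, and `covariates`, a tidy data.frame with
#'   `group`, `variable`, `cases`, `n`, `percent`, `cell`
#'   ("cases/n (percent)").
#' @export
fa_class_profile <- function(cohort) {
  check_columns(cohort, c("fa_class", "age"), "cohort")
  cls <- as.character(cohort$fa_class)
  groups <- list(ALL = rep(TRUE, nrow(cohort)))
  for (g in fa_levels()) groups[[g]] <- !is.na(cls) & cls == g
  groups$Transient <- !is.na(cls) & cls %in% c("postRobust", "preFrail")
  age_tab <- do.call(rbind, lapply(names(groups), function(g) {
    a <- cohort$age[groups[[g]]]
    a <- a[!is.na(a)]
    data.frame(group = g, n = length(a),
               mean = if (length(a)) round_half_up(mean(a), 1) else NA_real_,
               sd = if (length(a) > 1) round_half_up(stats::sd(a), 1) else NA_real_,
               min = if (length(a)) min(a) else NA_real_,
               max = if (length(a)) max(a) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  vars <- intersect(c("female", "living_alone", "health_fairpoor",
                      "chronic_pain", "depressed", "poor_vision"),
                    c(names(cohort), if ("sex" %in% names(cohort)) "female"))
  get_var <- function(v) {
    if (v == "female") as.integer(cohort$sex == "female") else cohort[[v]]
  }
  cov_tab <- do.call(rbind, lapply(vars, function(v) {
    x <- get_var(v)
    do.call(rbind, lapply(names(groups), function(g) {
      xi <- x[groups[[g]]]
      n <- sum(!is.na(xi)); cases <- sum(xi, na.rm = TRUE)
      data.frame(group = g, variable = v, cases = cases, n = n,
                 percent = pct(cases, n),
                 cell = fmt_cases(cases, n), stringsAsFactors = FALSE)
    }))
  }))
  structure(list(age = age_tab, covariates = cov_tab),
            class = "fa_class_profile")
}

#' @export
print.fa_class_profile <- function(x, ...) {
  cat("Age by class:\n"); print(x$age, row.names = FALSE)
  if (!is.null(x$covariates) && nrow(x$covariates)) {
    cat("\nCovariate prevalence, cases/n (%):\n")
    wide <- stats::reshape(x$covariates[, c("group", "variable", "cell")],
                           idvar = "variable", timevar = "group",
                           direction = "wide")
    names(wide) <- sub("^cell\\.", "", names(wide))
    print(wide, row.names = FALSE)
  }
  invisible(x)
}

#' Rank correlations of the FA class with age and health measures
#'
#' Spearman correlations (complete-case per pair) of the ordinal class
#' encoding (Robust = 0 .. Frail = 3) with age and each available binary
#' health covariate.
#'
#' @param cohort scored cohort (see [fa_class_profile()] for columns).
#' @return data.frame: `variable`, `rho`, `n`, `p_value`.
#' @export
fa_correlations <- function(cohort) {
  check_columns(cohort, "fa_class", "cohort")
  ord <- fa_ordinal(cohort$fa_class)
  vars <- intersect(c("age", "health_fairpoor", "chronic_pain", "depressed",
                      "poor_vision", "living_alone"), names(cohort))
  do.call(rbind, lapply(vars, function(v) {
    r <- fa_spearman(ord, cohort[[v]])
    data.frame(variable = v, rho = r$rho, n = r$n, p_value = r$p_value,
               stringsAsFactors = FALSE)
  }))
}
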