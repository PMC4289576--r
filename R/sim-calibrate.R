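# Calibration of the latent-trait item model and of event-time hazards.
#
# Class membership in the generator is emergent: items are drawn from
# logistic models on a shared latent frailty trait z ~ N(0,1) and then
# scored. The class mixture is therefore an implicit function of the item
# intercepts and loadings. Calibration solves a 3-parameter problem — a
# common shift of the risk intercepts, a common shift of the resource
# intercepts, and a common rescaling of all loadings — so that the model's
# exact class-cell probabilities (computed by quadrature over z with
# Poisson-binomial score distributions) match the target mixture. The
# four-cell table has three degrees of freedom, so three parameters suffice.

# Poisson-binomial pmf for k independent Bernoulli columns, vectorized over
# rows (one row per quadrature node). p: matrix [m x k]. Returns [m x (k+1)]
# with column j+1 = P(sum = j).
.fa_poisbinom <- function(p) {
  m <- nrow(p); k <- ncol(p)
  pmf <- matrix(0, m, k + 1L)
  pmf[, 1L] <- 1
  for (j in seq_len(k)) {
    pj <- p[, j]
    pmf <- cbind(pmf * (1 - pj), 0) + cbind(0, pmf * pj)
  }
  pmf
}

# Exact class-cell probabilities for an item model, by quadrature over z.
# The outside-walk item W is handled separately: it adds 1 to the risk
# score when frail-direction, else 1 to the resource score, so risk and
# resource sums are conditionally dependent only through W.
.fa_cell_probs <- function(item_model, nodes = 241L, zmax = 6) {
  z <- seq(-zmax, zmax, length.out = nodes)
  w <- stats::dnorm(z); w <- w / sum(w)
  im <- item_model
  p_of <- function(cols) {
    sapply(cols, function(cn) {
      i <- match(cn, im$column)
      stats::plogis(im$a[i] + im$b[i] * z)
    })
  }
  risk5 <- c("weight_loss_5kg", "changed_walk_1km", "changed_climb_10steps",
             "changed_car_bus", "falls_12mo")
  res5 <- c("walk_500m", "moderate_activity_freq", "strenuous_activity_freq",
            "work_or_volunteer_7d", "fear_falling_limits")
  pR <- p_of(risk5)                      # frail-direction fires a risk
  pS <- 1 - p_of(res5)                   # robust-direction fires a resource
  pW <- p_of("walk_outside_freq")[, 1L]  # frail-direction of the shared item
  pmfR <- .fa_poisbinom(pR)              # [m x 6], sums 0..5
  pmfS <- .fa_poisbinom(pS)
  cdfR <- t(apply(pmfR, 1L, cumsum))     # P(R5 <= j)
  cdfS <- t(apply(pmfS, 1L, cumsum))
  le <- function(cdf, j) if (j < 0) rep(0, nrow(cdf)) else cdf[, min(j, 5L) + 1L]
  cells <- matrix(0, length(z), 4L, dimnames = list(NULL, fa_levels()))
  for (wv in 0:1) {
    pw <- if (wv == 1) pW else 1 - pW
    r_lo <- le(cdfR, 2L - wv)            # risk total <= 2
    s_hi <- 1 - le(cdfS, 1L + wv)        # resource total >= 3 (incl. 1-wv)
    cells[, "Robust"]     <- cells[, "Robust"]     + pw * r_lo * s_hi
    cells[, "postRobust"] <- cells[, "postRobust"] + pw * (1 - r_lo) * s_hi
    cells[, "preFrail"]   <- cells[, "preFrail"]   + pw * r_lo * (1 - s_hi)
    cells[, "Frail"]      <- cells[, "Frail"]      + pw * (1 - r_lo) * (1 - s_hi)
  }
  drop(crossprod(cells, w))
}

#' Calibrate the item model to the target class mixture
#'
#' Finds a common intercept shift for the risk items, a common intercept
#' shift for the resource items, and a common loading scale such that the
#' exact class-cell probabilities of the latent-trait item model (computed
#' by quadrature, no simulation) match `class_mixture`. Fails with
#' diagnostics if the optimizer cannot reach the target — e.g. when all
#' loadings are zero but the mixture requires dependence between the risk
#' and resource counts.
#'
#' @param config an [fa_sim_config()].
#' @param tol maximum tolerated absolute cell-probability error (default
#'   5e-4).
#' @return `config` with a calibrated `item_model` (attributes `calibrated`,
#'   `achieved` = the exact cell probabilities, `params` = the fitted shift
#'   and scale).
#' @examples
#' cfg <- fa_sim_config(n = 100, seed = 1, calibrate = FALSE)
#' cfg <- fa_calibrate_items(cfg)
#' attr(cfg$item_model, "achieved")
#' @export
fa_calibrate_items <- function(config, tol = 5e-4) {
  im0 <- config$item_model
  target <- config$class_mixture
  risk_rows <- im0$role == "risk"
  apply_par <- function(par) {
    im <- im0
    im$a[risk_rows] <- im$a[risk_rows] + par[1L]
    im$a[!risk_rows] <- im$a[!risk_rows] + par[2L]
    im$b <- im$b * exp(par[3L])
    im
  }
  obj <- function(par) {
    cells <- .fa_cell_probs(apply_par(par))
    sum((cells - target)^2)
  }
  fit <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  im <- apply_par(fit$par)
  achieved <- .fa_cell_probs(im)
  err <- max(abs(achieved - target))
  if (!is.finite(err) || err > tol) {
    fa_stop(sprintf(paste0(
      "item-model calibration failure: max cell error %.4g > %.4g\n",
      "  target:   %s\n  achieved: %s\n",
      "  (is the item model degenerate, e.g. all loadings zero?)"),
      err, tol,
      paste(sprintf("%.4f", target), collapse = " "),
      paste(sprintf("%.4f", achieved), collapse = " ")))
  }
  attr(im, "calibrated") <- TRUE
  attr(im, "achieved") <- achieved
  attr(im, "params") <- c(risk_shift = fit$par[1L], resource_shift = fit$par[2L],
                          loading_log_scale = fit$par[3L])
  config$item_model <- im
  config
}

#' Constant hazard matching a cumulative event fraction
#'
#' Solves `1 - exp(-lambda * horizon) = target_fraction` for the constant
#' (exponential) hazard rate `lambda`.
#'
#' @param target_fraction cumulative event probability at the horizon, in
#'   `[0, 1)`.
#' @param horizon follow-up length (months).
#' @return hazard rate per month (0 when the target fraction is 0).
#' @examples
#' fa_calibrate_hazard(0.5, 93)   # log(2)/93
#' @export
fa_calibrate_hazard <- function(target_fraction, horizon) {
  if (any(target_fraction < 0) || any(target_fraction >= 1)) {
    fa_stop("target_fraction must lie in [0, 1): a fraction of 1 needs an infinite hazard")
  }
  if (any(horizon <= 0)) fa_stop("horizon must be positive")
  -log(1 - target_fraction) / horizon
}

# Weibull(shape, scale) event times with the scale chosen so that the
# cumulative event fraction at `horizon` equals `fraction`; shape = 1 is
# exponential. fraction = 0 gives times beyond any horizon.
.fa_rtime <- function(n, fraction, horizon, shape = 1) {
  if (n == 0L) return(numeric(0))
  if (fraction <= 0) return(rep(Inf, n))
  scale <- horizon / (-log(1 - fraction))^(1 / shape)
  scale * (-log(1 - stats::runif(n)))^(1 / shape)
}
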