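#' Lagged log mortality rate
#'
#' The autoregressive terms of the model use the natural log of the outcome
#' rate in prior years. A continuity constant (default 0.5) keeps the log
#' finite and monotone when a state-year records zero deaths:
#' `a = log((y + cont) / N)`.
#'
#' @param y Nonnegative integer death counts.
#' @param N Positive populations.
#' @param cont Continuity constant added to the count, default 0.5.
#' @return Log rates, same length as `y`.
#' @export
lag_log_rate <- function(y, N, cont = 0.5) {
  if (any(N <= 0)) stop("population N must be positive")
  if (any(y < 0) || any(y != round(y))) stop("y must be nonnegative integers")
  log((y + cont) / N)
}

#' Negative binomial log density (mean-dispersion form)
#'
#' Log pmf of the negative binomial with mean `mu` and dispersion `phi`,
#' parameterized so that `Var = mu + mu^2 / phi`; `phi -> Inf` recovers the
#' Poisson. This is the likelihood kernel of the mortality model.
#'
#' @param y Nonnegative integer counts.
#' @param mu Positive means.
#' @param phi Positive dispersion (scalar or vector).
#' @return Log pmf values.
#' @export
nb_log_density <- function(y, mu, phi) {
  if (any(y < 0) || any(y != round(y))) stop("y must be nonnegative integers")
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(phi <= 0)) stop("phi must be positive")
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    phi * (log(phi) - log(phi + mu)) +
    y * (log(mu) - log(phi + mu))
}

#' Cumulative policy effect on the log rate
#'
#' For one state-year, the total contribution of all policies to the log
#' rate: the sum over policies of the instant effect scaled by exposure e
#' plus the phase-in slope scaled by the phase covariate f.
#'
#' @param beta_inst,beta_slope Numeric vectors of per-policy instant effects
#'   and phase-in slopes (equal length).
#' @param e,f Exposure and phase covariate vectors for the state-year (same
#'   length as the coefficient vectors).
#' @return The scalar log-rate shift `sum(beta_inst * e + beta_slope * f)`.
#' @export
cumulative_policy_effect <- function(beta_inst, beta_slope, e, f) {
  n <- length(beta_inst)
  if (length(beta_slope) != n || length(e) != n || length(f) != n)
    stop("beta_inst, beta_slope, e and f must have equal length")
  sum(beta_inst * e + beta_slope * f)
}

#' Construct a model parameter set
#'
#' Houses every free symbol of the mortality model: the intercept and year
#' effects (the first analysis year is the reference level, so `year[1]` is
#' fixed at 0 and the intercept `alpha` carries the baseline), confounder and
#' lasso-regularized covariate coefficients, the AR(1)/AR(2) coefficients on
#' lagged log rates, per-policy instant effects and phase-in slopes, and the
#' negative binomial dispersion. The total effect of policy p,
#' `theta_p = beta_inst_p + beta_slope_p`, is always derived, never free.
#'
#' @param alpha Intercept (log-rate scale contribution per year).
#' @param year Year-effect offsets, length = number of analysis years, first
#'   element 0.
#' @param beta_conf,beta_other Covariate coefficients.
#' @param rho1,rho2 AR coefficients on 1- and 2-year lagged log rates.
#' @param beta_inst,beta_slope Per-policy instant effects and phase-in
#'   slopes (equal length).
#' @param phi Negative binomial dispersion (> 0).
#' @return A list of class `"model_params"`.
#' @export
model_params <- function(alpha = 0, year = 0, beta_conf = numeric(),
                         beta_other = numeric(), rho1 = 0, rho2 = 0,
                         beta_inst = numeric(), beta_slope = numeric(),
                         phi = 10) {
  if (phi <= 0) stop("phi must be positive")
  if (length(beta_inst) != length(beta_slope))
    stop("beta_inst and beta_slope must have equal length")
  if (length(year) >= 1L && abs(year[1]) > 1e-12)
    stop("year[1] is the reference level and must be 0")
  structure(list(alpha = alpha, year = year, beta_conf = beta_conf,
                 beta_other = beta_other, rho1 = rho1, rho2 = rho2,
                 beta_inst = beta_inst, beta_slope = beta_slope, phi = phi),
            class = "model_params")
}

#' Total policy effects
#'
#' @param params A `"model_params"` object.
#' @return `beta_inst + beta_slope`, the per-policy total effects on the log
#'   rate at or beyond the phase-in horizon.
#' @export
total_effects <- function(params) params$beta_inst + params$beta_slope

#' Linear predictor of the debiased autoregressive model
#'
#' Computes, for every analysis row, the log mean
#' \deqn{\eta = \log N + \gamma_t + x'\beta + \rho_1 (a_1 - \Delta_1) +
#'   \rho_2 (a_2 - \Delta_2) + \Delta_t,}
#' where `a_k` is the lagged log rate k years back and `Delta_k` is the
#' cumulative policy effect evaluated at that lag. Subtracting `Delta_k`
#' before applying the AR coefficients adjusts the lags to their policy-free
#' counterfactual: conditioning on prior outcomes (which are themselves
#' affected by the policy) would otherwise attenuate the estimated effects,
#' and with the adjustment the equilibrium effect of a fully phased-in
#' policy on the log rate is exactly `theta_p` for any stationary AR
#' coefficients. `debias = FALSE` drops the adjustment (the naive
#' lagged-outcome model, kept for attenuation experiments).
#'
#' @param inputs A `"model_inputs"` object from [build_model_inputs()].
#' @param params A `"model_params"` object with dimensions matching `inputs`.
#' @param debias Apply the counterfactual lag adjustment? Default `TRUE`.
#' @return Numeric vector eta, one element per analysis row.
#' @export
linear_predictor <- function(inputs, params, debias = TRUE) {
  p <- params
  stopifnot(inherits(inputs, "model_inputs"))
  if (length(p$year) != inputs$n_years)
    stop("params$year has length ", length(p$year), ", expected ",
         inputs$n_years)
  if (length(p$beta_inst) != ncol(inputs$E))
    stop("policy coefficient length mismatch")
  if (anyNA(inputs$a1) || anyNA(inputs$a2)) stop("missing lagged log rates")
  d_t <- drop(inputs$E %*% p$beta_inst + inputs$F %*% p$beta_slope)
  d_1 <- drop(inputs$E1 %*% p$beta_inst + inputs$F1 %*% p$beta_slope)
  d_2 <- drop(inputs$E2 %*% p$beta_inst + inputs$F2 %*% p$beta_slope)
  eta <- inputs$log_N + p$alpha + p$year[inputs$year_idx] +
    drop(inputs$X_conf %*% p$beta_conf) +
    drop(inputs$X_other %*% p$beta_other) + d_t
  if (debias) {
    eta + p$rho1 * (inputs$a1 - d_1) + p$rho2 * (inputs$a2 - d_2)
  } else {
    eta + p$rho1 * inputs$a1 + p$rho2 * inputs$a2
  }
}

#' Assemble model inputs from a state-year panel and a policy panel
#'
#' Restricts to the analysis years, attaches the log-population offset,
#' builds lagged log rates from the two lead-in years (which are consumed
#' only as predictors), standardizes covariates to mean 0 / SD 1 over the
#' analysis rows, and attaches the policy exposure and phase matrices along
#' with their 1- and 2-year lags (needed by the debiasing adjustment).
#'
#' @param panel State-year data.frame with columns `state`, `year`,
#'   `population`, the outcome count column, and all covariate columns.
#' @param policy_panel A `"policy_panel"` covering the same states and years.
#' @param config List: `outcome` (count column name), `analysis_years`
#'   (default: panel years minus the first two), `conf_covariates` and
#'   `other_covariates` (character vectors of column names), `cont`
#'   (continuity constant, default 0.5).
#' @return A list of class `"model_inputs"`.
#' @export
build_model_inputs <- function(panel, policy_panel, config) {
  outcome <- config$outcome %||% "deaths_total"
  cont <- config$cont %||% 0.5
  conf_cols <- config$conf_covariates %||% character()
  other_cols <- config$other_covariates %||% character()
  states <- sort(unique(panel$state))
  all_years <- sort(unique(panel$year))
  analysis_years <- config$analysis_years %||% all_years[-(1:2)]
  analysis_years <- as.integer(analysis_years)
  lag_years <- c(min(analysis_years) - 2L, min(analysis_years) - 1L)
  need_years <- seq(lag_years[1], max(analysis_years))

  if (!all(lag_years %in% all_years))
    stop("panel must include at least 2 lead-in years before ",
         min(analysis_years))
  # completeness of the grid
  have <- paste(panel$state, panel$year)
  want <- paste(rep(states, each = length(need_years)),
                rep(need_years, times = length(states)))
  missing_rows <- setdiff(want, have)
  if (length(missing_rows))
    stop("missing state-years: ",
         paste(utils::head(missing_rows, 5), collapse = "; "))

  cols <- c("population", outcome, conf_cols, other_cols)
  miss_col <- setdiff(cols, names(panel))
  if (length(miss_col))
    stop("panel missing columns: ", paste(miss_col, collapse = ", "))
  sub <- panel[panel$year %in% need_years, c("state", "year", cols)]
  for (cl in cols) {
    bad <- which(is.na(sub[[cl]]))
    if (length(bad))
      stop("missing values in column '", cl, "' at ",
           paste(sprintf("%s %d", sub$state[bad[1]], sub$year[bad[1]]),
                 collapse = ", "))
  }
  if (any(sub$population <= 0)) stop("population must be positive")
  yv <- sub[[outcome]]
  if (any(yv < 0) || any(yv != round(yv)))
    stop("outcome '", outcome, "' must be nonnegative integer counts")

  sub <- sub[order(sub$state, sub$year), ]
  arow <- sub[sub$year %in% analysis_years, ]
  key <- function(st, yr) match(paste(st, yr), paste(sub$state, sub$year))
  i1 <- key(arow$state, arow$year - 1L)
  i2 <- key(arow$state, arow$year - 2L)
  a_all <- lag_log_rate(sub[[outcome]], sub$population, cont)

  std <- function(colnames_) {
    if (!length(colnames_))
      return(matrix(0, nrow(arow), 0))
    m <- as.matrix(arow[, colnames_, drop = FALSE])
    mu <- colMeans(m); sdv <- apply(m, 2, stats::sd)
    if (any(sdv == 0))
      stop("constant covariate cannot be standardized: ",
           paste(colnames_[sdv == 0], collapse = ", "))
    scale(m, center = mu, scale = sdv)[, , drop = FALSE]
  }

  pm <- policy_matrices(policy_panel)
  pp_years <- attr(policy_panel, "years")
  pidx <- function(yr) match(paste(arow$state, yr),
                             paste(pm$keys$state, pm$keys$year))
  if (!all(need_years %in% pp_years))
    stop("policy panel must cover years ", lag_years[1], "-",
         max(analysis_years))
  i0 <- pidx(arow$year); l1 <- pidx(arow$year - 1L); l2 <- pidx(arow$year - 2L)

  structure(list(
    y = as.integer(arow[[outcome]]),
    log_N = log(arow$population),
    N = arow$population,
    year_idx = match(arow$year, analysis_years),
    years = analysis_years,
    n_years = length(analysis_years),
    keys = arow[, c("state", "year")],
    states = states,
    X_conf = std(conf_cols),
    X_other = std(other_cols),
    a1 = a_all[i1],
    a2 = a_all[i2],
    E = pm$E[i0, , drop = FALSE], F = pm$F[i0, , drop = FALSE],
    E1 = pm$E[l1, , drop = FALSE], F1 = pm$F[l1, , drop = FALSE],
    E2 = pm$E[l2, , drop = FALSE], F2 = pm$F[l2, , drop = FALSE],
    outcome = outcome, cont = cont,
    horizon = attr(policy_panel, "horizon") %||% 5
  ), class = "model_inputs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Steady-state log-rate shift of a phased-in policy
#'
#' Runs the model's deterministic forward recursion (noise off, covariates
#' and year effects constant) through a policy switch-on with a linear
#' phase-in, and returns the long-run change in the log rate. With the
#' counterfactual-adjusted lags this equals `beta_inst + beta_slope` exactly
#' for any stationary AR coefficients; the naive variant attenuates it. Each
#' recursion step evaluates [linear_predictor()] on a one-row input, so the
#' check exercises the same code path as estimation.
#'
#' @param rho1,rho2 AR coefficients (stationary region).
#' @param beta_inst,beta_slope Scalar policy coefficients.
#' @param horizon Phase-in horizon in years, default 5.
#' @param n_burn,n_post Years simulated before and after switch-on.
#' @param debias Use the counterfactual lag adjustment? Default `TRUE`.
#' @return Scalar: steady-state log rate with the policy minus without.
#' @export
recursion_shift <- function(rho1, rho2, beta_inst, beta_slope, horizon = 5,
                            n_burn = 50, n_post = 400, debias = TRUE) {
  step <- function(a1, a2, e, f, e1, f1, e2, f2) {
    inp <- structure(list(
      log_N = 0, year_idx = 1L, n_years = 1L,
      X_conf = matrix(0, 1, 0), X_other = matrix(0, 1, 0),
      a1 = a1, a2 = a2,
      E = matrix(e, 1, 1), F = matrix(f, 1, 1),
      E1 = matrix(e1, 1, 1), F1 = matrix(f1, 1, 1),
      E2 = matrix(e2, 1, 1), F2 = matrix(f2, 1, 1)
    ), class = "model_inputs")
    par <- model_params(alpha = 0, year = 0, rho1 = rho1, rho2 = rho2,
                        beta_inst = beta_inst, beta_slope = beta_slope,
                        phi = 10)
    linear_predictor(inp, par, debias = debias) # log N = 0, so eta = log rate
  }
  run <- function(on_year, n_total) {
    a <- c(0, 0)
    for (t in seq_len(n_total)) {
      ys <- t - on_year
      e <- as.numeric(ys >= 0); f <- phase_in(ys, horizon)
      e1 <- as.numeric(ys - 1 >= 0); f1 <- phase_in(ys - 1, horizon)
      e2 <- as.numeric(ys - 2 >= 0); f2 <- phase_in(ys - 2, horizon)
      a <- c(step(a[1], a[2], e, f, e1, f1, e2, f2), a[1])
    }
    a[1]
  }
  n_total <- n_burn + n_post
  run(n_burn + 1, n_total) - run(n_total + 10, n_total)
}
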