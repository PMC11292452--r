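#' Synthetic-world configuration
#'
#' Describes the simulated study: grid size, years, covariate structure,
#' policy-adoption hazard and population. Defaults emulate the real study's
#' shape: 50 states observed 1979-2019 (the first two years consumed as
#' lags), 5 confounders and 23 other covariates evolving as stationary AR(1)
#' processes within state, constant populations of 5 million (isolating rate
#' dynamics from demographic drift), and policy adoption driven by a
#' logistic hazard on the first confounder (a firearm-ownership-rate proxy),
#' which also affects mortality — the confounded-adoption structure the
#' model must adjust for.
#'
#' @param n_states Number of states (>= 2), default 50.
#' @param years Output panel years, default 1979:2019.
#' @param n_conf,n_other Numbers of confounder / other covariates (5, 23).
#' @param burn_in Pre-panel years simulated to initialize lags near
#'   stationarity, default 10.
#' @param population Constant state population, default 5e6.
#' @param cov_ar AR(1) coefficient of covariate processes, default 0.9.
#' @param adoption_intercept,adoption_conf_coef Logistic hazard intercept
#'   and coefficient on the first confounder.
#' @param adopting_policies Policies eligible for adoption, default all ten.
#' @param horizon Phase-in horizon, default 5.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_states = 50, years = 1979:2019, n_conf = 5,
                       n_other = 23, burn_in = 10, population = 5e6,
                       cov_ar = 0.9, adoption_intercept = -3.5,
                       adoption_conf_coef = 0.8,
                       adopting_policies = policy_ids(), horizon = 5) {
  if (n_states < 2) stop("n_states must be >= 2")
  if (length(years) < 5) stop("need at least 5 years")
  structure(as.list(environment()), class = "sim_config")
}

state_codes <- function(n) {
  codes <- paste0(rep(LETTERS, each = 26), rep(LETTERS, times = 26))
  codes[seq_len(n)]
}

#' Ground-truth parameters for the generator
#'
#' The default stated world: one policy (dealer background checks) with a
#' total effect of log(0.9) — a detectable but prior-plausible 10% reduction
#' — split evenly between instant effect and phase-in slope; all other
#' policies null. Strong state persistence (rho1 = 0.6, rho2 = 0.2), a
#' baseline steady-state rate of about 12 deaths per 100,000, a real effect
#' of the adoption-driving confounder on mortality, moderate overdispersion
#' (phi = 30), and flat year effects.
#'
#' @param config A `"sim_config"`.
#' @param theta Total effect of the first adopting policy, default log(0.9).
#' @return List of class `"true_params"` with the generator's parameter
#'   fields and `year_offsets` named by calendar year.
#' @export
default_true_params <- function(config, theta = log(0.9)) {
  P <- length(policy_ids())
  beta_inst <- beta_slope <- numeric(P)
  i <- match(config$adopting_policies[1], policy_ids())
  beta_inst[i] <- theta / 2
  beta_slope[i] <- theta / 2
  rho1 <- 0.6; rho2 <- 0.2
  target_log_rate <- log(12e-5)  # ~12 per 100k steady state
  bc <- c(0.15, 0.05, 0.05, 0.03, 0.03)[seq_len(config$n_conf)]
  bo <- numeric(config$n_other)
  bo[seq_len(min(3, config$n_other))] <- 0.02
  structure(list(
    alpha = target_log_rate * (1 - rho1 - rho2),
    beta_conf = bc, beta_other = bo,
    rho1 = rho1, rho2 = rho2,
    beta_inst = beta_inst, beta_slope = beta_slope,
    phi = 30,
    year_offsets = stats::setNames(rep(0, length(config$years)),
                                   config$years)
  ), class = "true_params")
}

#' Generate state covariate panels
#'
#' Each covariate follows an independent stationary AR(1) process per state
#' with the configured coefficient and unit marginal variance, initialized
#' at stationarity.
#'
#' @param n_states Number of states (>= 2).
#' @param years Integer years (>= 5).
#' @param seed RNG seed.
#' @param n_conf,n_other Covariate counts.
#' @param ar AR(1) coefficient, default 0.9.
#' @return data.frame: `state`, `year`, `conf_1..`, `other_1..`.
#' @export
generate_covariates <- function(n_states, years, seed, n_conf = 5,
                                n_other = 23, ar = 0.9) {
  if (n_states < 2) stop("n_states must be >= 2")
  if (length(years) < 5) stop("need at least 5 years")
  set.seed(seed)
  states <- state_codes(n_states)
  ny <- length(years); k <- n_conf + n_other
  innov_sd <- sqrt(1 - ar^2)
  out <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    m <- matrix(NA_real_, ny, k)
    m[1, ] <- stats::rnorm(k)
    if (ny > 1) for (t in 2:ny)
      m[t, ] <- ar * m[t - 1, ] + innov_sd * stats::rnorm(k)
    df <- as.data.frame(m)
    names(df) <- c(if (n_conf) paste0("conf_", seq_len(n_conf)),
                   if (n_other) paste0("other_", seq_len(n_other)))
    out[[s]] <- cbind(data.frame(state = states[s], year = years), df)
  }
  do.call(rbind, out)
}

#' Generate confounded policy adoptions
#'
#' For each eligible (state, policy), adoption is a first-passage event of a
#' yearly logistic hazard on the first confounder: states with higher values
#' of the confounder adopt sooner (for a positive coefficient), inducing the
#' adoption-outcome confounding the fitted model must remove. Effective
#' dates fall mid-year (July 1); no repeals are generated.
#'
#' @param covariates Covariate panel from [generate_covariates()].
#' @param config A `"sim_config"` (hazard parameters, eligible policies).
#' @param seed RNG seed.
#' @param years Years during which adoption may occur; defaults to the
#'   covariate panel's years.
#' @return A `"law_records"` data.frame (possibly zero rows).
#' @export
generate_adoptions <- function(covariates, config, seed,
                               years = sort(unique(covariates$year))) {
  set.seed(seed)
  states <- unique(covariates$state)
  recs <- list()
  for (pol in config$adopting_policies) {
    for (st in states) {
      cv <- covariates[covariates$state == st & covariates$year %in% years, ]
      cv <- cv[order(cv$year), ]
      haz <- stats::plogis(config$adoption_intercept +
                             config$adoption_conf_coef * cv$conf_1)
      u <- stats::runif(nrow(cv))
      hit <- which(u < haz)
      if (length(hit)) {
        yr <- cv$year[hit[1]]
        recs[[length(recs) + 1L]] <-
          data.frame(state = st, policy_id = pol,
                     effective_date = sprintf("%d-07-01", yr),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs))
    return(law_records(character(), character(), as.Date(character())))
  df <- do.call(rbind, recs)
  law_records(df$state, df$policy_id, df$effective_date)
}

#' Forward-simulate a state-year mortality panel
#'
#' Draws counts sequentially from the same conditional model the fitter
#' assumes: `y_st ~ NB(mu_st, phi)` with `log mu_st` equal to the debiased
#' linear predictor evaluated at the realized lagged log rates. Lags are
#' initialized at the policy-free steady state and run through `burn_in`
#' pre-panel years. With `noise = FALSE` the recursion is deterministic
#' (counts replaced by their conditional means, lags tracked as exact log
#' rates) and a `log_rate` column is returned — used by steady-state oracles.
#'
#' @param true_params A `"true_params"` list.
#' @param covariates Covariate panel covering the output years (values are
#'   held at their first-year level during burn-in).
#' @param records A `"law_records"` data.frame.
#' @param config A `"sim_config"`.
#' @param seed RNG seed.
#' @param noise Draw NB counts (default) or run the deterministic recursion.
#' @return State-year data.frame: `state`, `year`, `population`,
#'   `deaths_total` (and `log_rate` when `noise = FALSE`), plus covariates;
#'   with `true_params` attached as an attribute.
#' @export
generate_panel <- function(true_params, covariates, records, config, seed,
                           noise = TRUE) {
  tp <- true_params
  years_out <- config$years
  if (!all(years_out %in% covariates$year))
    stop("covariates must cover all output years")
  if (nrow(records) &&
      any(as.integer(format(records$effective_date, "%Y")) > max(years_out)))
    stop("law records extend beyond the panel years")
  set.seed(seed)
  states <- sort(unique(covariates$state))
  years_all <- (min(years_out) - config$burn_in):max(years_out)
  pp <- build_policy_panel(records, states, years_all, config$horizon)
  pm <- policy_matrices(pp)
  cont <- 0.5
  N <- config$population

  conf_cols <- grep("^conf_", names(covariates), value = TRUE)
  other_cols <- grep("^other_", names(covariates), value = TRUE)
  ny <- length(years_all)
  rows <- vector("list", length(states))
  for (si in seq_along(states)) {
    st <- states[si]
    cv <- covariates[covariates$state == st, ]
    cv <- cv[order(cv$year), ]
    xb <- function(yr) {
      r <- cv[match(max(yr, min(years_out)), cv$year), ]
      sum(unlist(r[conf_cols]) * tp$beta_conf) +
        sum(unlist(r[other_cols]) * tp$beta_other)
    }
    yoff <- function(yr) {
      v <- tp$year_offsets[as.character(yr)]
      if (is.na(v) || is.null(v)) 0 else unname(v)
    }
    # policy-free steady state of the log rate at first-year covariates
    a1 <- a2 <- (tp$alpha + xb(years_all[1]) + yoff(years_all[1])) /
      (1 - tp$rho1 - tp$rho2)
    y <- integer(ny); lograte <- numeric(ny)
    prow <- match(paste(st, years_all), paste(pm$keys$state, pm$keys$year))
    for (t in seq_len(ny)) {
      i0 <- prow[t]
      d_t <- sum(tp$beta_inst * pm$E[i0, ] + tp$beta_slope * pm$F[i0, ])
      d_1 <- if (t > 1) {
        i1 <- prow[t - 1]
        sum(tp$beta_inst * pm$E[i1, ] + tp$beta_slope * pm$F[i1, ])
      } else d_t * 0
      d_2 <- if (t > 2) {
        i2 <- prow[t - 2]
        sum(tp$beta_inst * pm$E[i2, ] + tp$beta_slope * pm$F[i2, ])
      } else d_1 * 0
      eta <- log(N) + tp$alpha + yoff(years_all[t]) + xb(years_all[t]) +
        tp$rho1 * (a1 - d_1) + tp$rho2 * (a2 - d_2) + d_t
      if (noise) {
        y[t] <- stats::rnbinom(1, mu = exp(eta), size = tp$phi)
        a_new <- lag_log_rate(y[t], N, cont)
      } else {
        lograte[t] <- eta - log(N)
        a_new <- eta - log(N)
      }
      a2 <- a1; a1 <- a_new
    }
    df <- data.frame(state = st, year = years_all, population = N,
                     deaths_total = y, stringsAsFactors = FALSE)
    if (!noise) df$log_rate <- lograte
    rows[[si]] <- df
  }
  panel <- do.call(rbind, rows)
  panel <- panel[panel$year %in% years_out, ]
  panel <- merge(panel, covariates, by = c("state", "year"), sort = TRUE)
  panel <- panel[order(panel$state, panel$year), ]
  rownames(panel) <- NULL
  attr(panel, "true_params") <- tp
  panel
}

#' Simulate a complete synthetic study
#'
#' Orchestrates [generate_covariates()], [generate_adoptions()] and
#' [generate_panel()] under one seed and returns everything the analysis
#' pipeline needs, plus the ground truth.
#'
#' @param config A `"sim_config"`.
#' @param true_params Optional `"true_params"`; default
#'   [default_true_params()].
#' @param seed RNG seed (sub-seeds for the three stages are derived from it).
#' @return List: `panel`, `laws`, `policy_panel`, `covariates`,
#'   `true_params`, `model_config` (ready for [build_model_inputs()]).
#' @export
simulate_study <- function(config, true_params = NULL, seed = 1) {
  if (is.null(true_params)) true_params <- default_true_params(config)
  seed <- as.integer(abs(seed) %% 500000000)  # headroom for derived sub-seeds
  covariates <- generate_covariates(config$n_states, config$years,
                                    seed = seed * 3L + 1L,
                                    n_conf = config$n_conf,
                                    n_other = config$n_other,
                                    ar = config$cov_ar)
  laws <- generate_adoptions(covariates, config, seed = seed * 3L + 2L)
  panel <- generate_panel(true_params, covariates, laws, config,
                          seed = seed * 3L + 3L)
  states <- sort(unique(panel$state))
  pp <- build_policy_panel(laws, states, config$years, config$horizon)
  list(panel = panel, laws = laws, policy_panel = pp,
       covariates = covariates, true_params = true_params,
       model_config = list(
         outcome = "deaths_total",
         analysis_years = config$years[-(1:2)],
         conf_covariates = if (config$n_conf)
           paste0("conf_", seq_len(config$n_conf)) else character(),
         other_covariates = if (config$n_other)
           paste0("other_", seq_len(config$n_other)) else character(),
         cont = 0.5))
}
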