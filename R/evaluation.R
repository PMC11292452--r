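#' Desk-scale defaults for the experiment harness
#'
#' The calibration and attenuation experiments run many simulate-fit cycles,
#' so they default to a reduced world — 15 states over 2000-2017 (16
#' analysis years), 2 confounders and 3 other covariates, a brisker adoption
#' hazard — and reduced MCMC (2 chains, 500 warmup, 400 draws). These keep a
#' full run in minutes while leaving the model structure (all ten policy
#' columns, AR(2) lags, debiasing) intact.
#'
#' @return A `"sim_config"` / list of MCMC settings.
#' @export
harness_sim_config <- function() {
  sim_config(n_states = 15, years = 2000:2017, n_conf = 2, n_other = 3,
             burn_in = 10, adoption_intercept = -2.5,
             adoption_conf_coef = 0.8,
             adopting_policies = "bc_dealer")
}

#' @rdname harness_sim_config
#' @export
harness_fit_config <- function() {
  list(chains = 2, warmup = 2000, iter = 400, thin = 1)
}

#' Priors used by the harness fits
#'
#' Simulation-based calibration draws every free parameter from the fitted
#' model's prior, so the harness priors must put their mass on worlds the
#' generator can realize with finite counts: stationary AR mass
#' (rho1 ~ N(0.5, 0.1), rho2 ~ N(0.1, 0.05)), an intercept centered on a
#' ~12-per-100k steady state, small year shocks, and dispersion near the
#' generator's. The policy-effect prior is the informative one (total-effect
#' SD from [prior_sd_total()]).
#'
#' @return A `"prior_spec"`.
#' @export
harness_priors <- function() {
  make_priors(sd_total = prior_sd_total(),
              conf_sd = 0.1, lasso_scale = 0.03,
              alpha_mean = log(12e-5) * 0.4, alpha_sd = 0.2,
              year_sd = 0.05,
              rho_mean = c(0.5, 0.1), rho_sd = c(0.1, 0.05),
              log_phi_mean = log(30), log_phi_sd = 0.2)
}

prior_to_true_params <- function(mp, config) {
  structure(list(
    alpha = mp$alpha, beta_conf = mp$beta_conf, beta_other = mp$beta_other,
    rho1 = mp$rho1, rho2 = mp$rho2,
    beta_inst = mp$beta_inst, beta_slope = mp$beta_slope, phi = mp$phi,
    year_offsets = stats::setNames(
      c(rep(0, 2), mp$year), config$years)  # lead-in years at reference
  ), class = "true_params")
}

run_one_fit <- function(study, fit_cfg, priors, seed, debias = TRUE) {
  inputs <- build_model_inputs(study$panel, study$policy_panel,
                               study$model_config)
  fit(inputs, priors, chains = fit_cfg$chains, warmup = fit_cfg$warmup,
      iter = fit_cfg$iter, thin = fit_cfg$thin %||% 1, seed = seed,
      debias = debias)
}

#' Simulation-based calibration of the full pipeline
#'
#' For each replicate: draw every free parameter of the model from its
#' prior, simulate a complete study (covariates, confounded adoptions,
#' counts), fit the model with the same priors, and record — for the target
#' (first adopting) policy's total effect — the posterior median, the 95%
#' credible interval and whether it covers the truth, and the rank of the
#' truth among thinned posterior draws. If the posterior is computed
#' correctly, coverage is binomially distributed around 0.95 and ranks are
#' uniform. Replicates with split-R-hat above 1.1 are flagged and excluded
#' from the coverage aggregate (never silently dropped).
#'
#' @param n_reps Number of replicates (>= 10).
#' @param sim_cfg A `"sim_config"`, default [harness_sim_config()].
#' @param fit_cfg MCMC settings, default [harness_fit_config()].
#' @param priors Fit priors, default [harness_priors()].
#' @param base_seed Integer seed; the whole report is reproducible from it.
#' @return A `"recovery_report"`: `replicates` data.frame (one row per
#'   replicate, with its seed), `aggregates` (coverage with an exact
#'   binomial 95% interval, mean bias, rank-bin counts), and the
#'   configuration.
#' @export
run_calibration <- function(n_reps = 20, sim_cfg = harness_sim_config(),
                            fit_cfg = harness_fit_config(),
                            priors = harness_priors(), base_seed = 1) {
  if (n_reps < 10) stop("n_reps must be >= 10")
  set.seed(base_seed)
  seeds <- sample.int(2^30, 2 * n_reps)
  target <- sim_cfg$adopting_policies[1]
  dims <- list(years = sim_cfg$years[-(1:2)],
               conf = paste0("conf_", seq_len(sim_cfg$n_conf)),
               other = paste0("other_", seq_len(sim_cfg$n_other)),
               policies = policy_ids())
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seeds[2 * r - 1])
    vec <- drop(draw_from_prior(priors, dims, 1))
    mp <- unpack_params(vec, dims)
    tp <- prior_to_true_params(mp, sim_cfg)
    true_theta <- total_effects(mp)[match(target, policy_ids())]
    study <- simulate_study(sim_cfg, tp, seed = seeds[2 * r])
    ft <- run_one_fit(study, fit_cfg, priors, seed = seeds[2 * r])
    th <- theta_draws(ft)[, target]
    thin_idx <- seq(1, length(th), by = 10)
    rows[[r]] <- data.frame(
      rep = r, seed = seeds[2 * r], true_theta = unname(true_theta),
      median = stats::median(th),
      lo95 = stats::quantile(th, 0.025, type = 1, names = FALSE),
      hi95 = stats::quantile(th, 0.975, type = 1, names = FALSE),
      rank_u = mean(th[thin_idx] < true_theta),
      max_rhat = max(ft$diagnostics$rhat, na.rm = TRUE)
    )
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  reps$covered <- reps$lo95 <= reps$true_theta & reps$true_theta <= reps$hi95
  reps$converged <- reps$max_rhat <= 1.1
  use <- reps[reps$converged, ]
  n_use <- nrow(use)
  ci <- if (n_use) as.numeric(
    stats::binom.test(sum(use$covered), n_use, p = 0.95)$conf.int
  ) else c(NA_real_, NA_real_)
  bins <- table(cut(reps$rank_u, breaks = seq(0, 1, by = 0.25),
                    include.lowest = TRUE))
  structure(list(
    mode = "calibration",
    replicates = reps,
    aggregates = list(
      n_reps = n_reps, n_converged = n_use,
      coverage = if (n_use) mean(use$covered) else NA_real_,
      coverage_ci = ci,
      mean_bias = mean(reps$median - reps$true_theta),
      rank_bins = as.integer(bins)
    ),
    target = target, base_seed = base_seed,
    sim_cfg = sim_cfg, fit_cfg = fit_cfg
  ), class = "recovery_report")
}

#' Attenuation of naive lagged-outcome fits
#'
#' Simulates panels with a fixed nonzero policy effect under persistent
#' dynamics, then fits both the debiased model and the naive variant
#' (counterfactual lag adjustment off). Conditioning on the lagged outcome
#' without adjustment absorbs most of the long-run effect into the AR terms,
#' so the naive posterior median of the total effect should be attenuated
#' toward zero relative to the debiased one.
#'
#' @param n_reps Number of replicates (>= 10 recommended).
#' @param theta_true True total effect of the target policy (nonzero),
#'   default log(0.8).
#' @inheritParams run_calibration
#' @return A `"recovery_report"` with per-replicate debiased and naive
#'   medians and aggregates (share of replicates attenuated, mean bias of
#'   each variant, attenuation ratio of median magnitudes).
#' @export
run_attenuation <- function(n_reps = 10, theta_true = log(0.8),
                            sim_cfg = harness_sim_config(),
                            fit_cfg = harness_fit_config(),
                            priors = harness_priors(), base_seed = 1) {
  if (theta_true == 0) stop("theta_true must be nonzero")
  set.seed(base_seed)
  seeds <- sample.int(2^30, n_reps)
  target <- sim_cfg$adopting_policies[1]
  tp <- default_true_params(sim_cfg, theta = theta_true)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    study <- simulate_study(sim_cfg, tp, seed = seeds[r])
    fd <- run_one_fit(study, fit_cfg, priors, seed = seeds[r], debias = TRUE)
    fn <- run_one_fit(study, fit_cfg, priors, seed = seeds[r], debias = FALSE)
    rows[[r]] <- data.frame(
      rep = r, seed = seeds[r], true_theta = theta_true,
      debiased = stats::median(theta_draws(fd)[, target]),
      naive = stats::median(theta_draws(fn)[, target]),
      max_rhat = max(fd$diagnostics$rhat, fn$diagnostics$rhat, na.rm = TRUE)
    )
  }
  reps <- do.call(rbind, rows)
  reps$attenuated <- abs(reps$naive) < abs(reps$debiased)
  reps$converged <- reps$max_rhat <= 1.1
  structure(list(
    mode = "attenuation",
    replicates = reps,
    aggregates = list(
      n_reps = n_reps,
      prop_attenuated = mean(reps$attenuated),
      mean_bias_debiased = mean(reps$debiased - theta_true),
      mean_bias_naive = mean(reps$naive - theta_true),
      attenuation_ratio = stats::median(reps$naive) /
        stats::median(reps$debiased)
    ),
    target = target, base_seed = base_seed, theta_true = theta_true,
    sim_cfg = sim_cfg, fit_cfg = fit_cfg
  ), class = "recovery_report")
}

#' Serialize a recovery report to JSON
#'
#' @param report A `"recovery_report"`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  out <- list(schema = "gunpolicy/recovery_report/v1",
              mode = report$mode, base_seed = report$base_seed,
              aggregates = report$aggregates,
              replicates = report$replicates)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report:", x$mode, ">", nrow(x$replicates), "replicates\n")
  str(x$aggregates, give.attr = FALSE)
  invisible(x)
}
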