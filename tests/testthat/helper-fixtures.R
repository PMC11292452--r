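# shared fixtures: tiny synthetic worlds, built once per test run

tiny_sim_config <- function(n_states = 3, years = 2000:2005) {
  sim_config(n_states = n_states, years = years, n_conf = 2, n_other = 2,
             burn_in = 5, adoption_intercept = -1.5,
             adoption_conf_coef = 0.8, adopting_policies = "bc_dealer")
}

# small study + model inputs reused across fit/effects tests
.cache <- new.env()
tiny_study <- function(seed = 101) {
  key <- paste0("study_", seed)
  if (is.null(.cache[[key]])) {
    st <- simulate_study(tiny_sim_config(), seed = seed)
    st$inputs <- build_model_inputs(st$panel, st$policy_panel,
                                    st$model_config)
    .cache[[key]] <- st
  }
  .cache[[key]]
}

tiny_fit <- function(seed = 101, fit_seed = 1, debias = TRUE,
                     priors = harness_priors()) {
  key <- paste0("fit_", seed, "_", fit_seed, "_", debias)
  if (is.null(.cache[[key]])) {
    st <- tiny_study(seed)
    .cache[[key]] <- fit(st$inputs, priors, chains = 2, warmup = 800,
                         iter = 250, seed = fit_seed, debias = debias)
  }
  .cache[[key]]
}

# random parameter vector compatible with given inputs, for oracle checks
random_params <- function(inputs, seed = 1) {
  set.seed(seed)
  dims <- param_dims(inputs)
  K <- length(gunpolicy:::param_names(dims))
  vec <- stats::rnorm(K, 0, 0.05)
  blk <- gunpolicy:::param_blocks(dims)
  vec[blk$alpha] <- -9 * 0.4
  vec[blk$rho] <- c(0.5, 0.1)
  vec[blk$log_phi] <- log(25)
  vec
}

# independent log-posterior oracle: R-side NB pmf via dnbinom plus explicit
# prior terms, routed through linear_predictor rather than the sampler code
oracle_logpost <- function(vec, inputs, priors, debias = TRUE) {
  dims <- param_dims(inputs)
  par <- unpack_params(vec, dims)
  eta <- linear_predictor(inputs, par, debias = debias)
  ll <- sum(dnbinom(inputs$y, size = par$phi, mu = exp(eta), log = TRUE))
  pv <- prior_vectors(priors, dims)
  for (k in seq_along(vec)) {
    ll <- ll + if (pv$type[k] == 0L) {
      dnorm(vec[k], pv$mean[k], pv$sd[k], log = TRUE)
    } else {
      -abs(vec[k] - pv$mean[k]) / pv$sd[k] - log(2 * pv$sd[k])
    }
  }
  ll
}

# constructed effect-draw containers for the combination algebra tests
constant_draws <- function(theta_by_policy, n = 4, split = 0.5) {
  pols <- firearm_policies()$policy_id
  th <- stats::setNames(rep(0, length(pols)), pols)
  th[names(theta_by_policy)] <- unlist(theta_by_policy)
  list(beta_inst = matrix(rep(th * split, each = n), n,
                          dimnames = list(NULL, pols)),
       beta_slope = matrix(rep(th * (1 - split), each = n), n,
                           dimnames = list(NULL, pols)))
}

random_effect_draws <- function(n = 500, seed = 7) {
  set.seed(seed)
  pols <- firearm_policies()$policy_id
  list(beta_inst = matrix(stats::rnorm(n * length(pols), 0, 0.07), n,
                          dimnames = list(NULL, pols)),
       beta_slope = matrix(stats::rnorm(n * length(pols), 0, 0.07), n,
                           dimnames = list(NULL, pols)))
}
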