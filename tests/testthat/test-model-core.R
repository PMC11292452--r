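test_that("lag_log_rate applies the continuity correction and is monotone", {
  expect_equal(lag_log_rate(0, 1e6), log(0.5e-6))
  expect_equal(lag_log_rate(100, 1e6), log(100.5 / 1e6))
  expect_equal(lag_log_rate(100, 1e6), -9.2054, tolerance = 1e-4)
  y <- 0:50
  expect_true(all(diff(lag_log_rate(y, 1e6)) > 0))
  expect_error(lag_log_rate(3, 0), "positive")
  expect_error(lag_log_rate(-1, 10), "nonnegative")
})

test_that("nb_log_density matches oracles and normalizes", {
  # brute-force oracle from R's dnbinom (size = phi, mu parameterization)
  set.seed(4)
  for (i in 1:20) {
    y <- sample(0:50, 1); mu <- runif(1, 0.1, 30); phi <- runif(1, 0.3, 50)
    expect_equal(nb_log_density(y, mu, phi),
                 dnbinom(y, size = phi, mu = mu, log = TRUE),
                 tolerance = 1e-10)
  }
  expect_equal(nb_log_density(0, 2, 5), 5 * log(5 / 7))
  # Poisson limit
  expect_equal(nb_log_density(0:10, rep(2, 11), 1e6),
               dpois(0:10, 2, log = TRUE), tolerance = 1e-4)
  # normalization
  for (pars in list(c(2, 5), c(10, 0.5), c(0.3, 30))) {
    expect_equal(sum(exp(nb_log_density(0:2000, rep(pars[1], 2001),
                                        pars[2]))), 1, tolerance = 1e-8)
  }
  expect_error(nb_log_density(1.5, 2, 5), "integer")
  expect_error(nb_log_density(1, -2, 5), "positive")
  expect_error(nb_log_density(1, 2, 0), "positive")
})

test_that("cumulative_policy_effect is the signed exposure-weighted sum", {
  z <- rep(0, 10)
  expect_equal(cumulative_policy_effect(z, z, z, z), 0)
  bi <- c(log(0.95), rep(0, 9)); bs <- c(log(0.9) - log(0.95), rep(0, 9))
  on <- c(1, rep(0, 9))
  expect_equal(cumulative_policy_effect(bi, bs, on, on), log(0.9))
  bi2 <- c(log(0.9) / 2, log(0.9) / 2, rep(0, 8))
  both <- c(1, 1, rep(0, 8))
  expect_equal(exp(cumulative_policy_effect(bi2, bi2, both, both)), 0.81)
  expect_error(cumulative_policy_effect(bi, bs[-1], on, on), "equal length")
})

one_row_inputs <- function(a1, a2, e, f, e1 = e, f1 = f, e2 = e, f2 = f) {
  structure(list(log_N = log(5e6), year_idx = 1L, n_years = 1L,
                 X_conf = matrix(0, 1, 0), X_other = matrix(0, 1, 0),
                 a1 = a1, a2 = a2,
                 E = matrix(e, 1, 1), F = matrix(f, 1, 1),
                 E1 = matrix(e1, 1, 1), F1 = matrix(f1, 1, 1),
                 E2 = matrix(e2, 1, 1), F2 = matrix(f2, 1, 1)),
            class = "model_inputs")
}

test_that("linear_predictor implements counterfactual-adjusted lags", {
  st <- tiny_study()
  inp <- st$inputs
  dims <- param_dims(inp)
  par0 <- unpack_params(random_params(inp), dims)
  par0$rho1 <- 0; par0$rho2 <- 0
  par0$beta_inst[] <- 0; par0$beta_slope[] <- 0
  eta <- linear_predictor(inp, par0)
  expect_equal(eta, inp$log_N + par0$alpha + par0$year[inp$year_idx] +
                 drop(inp$X_conf %*% par0$beta_conf) +
                 drop(inp$X_other %*% par0$beta_other))

  # fully phased-in policy: realized lag rates sit theta above their
  # policy-free counterfactual, and the equilibrium contrast is exactly theta
  theta <- -0.1
  par <- model_params(rho1 = 0.6, rho2 = 0.2,
                      beta_inst = theta / 2, beta_slope = theta / 2, phi = 10)
  on <- one_row_inputs(-9 + theta, -9.1 + theta, 1, 1)
  off <- one_row_inputs(-9, -9.1, 0, 0)
  expect_equal(linear_predictor(on, par) - linear_predictor(off, par), theta)

  # naive variant drops the adjustment: difference is rho'Delta
  expect_equal(linear_predictor(on, par, debias = FALSE) -
                 linear_predictor(on, par, debias = TRUE),
               (0.6 + 0.2) * theta)
  expect_error(linear_predictor(on, model_params(beta_inst = c(0, 0),
                                                 beta_slope = c(0, 0))),
               "mismatch")
})

test_that("recursion_shift recovers theta exactly for stationary AR", {
  for (rho in list(c(0, 0), c(0.6, 0.2), c(0.9, -0.1))) {
    expect_equal(recursion_shift(rho[1], rho[2], -0.05, -0.05),
                 -0.1, tolerance = 1e-8)
  }
  # without the adjustment the recursion compounds the effect through the
  # lags: long-run shift is theta / (1 - rho1 - rho2), not theta
  expect_equal(recursion_shift(0.6, 0.2, -0.05, -0.05, debias = FALSE),
               -0.1 / (1 - 0.8), tolerance = 1e-6)
})

test_that("build_model_inputs shapes, lags and validation", {
  st <- tiny_study()
  inp <- st$inputs
  n_analysis <- 3 * (length(2000:2005) - 2)
  expect_equal(length(inp$y), n_analysis)
  expect_equal(dim(inp$E), c(n_analysis, 10))
  expect_equal(colMeans(inp$X_conf), c(conf_1 = 0, conf_2 = 0),
               tolerance = 1e-12)
  expect_equal(unname(apply(inp$X_conf, 2, sd)), c(1, 1))
  # lag alignment: a1 of year t equals the panel's log rate at t-1
  k <- which(inp$keys$year == 2003 & inp$keys$state == inp$states[2])
  prev <- st$panel[st$panel$state == inp$states[2] & st$panel$year == 2002, ]
  expect_equal(inp$a1[k], log((prev$deaths_total + 0.5) / prev$population))

  # idempotence
  inp2 <- build_model_inputs(st$panel, st$policy_panel, st$model_config)
  expect_identical(inp, inp2)

  # too-short lead-in
  cfg_bad <- st$model_config; cfg_bad$analysis_years <- 2000:2005
  expect_error(build_model_inputs(st$panel, st$policy_panel, cfg_bad),
               "lead-in")
  # missing covariate cell named
  pan <- st$panel
  pan$conf_1[pan$state == pan$state[1] & pan$year == 2003] <- NA
  err <- tryCatch(build_model_inputs(pan, st$policy_panel, st$model_config),
                  error = conditionMessage)
  expect_match(err, "conf_1")
  expect_match(err, "2003")
  # missing state-year
  pan2 <- st$panel[-5, ]
  expect_error(build_model_inputs(pan2, st$policy_panel, st$model_config),
               "missing state-years")
})

test_that("full-size grid yields 1950 analysis rows", {
  cfg <- sim_config()
  cov <- generate_covariates(50, 1979:2019, seed = 3, n_conf = 1,
                             n_other = 0)
  empty <- law_records(character(), character(), as.Date(character()))
  tp <- default_true_params(sim_config(n_conf = 1, n_other = 0))
  pan <- generate_panel(tp, cov, empty, sim_config(n_conf = 1, n_other = 0),
                        seed = 3)
  pp <- build_policy_panel(empty, sort(unique(pan$state)), 1979:2019)
  inp <- build_model_inputs(pan, pp, list(outcome = "deaths_total",
                                          analysis_years = 1981:2019,
                                          conf_covariates = "conf_1"))
  expect_equal(length(inp$y), 1950)
})

test_that("doubling the population offset doubles fitted means exactly", {
  st <- tiny_study()
  inp <- st$inputs
  par <- unpack_params(random_params(inp), param_dims(inp))
  mu1 <- exp(linear_predictor(inp, par))
  inp2 <- inp
  inp2$log_N <- inp$log_N + log(2)
  mu2 <- exp(linear_predictor(inp2, par))
  expect_equal(mu2, 2 * mu1)
})
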