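test_that("generate_covariates: shape, determinism, AR structure", {
  cov <- generate_covariates(4, 2000:2010, seed = 1, n_conf = 2, n_other = 3)
  expect_equal(nrow(cov), 4 * 11)
  expect_setequal(setdiff(names(cov), c("state", "year")),
                  c("conf_1", "conf_2", "other_1", "other_2", "other_3"))
  cov2 <- generate_covariates(4, 2000:2010, seed = 1, n_conf = 2, n_other = 3)
  expect_identical(cov, cov2)
  expect_error(generate_covariates(1, 2000:2010, seed = 1), "n_states")
  expect_error(generate_covariates(4, 2000:2002, seed = 1), "5 years")

  # pooled lag-1 autocorrelation near the configured 0.9 at full size
  big <- generate_covariates(50, 1979:2019, seed = 2, n_conf = 5,
                             n_other = 23)
  x <- big[order(big$state, big$year), "conf_1"]
  m <- matrix(x, nrow = 41)
  r <- cor(as.vector(m[-41, ]), as.vector(m[-1, ]))
  expect_equal(r, 0.9, tolerance = 0.05)
})

test_that("generate_adoptions responds to the hazard and the confounder", {
  cov <- generate_covariates(10, 2000:2010, seed = 3, n_conf = 1, n_other = 0)
  none <- sim_config(n_states = 10, years = 2000:2010, n_conf = 1,
                     n_other = 0, adoption_intercept = -Inf,
                     adopting_policies = "bc_dealer")
  expect_equal(nrow(generate_adoptions(cov, none, seed = 1)), 0)
  all_cfg <- sim_config(n_states = 10, years = 2000:2010, n_conf = 1,
                        n_other = 0, adoption_intercept = Inf,
                        adopting_policies = "bc_dealer")
  ad <- generate_adoptions(cov, all_cfg, seed = 1)
  expect_equal(nrow(ad), 10)
  expect_true(all(ad$effective_date == as.Date("2000-07-01")))

  # positive coefficient implies adopters have higher mean confounder
  cfg <- sim_config(n_states = 40, years = 2000:2010, n_conf = 1,
                    n_other = 0, adoption_intercept = -2.5,
                    adoption_conf_coef = 1.2, adopting_policies = "bc_dealer")
  hits <- sapply(1:20, function(s) {
    cv <- generate_covariates(40, 2000:2010, seed = s, n_conf = 1,
                              n_other = 0)
    ad <- generate_adoptions(cv, cfg, seed = s + 1000)
    mean_conf <- tapply(cv$conf_1, cv$state, mean)
    adopted <- names(mean_conf) %in% ad$state
    if (length(unique(adopted)) < 2) return(NA)
    cor(mean_conf, as.numeric(adopted)) > 0
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("generate_panel produces a valid, deterministic panel", {
  st <- tiny_study()
  p <- st$panel
  expect_true(all(p$deaths_total >= 0))
  expect_true(all(p$deaths_total == round(p$deaths_total)))
  expect_false(anyNA(p))
  # passes model-input validation unchanged (already built in the helper)
  expect_s3_class(st$inputs, "model_inputs")
  st2 <- simulate_study(tiny_sim_config(), seed = 101)
  expect_identical(st$panel, st2$panel)
  expect_identical(st$laws, st2$laws)
})

test_that("deterministic recursion settles at steady state shifted by theta", {
  cfg <- sim_config(n_states = 2, years = 1990:2019, n_conf = 1, n_other = 0,
                    burn_in = 10)
  tp <- default_true_params(cfg, theta = log(0.85))
  tp$beta_conf[] <- 0  # constant-covariate steady state
  cov <- generate_covariates(2, cfg$years, seed = 5, n_conf = 1, n_other = 0)
  # adopt in one state early; the other never
  laws <- law_records("AA", "bc_dealer", "1995-01-01")
  pan <- generate_panel(tp, cov, laws, cfg, seed = 1, noise = FALSE)
  last <- pan[pan$year == 2019, ]
  base <- (tp$alpha) / (1 - tp$rho1 - tp$rho2)
  expect_equal(last$log_rate[last$state == "AB"], base, tolerance = 1e-6)
  expect_equal(last$log_rate[last$state == "AA"], base + log(0.85),
               tolerance = 1e-6)
})

test_that("a larger restrictive effect lowers post-adoption counts", {
  cfg <- sim_config(n_states = 6, years = 2000:2012, n_conf = 1, n_other = 0,
                    burn_in = 5)
  cov <- generate_covariates(6, cfg$years, seed = 11, n_conf = 1, n_other = 0)
  laws <- law_records(rep(c("AA", "AB", "AC"), 1), rep("bc_dealer", 3),
                      rep("2004-01-01", 3))
  tot <- function(theta, seed) {
    tp <- default_true_params(cfg, theta = theta)
    pan <- generate_panel(tp, cov, laws, cfg, seed = seed)
    sum(pan$deaths_total[pan$state %in% c("AA", "AB", "AC") &
                           pan$year >= 2009])
  }
  contrast <- sapply(1:100, function(s) tot(log(0.8), s) < tot(0, s))
  expect_gt(mean(contrast), 0.8)
})

test_that("log density at truth beats parameters perturbed by +3 prior SD", {
  pr <- harness_priors()
  cfg <- harness_sim_config()
  wins <- sapply(1:5, function(s) {
    st <- simulate_study(cfg, seed = s + 40)
    inp <- build_model_inputs(st$panel, st$policy_panel, st$model_config)
    dims <- param_dims(inp)
    tp <- st$true_params
    vec <- c(tp$alpha, tp$year_offsets[-(1:2)][-1], tp$beta_conf,
             tp$beta_other, tp$rho1, tp$rho2, tp$beta_inst, tp$beta_slope,
             log(tp$phi))
    lp_true <- log_posterior(vec, inp, pr)
    expect_true(is.finite(lp_true))
    pv <- prior_vectors(pr, dims)
    set.seed(s)
    pert <- vec
    idx <- sample(length(vec), 5)
    pert[idx] <- pert[idx] + 3 * pv$sd[idx]
    lp_true > log_posterior(pert, inp, pr)
  })
  expect_gt(mean(wins), 0.8)
})

test_that("omitting the adoption-driving confounder shifts the estimate", {
  cfg <- harness_sim_config()
  pr <- harness_priors()
  shifts <- sapply(1:3, function(s) {
    st <- simulate_study(cfg, seed = s + 200)
    inp_full <- build_model_inputs(st$panel, st$policy_panel,
                                   st$model_config)
    mc <- st$model_config; mc$conf_covariates <- "conf_2"
    inp_om <- build_model_inputs(st$panel, st$policy_panel, mc)
    ff <- fit(inp_full, pr, chains = 2, warmup = 1200, iter = 300, seed = s)
    fo <- fit(inp_om, pr, chains = 2, warmup = 1200, iter = 300, seed = s)
    median(theta_draws(fo)[, "bc_dealer"]) -
      median(theta_draws(ff)[, "bc_dealer"])
  })
  # conf_1 raises both adoption and mortality: omitting it makes the
  # restrictive policy look more harmful (upward shift)
  expect_true(all(abs(shifts) > 0))
  expect_gt(mean(shifts), 0)
})
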