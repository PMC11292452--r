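#' Prior standard deviation of a policy's total effect
#'
#' The informative prior on each policy's total effect (log-IRR scale) is a
#' zero-mean normal whose SD is chosen so that a stated central mass falls
#' between two IRR endpoints. With the defaults (0.82 to 1.22 holding 0.95
#' mass) the endpoints are nearly symmetric about IRR 1 on the log scale
#' (`|log 0.82 + log 1.22| < 0.001`), so a zero-centered normal reproduces
#' both: `sd = (log(upper) - log(lower)) / (2 z)` with `z` the standard
#' normal quantile at `(1 + mass) / 2`.
#'
#' @param lower,upper IRR endpoints, `0 < lower < upper`.
#' @param mass Central prior mass between the endpoints, in (0, 1).
#' @return The implied prior SD on the log-IRR scale (about 0.1014 for the
#'   defaults).
#' @export
prior_sd_total <- function(lower = 0.82, upper = 1.22, mass = 0.95) {
  if (!(lower > 0 && upper > lower)) stop("need 0 < lower < upper")
  if (!(mass > 0 && mass < 1)) stop("mass must be in (0, 1)")
  (log(upper) - log(lower)) / (2 * stats::qnorm((1 + mass) / 2))
}

#' Construct the model's prior specification
#'
#' Encodes all priors of the mortality model. Each policy's instant effect
#' and phase-in slope get independent zero-mean normals with SD
#' `sd_total / sqrt(2)` each, so the induced SD of the total effect
#' `theta = beta_inst + beta_slope` is exactly `sd_total` (equal-variance
#' split). The 23 non-confounder covariates get a double-exponential
#' (Bayesian lasso) prior; the 5 designated confounders get a
#' weakly-informative normal so their adjustment is not shrunk away. Year
#' effects, AR coefficients and the intercept get weak normals; the
#' dispersion gets a lognormal (a normal prior on `log(phi)`).
#' `mode = "uninformative"` multiplies the policy-effect SD by
#' `uninformative_factor`, widening the induced 95% IRR interval well beyond
#' [0.5, 2].
#'
#' @param sd_total SD of the induced prior on each total effect; default
#'   from [prior_sd_total()] (IRR 0.82-1.22 holding 0.95 mass).
#' @param mode `"informative"` (default) or `"uninformative"`.
#' @param lasso_scale Scale of the double-exponential prior on the other
#'   covariates (standardized log-rate scale), default 0.05.
#' @param conf_sd Normal SD for confounder coefficients, default 1.
#' @param alpha_mean,alpha_sd Normal prior on the intercept.
#' @param year_sd Normal SD for year-effect offsets, default 1.
#' @param rho_mean,rho_sd Length-2 normal means/SDs for (rho1, rho2); no
#'   hard stationarity constraint is imposed.
#' @param log_phi_mean,log_phi_sd Normal prior on log dispersion.
#' @param uninformative_factor Inflation applied to the policy SD in
#'   uninformative mode, default 10.
#' @return A list of class `"prior_spec"`.
#' @export
make_priors <- function(sd_total = prior_sd_total(),
                        mode = c("informative", "uninformative"),
                        lasso_scale = 0.05, conf_sd = 1,
                        alpha_mean = 0, alpha_sd = 10, year_sd = 1,
                        rho_mean = c(0, 0), rho_sd = c(0.5, 0.5),
                        log_phi_mean = log(20), log_phi_sd = 1.5,
                        uninformative_factor = 10) {
  mode <- match.arg(mode)
  if (!is.numeric(sd_total) || sd_total <= 0) stop("sd_total must be > 0")
  if (lasso_scale <= 0) stop("lasso_scale must be > 0")
  policy_sd <- sd_total / sqrt(2)
  if (mode == "uninformative") policy_sd <- policy_sd * uninformative_factor
  structure(list(
    sd_total = sd_total, mode = mode, policy_sd = policy_sd,
    lasso_scale = lasso_scale, conf_sd = conf_sd,
    alpha_mean = alpha_mean, alpha_sd = alpha_sd, year_sd = year_sd,
    rho_mean = rho_mean, rho_sd = rho_sd,
    log_phi_mean = log_phi_mean, log_phi_sd = log_phi_sd
  ), class = "prior_spec")
}

#' Expand a prior specification to per-coordinate vectors
#'
#' Maps a [make_priors()] object onto the packed parameter vector used by
#' the sampler: one prior mean, SD/scale and family (normal or Laplace) per
#' coordinate, in packing order (intercept, year offsets, confounder
#' coefficients, lasso coefficients, rho1, rho2, instant effects, phase-in
#' slopes, log dispersion).
#'
#' @param priors A `"prior_spec"`.
#' @param dims Parameter dimensions, see [param_dims()].
#' @return List with `mean`, `sd`, `type` (0 normal / 1 Laplace), `names`.
#' @export
prior_vectors <- function(priors, dims) {
  nm <- param_names(dims)
  K <- length(nm)
  mean <- numeric(K); sd <- numeric(K); type <- integer(K)
  blk <- param_blocks(dims)
  mean[blk$alpha] <- priors$alpha_mean; sd[blk$alpha] <- priors$alpha_sd
  sd[blk$year] <- priors$year_sd
  sd[blk$beta_conf] <- priors$conf_sd
  sd[blk$beta_other] <- priors$lasso_scale
  type[blk$beta_other] <- 1L
  mean[blk$rho] <- priors$rho_mean; sd[blk$rho] <- priors$rho_sd
  sd[c(blk$beta_inst, blk$beta_slope)] <- priors$policy_sd
  mean[blk$log_phi] <- priors$log_phi_mean; sd[blk$log_phi] <- priors$log_phi_sd
  list(mean = mean, sd = sd, type = type, names = nm)
}

#' Draw parameter vectors from the prior
#'
#' Used by prior-calibration checks and simulation-based calibration: draws
#' every free coordinate from its marginal prior (normal or Laplace).
#'
#' @param priors A `"prior_spec"`.
#' @param dims Parameter dimensions, see [param_dims()].
#' @param n Number of draws.
#' @return An `n x K` matrix with parameter names as column names.
#' @export
draw_from_prior <- function(priors, dims, n) {
  pv <- prior_vectors(priors, dims)
  K <- length(pv$mean)
  out <- matrix(NA_real_, n, K, dimnames = list(NULL, pv$names))
  for (k in seq_len(K)) {
    out[, k] <- if (pv$type[k] == 0L) {
      stats::rnorm(n, pv$mean[k], pv$sd[k])
    } else {
      # Laplace via difference of exponentials
      pv$mean[k] + pv$sd[k] * (stats::rexp(n) - stats::rexp(n))
    }
  }
  out
}
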