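#' Define a combination of policies to evaluate jointly
#'
#' A combination is a signed set of policies whose log effects are summed
#' per posterior draw: +1 means the policy is present in the regime being
#' evaluated, -1 means it is absent (its effect is subtracted, i.e. the
#' contrast is against a regime that has it).
#'
#' @param name Combination name.
#' @param policy_id Character vector of policy ids.
#' @param sign Integer vector of +1/-1, recycled if scalar.
#' @return A list of class `"combo_spec"`.
#' @export
combo_spec <- function(name, policy_id, sign = 1L) {
  sign <- rep_len(as.integer(sign), length(policy_id))
  if (!length(policy_id)) stop("combination must be nonempty")
  bad <- setdiff(policy_id, policy_ids())
  if (length(bad)) stop("unknown policy in combo: ", paste(bad, collapse = ", "))
  if (!all(sign %in% c(-1L, 1L))) stop("sign must be +1 or -1")
  structure(list(name = name, policy_id = policy_id, sign = sign),
            class = "combo_spec")
}

#' Built-in policy combinations
#'
#' The six conceptual policy classes (each member entering with +1), the two
#' broader combinations — purchase-and-possession (the six restrictive
#' purchase/possession policies) and restrictive use-and-storage (child
#' access present, carry deregulation and stand-your-ground absent) — and
#' the most-restrictive regime (all seven restrictive policies present, all
#' three permissive policies absent) contrasted against the most permissive.
#'
#' @return Named list of `"combo_spec"` objects.
#' @export
policy_combos <- function() {
  pol <- firearm_policies()
  combos <- list()
  for (cl in unique(pol$class)) {
    ids <- pol$policy_id[pol$class == cl]
    combos[[cl]] <- combo_spec(cl, ids, 1L)
  }
  pp <- pol$policy_id[pol$combination == "purchase_possession"]
  combos$purchase_possession <- combo_spec("purchase_possession", pp, 1L)
  us <- pol$policy_id[pol$combination == "use_storage"]
  us_sign <- ifelse(pol$direction[match(us, pol$policy_id)] == "restrictive",
                    1L, -1L)
  combos$use_storage <- combo_spec("use_storage", us, us_sign)
  mr_sign <- ifelse(pol$direction == "restrictive", 1L, -1L)
  combos$most_restrictive <- combo_spec("most_restrictive", pol$policy_id,
                                        mr_sign)
  combos
}

# normalize draw containers: a gp_fit or list(beta_inst=, beta_slope=) of
# S x P matrices with policy-id column names
effect_draw_mats <- function(x) {
  if (inherits(x, "gp_fit")) {
    pols <- x$dims$policies
    list(beta_inst = {
      m <- x$draws[, paste0("beta_inst[", pols, "]"), drop = FALSE]
      colnames(m) <- pols; m
    }, beta_slope = {
      m <- x$draws[, paste0("beta_slope[", pols, "]"), drop = FALSE]
      colnames(m) <- pols; m
    })
  } else if (is.list(x) && !is.null(x$beta_inst) && !is.null(x$beta_slope)) {
    stopifnot(identical(dim(x$beta_inst), dim(x$beta_slope)))
    x
  } else stop("x must be a gp_fit or a list with beta_inst/beta_slope matrices")
}

#' Per-draw combined log effect of a policy combination
#'
#' For each posterior draw, the combined log effect at `t` years after
#' implementation: `l = sum over (p, sign) of sign * (beta_inst_p +
#' beta_slope_p * min(t / horizon, 1))`. At `t >= horizon` this is the signed
#' sum of total effects `theta_p`.
#'
#' @param x A `"gp_fit"` or a list with `beta_inst` and `beta_slope` draw
#'   matrices (columns named by policy id).
#' @param combo A `"combo_spec"`.
#' @param t Years since implementation (>= 0), default 5.
#' @param horizon Phase-in horizon, default 5.
#' @return Numeric vector of per-draw combined log effects.
#' @export
combine_draws <- function(x, combo, t = 5, horizon = 5) {
  stopifnot(inherits(combo, "combo_spec"), t >= 0)
  mats <- effect_draw_mats(x)
  miss <- setdiff(combo$policy_id, colnames(mats$beta_inst))
  if (length(miss))
    stop("combo references policies absent from the draws: ",
         paste(miss, collapse = ", "))
  w <- min(t / horizon, 1)
  l <- 0
  for (i in seq_along(combo$policy_id)) {
    p <- combo$policy_id[i]
    l <- l + combo$sign[i] * (mats$beta_inst[, p] + mats$beta_slope[, p] * w)
  }
  l
}

#' Summarize a combined-effect posterior
#'
#' Posterior median incidence rate ratio, equal-tailed 80% and 95% credible
#' intervals (order-statistic quantiles, type 1), and the posterior
#' probability of reduced deaths, `P(l < 0)`.
#'
#' @param l Numeric vector of per-draw combined log effects (>= 2 draws).
#' @return One-row data.frame of class `"effect_summary"` with columns
#'   `median_irr`, `lo80`, `hi80`, `lo95`, `hi95`, `p_reduced`.
#' @export
summarize_effect <- function(l) {
  if (length(l) < 2) stop("need at least 2 draws")
  q <- function(p) exp(stats::quantile(l, p, type = 1, names = FALSE))
  out <- data.frame(
    median_irr = exp(stats::median(l)),
    lo80 = q(0.10), hi80 = q(0.90),
    lo95 = q(0.025), hi95 = q(0.975),
    p_reduced = mean(l < 0)
  )
  class(out) <- c("effect_summary", "data.frame")
  out
}

#' Effect-by-time-since-implementation curve
#'
#' Evaluates [combine_draws()] on a grid of times since implementation and
#' summarizes each. The curve is constant for `t >= horizon` (the phase-in
#' is clipped).
#'
#' @inheritParams combine_draws
#' @param t_grid Nonnegative, sorted times.
#' @return data.frame: one row per `t` with the [summarize_effect()] columns.
#' @export
effect_curve <- function(x, combo, t_grid = seq(0, 6, by = 0.25),
                         horizon = 5) {
  if (is.unsorted(t_grid) || any(t_grid < 0))
    stop("t_grid must be nonnegative and sorted")
  rows <- lapply(t_grid, function(t)
    cbind(t = t, summarize_effect(combine_draws(x, combo, t, horizon))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Deaths averted implied by a combined effect
#'
#' Translates a combined log effect into deaths averted, per draw:
#' `averted = D * (1 - exp(l))`, where `D` is the number of deaths observed
#' under the baseline (permissive) regime. The convention — that observed
#' deaths arise under the baseline, so a 20% reduction of 350,000 deaths
#' averts 70,000 — is recorded in the returned metadata rather than hidden.
#'
#' @param l Per-draw combined log effects (typically at `t >= horizon`).
#' @param observed_deaths Nonnegative baseline death count `D`.
#' @return List of class `"deaths_averted"`: `draws` (per-draw averted
#'   deaths), `median`, `lo95`, `hi95`, `observed_deaths`, `convention`.
#' @export
deaths_averted <- function(l, observed_deaths) {
  if (observed_deaths < 0) stop("observed_deaths must be nonnegative")
  av <- observed_deaths * (1 - exp(l))
  structure(list(
    draws = av,
    median = stats::median(av),
    lo95 = stats::quantile(av, 0.025, type = 1, names = FALSE),
    hi95 = stats::quantile(av, 0.975, type = 1, names = FALSE),
    observed_deaths = observed_deaths,
    convention = "observed deaths arise under the permissive baseline regime"
  ), class = "deaths_averted")
}

#' Read tidy draws back into effect-draw matrices
#'
#' Inverse of [draws_tidy()] for the columns the effect combiners need:
#' reconstructs the `beta_inst` / `beta_slope` draw matrices from a tidy
#' draws CSV (columns `draw`, `chain`, `parameter`, `value`).
#'
#' @param path Path to a CSV written from [draws_tidy()].
#' @return List with `beta_inst` and `beta_slope` matrices (columns named by
#'   policy id), usable with [combine_draws()].
#' @export
read_draws <- function(path) {
  td <- utils::read.csv(path, stringsAsFactors = FALSE)
  grab <- function(prefix) {
    sel <- td[grepl(paste0("^", prefix, "\\["), td$parameter), ]
    pols <- unique(sub(paste0(prefix, "\\[(.*)\\]"), "\\1", sel$parameter))
    m <- vapply(pols, function(p)
      sel$value[sel$parameter == paste0(prefix, "[", p, "]")],
      numeric(sum(sel$parameter == sel$parameter[1])))
    colnames(m) <- pols
    m
  }
  list(beta_inst = grab("beta_inst"), beta_slope = grab("beta_slope"))
}

#' Summarize all built-in combinations
#'
#' @param x A `"gp_fit"` or draw-matrix list.
#' @param t Years since implementation, default 5.
#' @param horizon Phase-in horizon, default 5.
#' @return data.frame with one row per built-in combination.
#' @export
summarize_combos <- function(x, t = 5, horizon = 5) {
  combos <- policy_combos()
  out <- do.call(rbind, lapply(combos, function(cm)
    cbind(combo = cm$name,
          summarize_effect(combine_draws(x, cm, t, horizon)))))
  rownames(out) <- NULL
  out
}
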