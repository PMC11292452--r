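#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Parameter packing (shared with R/fit.R):
//   [0]            alpha
//   [1 .. T-1]     year offsets for analysis years 2..T (year 1 = reference)
//   [.. +K1]       beta_conf
//   [.. +K2]       beta_other
//   [.. +1]        rho1
//   [.. +1]        rho2
//   [.. +P]        beta_inst
//   [.. +P]        beta_slope
//   [last]         log_phi

struct PanelData {
  IntegerVector y;
  NumericVector logN, a1, a2;
  IntegerVector year_idx;            // 1-based
  NumericMatrix Xc, Xo, E, F, E1, F1, E2, F2;
  int T, K1, K2, P, n;
  bool debias;
  double sum_lgamma_y1;              // sum of lgamma(y + 1), constant
  double mean_a1 = 0.0;
  // cache of phi-dependent likelihood pieces (phi changes rarely in MWG)
  mutable double cached_phi = -1.0;
  mutable double cached_sum_lgamma_yphi = 0.0, cached_lgamma_phi = 0.0;
};

static PanelData unpack_data(const List& data, bool debias) {
  PanelData d;
  d.y = data["y"];
  d.logN = data["log_N"];
  d.a1 = data["a1"];
  d.a2 = data["a2"];
  d.year_idx = data["year_idx"];
  d.Xc = as<NumericMatrix>(data["X_conf"]);
  d.Xo = as<NumericMatrix>(data["X_other"]);
  d.E = as<NumericMatrix>(data["E"]);
  d.F = as<NumericMatrix>(data["F"]);
  d.E1 = as<NumericMatrix>(data["E1"]);
  d.F1 = as<NumericMatrix>(data["F1"]);
  d.E2 = as<NumericMatrix>(data["E2"]);
  d.F2 = as<NumericMatrix>(data["F2"]);
  d.T = as<int>(data["n_years"]);
  d.K1 = d.Xc.ncol();
  d.K2 = d.Xo.ncol();
  d.P = d.E.ncol();
  d.n = d.y.size();
  d.debias = debias;
  d.sum_lgamma_y1 = 0.0;
  for (int i = 0; i < d.n; ++i) d.sum_lgamma_y1 += lgamma(d.y[i] + 1.0);
  double ma = 0.0;
  for (int i = 0; i < d.n; ++i) ma += d.a1[i];
  d.mean_a1 = d.n ? ma / d.n : 0.0;
  return d;
}

static double log_posterior(const double* par, int K, const PanelData& d,
                            const double* pm, const double* ps,
                            const int* ptype) {
  int off = 0;
  const double alpha = par[off]; off += 1;
  const int year_off = off; off += d.T - 1;
  const int bc_off = off; off += d.K1;
  const int bo_off = off; off += d.K2;
  const double rho1 = par[off]; off += 1;
  const double rho2 = par[off]; off += 1;
  const int bi_off = off; off += d.P;
  const int bs_off = off; off += d.P;
  const double log_phi = par[off];
  if (log_phi > 30.0 || log_phi < -30.0) return R_NegInf;
  const double phi = exp(log_phi);
  if (phi != d.cached_phi) {
    double s = 0.0;
    for (int i = 0; i < d.n; ++i) s += lgamma(d.y[i] + phi);
    d.cached_sum_lgamma_yphi = s;
    d.cached_lgamma_phi = lgamma(phi);
    d.cached_phi = phi;
  }
  const double phi_log_phi = phi * log_phi;

  std::vector<double> eta(d.n);
  for (int i = 0; i < d.n; ++i) {
    double e = d.logN[i] + alpha + rho1 * d.a1[i] + rho2 * d.a2[i];
    if (d.year_idx[i] > 1) e += par[year_off + d.year_idx[i] - 2];
    eta[i] = e;
  }
  for (int k = 0; k < d.K1; ++k) {
    const double b = par[bc_off + k];
    const double* col = &d.Xc(0, k);
    for (int i = 0; i < d.n; ++i) eta[i] += b * col[i];
  }
  for (int k = 0; k < d.K2; ++k) {
    const double b = par[bo_off + k];
    const double* col = &d.Xo(0, k);
    for (int i = 0; i < d.n; ++i) eta[i] += b * col[i];
  }
  for (int p = 0; p < d.P; ++p) {
    const double bi = par[bi_off + p], bs = par[bs_off + p];
    if (bi == 0.0 && bs == 0.0) continue;
    const double *e0 = &d.E(0, p), *f0 = &d.F(0, p);
    if (d.debias) {
      const double *e1 = &d.E1(0, p), *f1 = &d.F1(0, p);
      const double *e2 = &d.E2(0, p), *f2 = &d.F2(0, p);
      for (int i = 0; i < d.n; ++i)
        eta[i] += bi * (e0[i] - rho1 * e1[i] - rho2 * e2[i]) +
                  bs * (f0[i] - rho1 * f1[i] - rho2 * f2[i]);
    } else {
      for (int i = 0; i < d.n; ++i)
        eta[i] += bi * e0[i] + bs * f0[i];
    }
  }

  double ll = d.cached_sum_lgamma_yphi - d.n * d.cached_lgamma_phi -
    d.sum_lgamma_y1 + d.n * phi_log_phi;
  for (int i = 0; i < d.n; ++i) {
    const double e = eta[i];
    if (e > 40.0 || e < -60.0) return R_NegInf;  // overflow guard
    const double lse = log(phi + exp(e));
    ll += -phi * lse + d.y[i] * (e - lse);
  }

  // priors: ptype 0 = normal(pm, ps), 1 = Laplace(pm, scale ps)
  static const double LOG_SQRT_2PI = 0.9189385332046727;
  for (int k = 0; k < K; ++k) {
    const double z = (par[k] - pm[k]) / ps[k];
    if (ptype[k] == 0) ll += -0.5 * z * z - log(ps[k]) - LOG_SQRT_2PI;
    else ll += -fabs(z) - log(2.0 * ps[k]);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_log_posterior(NumericVector par, List data, NumericVector prior_mean,
                         NumericVector prior_sd, IntegerVector prior_type,
                         bool debias) {
  PanelData d = unpack_data(data, debias);
  return log_posterior(par.begin(), par.size(), d, prior_mean.begin(),
                       prior_sd.begin(), prior_type.begin());
}

// lower Cholesky of a copy of S (K x K); returns false if not positive
// definite
static bool cholesky(std::vector<double>& S, int K) {
  for (int j = 0; j < K; ++j) {
    double dsum = S[j * K + j];
    for (int k = 0; k < j; ++k) dsum -= S[j * K + k] * S[j * K + k];
    if (dsum <= 0.0) return false;
    const double diag = sqrt(dsum);
    S[j * K + j] = diag;
    for (int i = j + 1; i < K; ++i) {
      double s = S[i * K + j];
      for (int k = 0; k < j; ++k) s -= S[i * K + k] * S[j * K + k];
      S[i * K + j] = s / diag;
    }
    for (int k = j + 1; k < K; ++k) S[j * K + k] = 0.0;
  }
  return true;
}

// Adaptive MCMC: Metropolis-within-Gibbs sweeps (Roberts & Rosenthal batch
// adaptation of per-coordinate scales toward 0.44 acceptance) interleaved
// with a joint random-walk proposal whose covariance is the empirical
// posterior covariance accumulated during warmup (Haario-style, scaled by
// 2.38^2/K). Adaptation is frozen at the end of warmup. Uses R's RNG, so
// draws are byte-identical for a fixed set.seed().
// [[Rcpp::export]]
List cpp_mwg_sample(NumericVector init, List data, NumericVector prior_mean,
                    NumericVector prior_sd, IntegerVector prior_type,
                    bool debias, int n_warmup, int n_keep, int thin,
                    NumericVector init_step) {
  PanelData d = unpack_data(data, debias);
  const int K = init.size();
  const double* pm = prior_mean.begin();
  const double* ps = prior_sd.begin();
  const int* pt = prior_type.begin();
  std::vector<double> par(init.begin(), init.end());
  std::vector<double> step(init_step.begin(), init_step.end());
  double lp = log_posterior(par.data(), K, d, pm, ps, pt);
  if (!R_finite(lp)) stop("non-finite log posterior at initial values");

  const int n_total = n_warmup + n_keep * thin;
  NumericMatrix draws(n_keep, K);
  NumericVector lp_out(n_keep);
  NumericVector acc(K), batch_acc(K);
  int batch = 0, kept = 0;
  const int batch_size = 50;
  double step_lvl = 0.05, lvl_batch_acc = 0.0;
  double step_rho = 0.02, rho_batch_acc = 0.0;

  // running moments for the joint proposal covariance
  std::vector<double> mean_acc(K, 0.0), cov_acc((size_t)K * K, 0.0);
  std::vector<double> chol_L;
  long n_mom = 0;
  const int mom_start = std::min(200, n_warmup / 4);
  const int chol_every = 100;
  bool have_chol = false;
  double joint_scale = 2.38 * 2.38 / K, joint_acc = 0.0;
  long joint_tries = 0;
  std::vector<double> prop(K), z(K);

  // rho1 and rho2 ride a narrow anti-correlated ridge (lagged log rates are
  // nearly collinear), so their two sweep slots propose along the rotated
  // sum/difference directions instead of the axes
  const int rho1_idx = 1 + (d.T - 1) + d.K1 + d.K2;
  const int rho2_idx = rho1_idx + 1;
  const double INV_SQRT2 = 0.7071067811865476;
  // each policy's instant effect and phase-in slope are likewise
  // anti-correlated (only their sum theta is well identified), so those
  // slot pairs also propose along sum/difference directions
  const int bi_idx = rho2_idx + 1, bs_idx = bi_idx + d.P;
  auto pair_of = [&](int k) -> int {
    if (k == rho1_idx) return rho2_idx;
    if (k == rho2_idx) return rho1_idx;
    if (k >= bi_idx && k < bs_idx) return k + d.P;
    if (k >= bs_idx && k < bs_idx + d.P) return k - d.P;
    return -1;
  };

  RNGScope scope;
  for (int iter = 1; iter <= n_total; ++iter) {
    for (int k = 0; k < K; ++k) {
      const int mate = pair_of(k);
      const double old1 = par[k];
      const double old2 = (mate >= 0) ? par[mate] : 0.0;
      const double delta = step[k] * norm_rand();
      if (mate >= 0) {
        const double sgn = (mate > k) ? 1.0 : -1.0;  // sum vs difference slot
        const int lo = std::min(k, mate), hi = std::max(k, mate);
        par[lo] += delta * INV_SQRT2;
        par[hi] += sgn * delta * INV_SQRT2;
      } else {
        par[k] = old1 + delta;
      }
      const double lp_new = log_posterior(par.data(), K, d, pm, ps, pt);
      if (R_finite(lp_new) && log(unif_rand()) < lp_new - lp) {
        lp = lp_new;
        acc[k] += 1.0;
        batch_acc[k] += 1.0;
      } else {
        par[k] = old1;
        if (mate >= 0) par[mate] = old2;
      }
    }

    // level move: alpha and all year offsets trade off along a ridge (only
    // reference-year rows identify them separately), so propose the
    // compensating direction alpha += c, year[.] -= c with its own scale
    if (d.T > 1) {
      const double c = step_lvl * norm_rand();
      par[0] += c;
      for (int k = 1; k < d.T; ++k) par[k] -= c;
      const double lp_new = log_posterior(par.data(), K, d, pm, ps, pt);
      if (R_finite(lp_new) && log(unif_rand()) < lp_new - lp) {
        lp = lp_new;
        lvl_batch_acc += 1.0;
      } else {
        par[0] -= c;
        for (int k = 1; k < d.T; ++k) par[k] += c;
      }
    }

    // persistence move: increasing rho1 + rho2 by u while lowering alpha by
    // u * mean(a1) leaves the fit at the average lag level unchanged — the
    // direction along which alpha and the AR coefficients trade off
    {
      const double u = step_rho * norm_rand();
      par[rho1_idx] += 0.5 * u;
      par[rho2_idx] += 0.5 * u;
      par[0] -= u * d.mean_a1;
      const double lp_new = log_posterior(par.data(), K, d, pm, ps, pt);
      if (R_finite(lp_new) && log(unif_rand()) < lp_new - lp) {
        lp = lp_new;
        rho_batch_acc += 1.0;
      } else {
        par[rho1_idx] -= 0.5 * u;
        par[rho2_idx] -= 0.5 * u;
        par[0] += u * d.mean_a1;
      }
    }

    if (iter > mom_start && iter <= n_warmup) {
      ++n_mom;
      for (int i = 0; i < K; ++i) {
        const double di = par[i] - mean_acc[i];
        mean_acc[i] += di / n_mom;
        for (int j = 0; j <= i; ++j)
          cov_acc[(size_t)i * K + j] += di * (par[j] - mean_acc[j]);
      }
      if (n_mom >= 2 * K && iter % chol_every == 0) {
        chol_L.assign((size_t)K * K, 0.0);
        for (int i = 0; i < K; ++i)
          for (int j = 0; j <= i; ++j) {
            double v = cov_acc[(size_t)i * K + j] / (n_mom - 1) * joint_scale;
            chol_L[(size_t)i * K + j] = v;
            chol_L[(size_t)j * K + i] = v;
          }
        for (int i = 0; i < K; ++i)
          chol_L[(size_t)i * K + i] += 1e-10 * joint_scale;
        have_chol = cholesky(chol_L, K);
      }
    }

    if (have_chol) {
      for (int k = 0; k < K; ++k) z[k] = norm_rand();
      for (int i = 0; i < K; ++i) {
        double s = par[i];
        for (int j = 0; j <= i; ++j) s += chol_L[(size_t)i * K + j] * z[j];
        prop[i] = s;
      }
      const double lp_new = log_posterior(prop.data(), K, d, pm, ps, pt);
      ++joint_tries;
      if (R_finite(lp_new) && log(unif_rand()) < lp_new - lp) {
        par = prop;
        lp = lp_new;
        joint_acc += 1.0;
      }
    }

    if (iter <= n_warmup && iter % batch_size == 0) {
      ++batch;
      const double delta = std::min(0.25, 1.0 / sqrt((double)batch));
      for (int k = 0; k < K; ++k) {
        if (batch_acc[k] / batch_size > 0.44) step[k] *= exp(delta);
        else step[k] *= exp(-delta);
        batch_acc[k] = 0.0;
      }
      if (lvl_batch_acc / batch_size > 0.44) step_lvl *= exp(delta);
      else step_lvl *= exp(-delta);
      lvl_batch_acc = 0.0;
      if (rho_batch_acc / batch_size > 0.44) step_rho *= exp(delta);
      else step_rho *= exp(-delta);
      rho_batch_acc = 0.0;
    }
    if (iter > n_warmup && (iter - n_warmup) % thin == 0) {
      for (int k = 0; k < K; ++k) draws(kept, k) = par[k];
      lp_out[kept] = lp;
      ++kept;
    }
  }
  return List::create(
    _["draws"] = draws, _["lp"] = lp_out,
    _["accept_rate"] = acc / n_total,
    _["joint_accept_rate"] = joint_tries ? joint_acc / joint_tries : NA_REAL,
    _["step"] = step);
}
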