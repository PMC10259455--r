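// Hierarchical Bayesian sampler for the four-parameter diffusion model.
//
// Model:
//   v_i   ~ Normal(mu_v, sigma_v)                 mu_v    ~ U[-5, 5]
//   a_i   ~ Normal(mu_a, sigma_a), a_i in (0,10]  mu_a    ~ U(0, 10]
//   zl_i  ~ Normal(eta_z, sigma_z)  (zl = logit z) eta_z  ~ U[-6.9, 6.9]
//   t0_i  ~ Normal(mu_t0, sigma_t0), t0 in [0,12] mu_t0   ~ U[0, 12]
//   sigma_* ~ U(0.01, 5]
//
// One sweep = per-subject single-site random-walk Metropolis on
// (v_i, a_i, zl_i, t0_i), then exact truncated-normal Gibbs draws for the
// four group means and log-scale random-walk Metropolis for the four group
// spreads. Subject proposal scales adapt toward 20-50% acceptance during
// burn-in and are frozen afterwards. All randomness uses R's RNG so that
// set.seed() in R makes runs reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

double subject_loglik(const double* rt, const int* up, int n,
                      double v, double a, double w, double t0);

static double rtnorm1(double mu, double sd, double lo, double hi) {
  double plo = Rf_pnorm5(lo, mu, sd, 1, 0), phi = Rf_pnorm5(hi, mu, sd, 1, 0);
  double u = plo + unif_rand() * (phi - plo);
  if (u < 1e-12) u = 1e-12;
  if (u > 1.0 - 1e-12) u = 1.0 - 1e-12;
  double x = Rf_qnorm5(u, mu, sd, 1, 0);
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

static inline double dnorm_l(double x, double mu, double sd) {
  double zz = (x - mu) / sd;
  return -0.5 * zz * zz - std::log(sd) - 0.5 * std::log(2.0 * M_PI);
}

static inline double plogis_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Parameter layout per subject: 0=v, 1=a, 2=zl (logit z), 3=t0
static const double SUBJ_LO[4] = {-5.0, 1e-3, -10.0, 0.0};
static const double SUBJ_HI[4] = { 5.0, 10.0,  10.0, 12.0};

// Group layout: 0=mu_v 1=sigma_v 2=mu_a 3=sigma_a 4=eta_z 5=sigma_z 6=mu_t0 7=sigma_t0
static const double MU_LO[4] = {-5.0, 1e-2, -6.9, 0.0};
static const double MU_HI[4] = { 5.0, 10.0,  6.9, 12.0};
static const double SD_LO = 0.01, SD_HI = 5.0;

// [[Rcpp::export]]
List hddm_mcmc_cpp(NumericVector rt, IntegerVector upper, IntegerVector offset,
                   NumericMatrix subj_init, NumericVector group_init,
                   int n_iter, int n_burn, int thin, int adapt_every) {
  RNGScope scope;
  int n_subj = subj_init.nrow();
  int n_keep = (n_iter - n_burn) / thin;

  std::vector<double> th(n_subj * 4);
  for (int i = 0; i < n_subj; ++i)
    for (int j = 0; j < 4; ++j) th[i * 4 + j] = subj_init(i, j);
  double gr[8];
  for (int j = 0; j < 8; ++j) gr[j] = group_init[j];

  const double* rtp = REAL(rt);
  const int* upp = INTEGER(upper);
  const int* off = INTEGER(offset); // length n_subj + 1, trials sorted by subject

  // cached data log-likelihood per subject
  std::vector<double> ll(n_subj);
  for (int i = 0; i < n_subj; ++i)
    ll[i] = subject_loglik(rtp + off[i], upp + off[i], off[i + 1] - off[i],
                           th[i * 4], th[i * 4 + 1], plogis_(th[i * 4 + 2]), th[i * 4 + 3]);

  // adaptive proposal scales
  std::vector<double> scale(n_subj * 4, 0.15);
  std::vector<int> acc(n_subj * 4, 0), tries(n_subj * 4, 0);
  double sd_scale[4] = {0.15, 0.15, 0.15, 0.15};
  int sd_acc[4] = {0, 0, 0, 0}, sd_tries[4] = {0, 0, 0, 0};
  long acc_total = 0, try_total = 0;

  NumericMatrix group_out(n_keep, 8);
  NumericVector subj_out(n_keep * n_subj * 4);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // ---- subject updates ----
    for (int i = 0; i < n_subj; ++i) {
      double* t = &th[i * 4];
      for (int j = 0; j < 4; ++j) {
        int idx = i * 4 + j;
        double cur = t[j];
        double prop = cur + scale[idx] * norm_rand();
        tries[idx]++; try_total++;
        if (prop < SUBJ_LO[j] || prop > SUBJ_HI[j]) continue;
        double mu = gr[2 * j], sd = gr[2 * j + 1];
        double lp_cur = dnorm_l(cur, mu, sd), lp_prop = dnorm_l(prop, mu, sd);
        double tmp[4] = {t[0], t[1], t[2], t[3]};
        tmp[j] = prop;
        double ll_prop = subject_loglik(rtp + off[i], upp + off[i],
                                        off[i + 1] - off[i],
                                        tmp[0], tmp[1], plogis_(tmp[2]), tmp[3]);
        if (ll_prop == R_NegInf) continue;
        double la = (ll_prop + lp_prop) - (ll[i] + lp_cur);
        if (la >= 0.0 || std::log(unif_rand()) < la) {
          t[j] = prop; ll[i] = ll_prop;
          acc[idx]++; acc_total++;
        }
      }
    }

    // ---- group means: exact truncated-normal Gibbs ----
    for (int j = 0; j < 4; ++j) {
      double m = 0.0;
      for (int i = 0; i < n_subj; ++i) m += th[i * 4 + j];
      m /= n_subj;
      gr[2 * j] = rtnorm1(m, gr[2 * j + 1] / std::sqrt((double)n_subj),
                          MU_LO[j], MU_HI[j]);
    }

    // ---- group spreads: random walk on log(sigma), Jacobian included ----
    for (int j = 0; j < 4; ++j) {
      double sd = gr[2 * j + 1], mu = gr[2 * j];
      double ss = 0.0;
      for (int i = 0; i < n_subj; ++i) {
        double d = th[i * 4 + j] - mu;
        ss += d * d;
      }
      double lsd = std::log(sd);
      double lprop = lsd + sd_scale[j] * norm_rand();
      double sdp = std::exp(lprop);
      sd_tries[j]++;
      if (sdp < SD_LO || sdp > SD_HI) continue;
      // log target on the log-sigma scale: -n log sd - ss/(2 sd^2) + log sd
      double lt_cur = -(double)n_subj * lsd - ss / (2.0 * sd * sd) + lsd;
      double lt_prop = -(double)n_subj * lprop - ss / (2.0 * sdp * sdp) + lprop;
      if (lt_prop - lt_cur >= 0.0 || std::log(unif_rand()) < lt_prop - lt_cur) {
        gr[2 * j + 1] = sdp; sd_acc[j]++;
      }
    }

    // ---- adaptation during burn-in ----
    if (it < n_burn && adapt_every > 0 && (it + 1) % adapt_every == 0) {
      for (size_t k = 0; k < scale.size(); ++k) {
        if (tries[k] > 0) {
          double r = (double)acc[k] / tries[k];
          if (r > 0.5) scale[k] *= 1.25;
          else if (r < 0.2) scale[k] *= 0.8;
        }
        acc[k] = 0; tries[k] = 0;
      }
      for (int j = 0; j < 4; ++j) {
        if (sd_tries[j] > 0) {
          double r = (double)sd_acc[j] / sd_tries[j];
          if (r > 0.5) sd_scale[j] *= 1.25;
          else if (r < 0.2) sd_scale[j] *= 0.8;
        }
        sd_acc[j] = 0; sd_tries[j] = 0;
      }
    }

    // ---- retain ----
    if (it >= n_burn && (it - n_burn) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < 8; ++j) group_out(kept, j) = gr[j];
      for (int i = 0; i < n_subj; ++i)
        for (int j = 0; j < 4; ++j)
          subj_out[kept + n_keep * (i * 4 + j)] = th[i * 4 + j];
      kept++;
    }
  }

  subj_out.attr("dim") = IntegerVector::create(n_keep, 4, n_subj);
  return List::create(_["group"] = group_out, _["subject"] = subj_out,
                      _["acceptance"] = try_total > 0 ? (double)acc_total / try_total : NA_REAL);
}
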