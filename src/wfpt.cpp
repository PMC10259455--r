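// Wiener first-passage-time machinery for the four-parameter diffusion model.
//
// Conventions (shared with the R layer):
//   - boundaries at 0 (lower) and a (upper); start at w*a with w in (0,1)
//   - drift v is signed toward the upper boundary; diffusion coefficient 1
//   - the upper boundary is the veracity-promoting response
//   - time axis is the model's decision axis (log-millisecond RT convention);
//     rt = t0 + decision time
//
// The defective density at the lower boundary is evaluated with the dual
// small-time / large-time series, switching by whichever needs fewer terms
// at truncation tolerance EPS. The upper-boundary density is the lower
// density under (v, w) -> (-v, 1 - w).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double EPS = 1e-7; // series truncation tolerance

// terms needed by the small-time expansion at scaled time u
static double n_terms_small(double u) {
  if (2.0 * std::sqrt(2.0 * M_PI * u) * EPS < 1.0) {
    double k = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * EPS * std::sqrt(2.0 * M_PI * u)));
    return std::max(k, std::sqrt(u) + 1.0);
  }
  return 2.0;
}

// terms needed by the large-time expansion at scaled time u
static double n_terms_large(double u) {
  if (M_PI * u * EPS < 1.0) {
    double k = std::sqrt(-2.0 * std::log(M_PI * u * EPS) / (M_PI * M_PI * u));
    return std::max(k, 1.0 / (M_PI * std::sqrt(u)));
  }
  return 1.0 / (M_PI * std::sqrt(u));
}

static double f1_small(double u, double w, int kmax) {
  double s = 0.0;
  for (int k = -kmax; k <= kmax; ++k) {
    double x = w + 2.0 * k;
    s += x * std::exp(-x * x / (2.0 * u));
  }
  return s / std::sqrt(2.0 * M_PI * u * u * u);
}

static double f1_large(double u, double w, int kmax) {
  double s = 0.0;
  for (int k = 1; k <= kmax; ++k)
    s += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
  return s * M_PI;
}

// log defective density of absorption at the LOWER boundary at decision time t
double wfpt_lpdf_lower(double t, double v, double a, double w) {
  if (!(t > 0.0)) return R_NegInf;
  double u = t / (a * a);
  double ks = n_terms_small(u), kl = n_terms_large(u);
  double f1;
  if (ks < kl)
    f1 = f1_small(u, w, (int)std::ceil((ks - 1.0) / 2.0));
  else
    f1 = f1_large(u, w, (int)std::ceil(kl));
  if (!(f1 > 0.0)) return R_NegInf; // underflow / alternating-series dust
  return std::log(f1) - v * a * w - v * v * t / 2.0 - 2.0 * std::log(a);
}

double wfpt_lpdf(double t, double v, double a, double w, bool upper) {
  return upper ? wfpt_lpdf_lower(t, -v, a, 1.0 - w) : wfpt_lpdf_lower(t, v, a, w);
}

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector t, double v, double a, double w,
                               bool upper, bool log_scale) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double lp = wfpt_lpdf(t[i], v, a, w, upper);
    out[i] = log_scale ? lp : std::exp(lp);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector trial_loglik_cpp(NumericVector rt, IntegerVector upper,
                               double v, double a, double w, double t0) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = wfpt_lpdf(rt[i] - t0, v, a, w, upper[i] == 1);
  return out;
}

// summed log-likelihood for one subject's trials (fast path for the sampler)
double subject_loglik(const double* rt, const int* up, int n,
                      double v, double a, double w, double t0) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double lp = wfpt_lpdf(rt[i] - t0, v, a, w, up[i] == 1);
    if (lp == R_NegInf) return R_NegInf;
    s += lp;
  }
  return s;
}

// Euler-Maruyama path simulation with Brownian-bridge crossing correction.
// The bridge term removes the O(sqrt(dt)) first-passage bias of the naive
// scheme, which the simulator-vs-density KS oracle would otherwise detect.
// [[Rcpp::export]]
List rddm_cpp(int n, double v, double a, double w, double t0, double dt) {
  RNGScope scope;
  NumericVector rt(n);
  IntegerVector up(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = w * a, t = 0.0;
    int b = -1;
    while (b < 0) {
      double xn = x + v * dt + sdt * norm_rand();
      t += dt;
      if (xn >= a) { b = 1; }
      else if (xn <= 0.0) { b = 0; }
      else {
        double pu = std::exp(-2.0 * (a - x) * (a - xn) / dt);
        if (unif_rand() < pu) b = 1;
        else {
          double pl = std::exp(-2.0 * x * xn / dt);
          if (unif_rand() < pl) b = 0;
        }
      }
      x = xn;
      if (t > 500.0) b = (x > 0.5 * a) ? 1 : 0; // unreachable for sane params
    }
    rt[i] = t0 + t;
    up[i] = b;
  }
  return List::create(_["rt"] = rt, _["upper"] = up);
}
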