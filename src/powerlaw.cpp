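// Clauset-style power-law fitting: Hurwitz zeta, discrete/continuous MLE,
// KS-minimizing xmin scan, and the semi-parametric bootstrap goodness-of-fit.
// Compiled because the 2500-resample bootstrap refits xmin and alpha on every
// resample; all randomness comes from R's RNG so set.seed() governs results.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hurwitz zeta(s, q) = sum_{k>=q} k^-s for s > 1, q >= 1, by direct summation
// of the first terms plus an Euler-Maclaurin tail correction.
static double hurwitz(double s, double q) {
  const int N = 24; // explicit terms before the tail expansion
  double sum = 0.0;
  double a = q;
  for (int k = 0; k < N; ++k, a += 1.0) sum += std::pow(a, -s);
  // tail starting at a: a^(1-s)/(s-1) + a^-s/2 + s*a^(-s-1)/12 - ...
  double as = std::pow(a, -s);
  double tail = a * as / (s - 1.0) + 0.5 * as;
  double t1 = s * as / a / 12.0;
  double t2 = s * (s + 1.0) * (s + 2.0) * as / (a * a * a) / 720.0;
  double t3 = s * (s + 1.0) * (s + 2.0) * (s + 3.0) * (s + 4.0) * as /
              (a * a * a * a * a) / 30240.0;
  return sum + tail + t1 - t2 + t3;
}

// [[Rcpp::export]]
double cpp_hurwitz_zeta(double s, double q) {
  if (s <= 1.0) stop("hurwitz zeta requires s > 1");
  if (q < 1.0) stop("hurwitz zeta requires q >= 1");
  return hurwitz(s, q);
}

// negative log-likelihood of the discrete power law on the tail
static double nll_discrete(double alpha, double xmin, double sum_log, int n) {
  return n * std::log(hurwitz(alpha, xmin)) + alpha * sum_log;
}

// golden-section minimisation of the discrete nll over alpha in (lo, hi)
static double mle_discrete(double xmin, double sum_log, int n) {
  const double gr = 0.61803398874989484820;
  double lo = 1.000001, hi = 25.0;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = nll_discrete(x1, xmin, sum_log, n);
  double f2 = nll_discrete(x2, xmin, sum_log, n);
  for (int it = 0; it < 200 && (hi - lo) > 1e-9; ++it) {
    if (f1 < f2) {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo);
      f1 = nll_discrete(x1, xmin, sum_log, n);
    } else {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo);
      f2 = nll_discrete(x2, xmin, sum_log, n);
    }
  }
  return 0.5 * (lo + hi);
}

// KS distance on the tail, discrete case. tail is sorted ascending.
static double ks_discrete(const std::vector<double>& tail, double alpha,
                          double xmin) {
  int n = (int)tail.size();
  double zx = hurwitz(alpha, xmin);
  double D = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && tail[j] == tail[i]) ++j;
    double v = tail[i];
    // theoretical CDF at v and just before the atom at v; both step
    // functions jump at the integers, and in a run of unobserved integers
    // the gap |emp - F| is largest right before the next observed atom,
    // so comparing (emp at v, F at v) and (emp below v, F below v) covers
    // the whole support
    double F = 1.0 - hurwitz(alpha, v + 1.0) / zx;
    double Fm = 1.0 - hurwitz(alpha, v) / zx;
    double emp_hi = (double)j / n;       // empirical CDF at v
    double emp_lo = (double)i / n;       // just below v
    double d = std::max(std::fabs(emp_hi - F), std::fabs(emp_lo - Fm));
    if (d > D) D = d;
    i = j;
  }
  return D;
}

// KS distance on the tail, continuous case. tail sorted ascending.
static double ks_continuous(const std::vector<double>& tail, double alpha,
                            double xmin) {
  int n = (int)tail.size();
  double D = 0.0;
  for (int i = 0; i < n; ++i) {
    double F = 1.0 - std::pow(tail[i] / xmin, 1.0 - alpha);
    double d = std::max(std::fabs((i + 1.0) / n - F), std::fabs((double)i / n - F));
    if (d > D) D = d;
  }
  return D;
}

struct FitResult {
  double alpha, xmin, D;
  int n_tail;
  bool ok;
};

// Fit alpha and (optionally) xmin to sorted data by minimising KS distance
// over candidate xmin values (the unique observed values). fixed_xmin = NA
// means scan; ties broken by the smallest xmin.
static FitResult fit_one(const std::vector<double>& x_sorted, bool discrete,
                         double fixed_xmin) {
  FitResult best; best.ok = false; best.D = R_PosInf;
  best.alpha = NA_REAL; best.xmin = NA_REAL; best.n_tail = 0;
  int n = (int)x_sorted.size();
  std::vector<double> cands;
  if (ISNA(fixed_xmin)) {
    for (int i = 0; i < n; ++i)
      if (i == 0 || x_sorted[i] != x_sorted[i - 1]) cands.push_back(x_sorted[i]);
  } else {
    cands.push_back(fixed_xmin);
  }
  for (double xm : cands) {
    // tail = observations >= xm
    size_t lo = std::lower_bound(x_sorted.begin(), x_sorted.end(), xm) -
                x_sorted.begin();
    int nt = n - (int)lo;
    if (nt < 2) continue;
    std::vector<double> tail(x_sorted.begin() + lo, x_sorted.end());
    double sum_log = 0.0;
    for (double v : tail) sum_log += std::log(v / xm);
    if (sum_log <= 0.0) continue; // all tail values equal: no spread
    double alpha, D;
    if (discrete) {
      double sl = 0.0;
      for (double v : tail) sl += std::log(v);
      alpha = mle_discrete(xm, sl, nt);
      D = ks_discrete(tail, alpha, xm);
    } else {
      alpha = 1.0 + nt / sum_log;
      D = ks_continuous(tail, alpha, xm);
    }
    if (D < best.D) {
      best.alpha = alpha; best.xmin = xm; best.D = D;
      best.n_tail = nt; best.ok = true;
    }
  }
  return best;
}

// Build the discrete tail CDF table for sampling: P(X <= xmin + k - 1).
static std::vector<double> discrete_cdf_table(double alpha, double xmin,
                                              double eps = 1e-9,
                                              int max_len = 2000000) {
  std::vector<double> cdf;
  double z = hurwitz(alpha, xmin);
  double acc = 0.0;
  double k = xmin;
  while ((int)cdf.size() < max_len) {
    acc += std::pow(k, -alpha) / z;
    cdf.push_back(acc);
    if (1.0 - acc < eps) break;
    k += 1.0;
  }
  return cdf;
}

static double draw_discrete_tail(const std::vector<double>& cdf, double alpha,
                                 double xmin) {
  double u = R::unif_rand();
  if (u > cdf.back()) {
    // beyond the table: continuous approximation to the zeta tail
    return std::floor((xmin - 0.5) * std::pow(1.0 - u, -1.0 / (alpha - 1.0)) + 0.5);
  }
  size_t j = std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin();
  return xmin + (double)j;
}

// [[Rcpp::export]]
List cpp_fit_powerlaw(NumericVector x, bool discrete, double fixed_xmin,
                      int n_boot) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  FitResult obs = fit_one(xs, discrete, fixed_xmin);
  if (!obs.ok)
    stop("power-law fit failed: zero log-spread or fewer than 2 tail observations");
  double boot_p = NA_REAL;
  if (n_boot > 0) {
    int n = (int)xs.size();
    std::vector<double> body;
    for (double v : xs) if (v < obs.xmin) body.push_back(v);
    double p_tail = (double)obs.n_tail / n;
    std::vector<double> cdf;
    if (discrete) cdf = discrete_cdf_table(obs.alpha, obs.xmin);
    int exceed = 0;
    std::vector<double> sim(n);
    for (int b = 0; b < n_boot; ++b) {
      for (int i = 0; i < n; ++i) {
        if (body.empty() || R::unif_rand() < p_tail) {
          if (discrete) {
            sim[i] = draw_discrete_tail(cdf, obs.alpha, obs.xmin);
          } else {
            sim[i] = obs.xmin *
                     std::pow(1.0 - R::unif_rand(), -1.0 / (obs.alpha - 1.0));
          }
        } else {
          sim[i] = body[(size_t)(R::unif_rand() * body.size())];
        }
      }
      std::sort(sim.begin(), sim.end());
      FitResult fb = fit_one(sim, discrete, NA_REAL);
      if (fb.ok && fb.D > obs.D) ++exceed;
      if (b % 64 == 0) Rcpp::checkUserInterrupt();
    }
    boot_p = (double)exceed / n_boot;
  }
  return List::create(_["alpha"] = obs.alpha, _["xmin"] = obs.xmin,
                      _["ks_D"] = obs.D, _["n_tail"] = obs.n_tail,
                      _["boot_p"] = boot_p);
}

// [[Rcpp::export]]
NumericVector cpp_sample_powerlaw(int n, double alpha, double xmin,
                                  bool discrete) {
  if (alpha <= 1.0) stop("alpha must exceed 1");
  NumericVector out(n);
  if (discrete) {
    std::vector<double> cdf = discrete_cdf_table(alpha, xmin);
    for (int i = 0; i < n; ++i) out[i] = draw_discrete_tail(cdf, alpha, xmin);
  } else {
    for (int i = 0; i < n; ++i)
      out[i] = xmin * std::pow(1.0 - R::unif_rand(), -1.0 / (alpha - 1.0));
  }
  return out;
}
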