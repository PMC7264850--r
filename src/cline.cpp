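#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter layout (natural scale), always length 8:
//   0 center (m), 1 width (m), 2 pmin, 3 pmax,
//   4 deltaL (m), 5 tauL, 6 deltaR, 7 tauR
// model_type: 0 = null (linear), 1 = sigmoid, 2 = shared symmetric tails
// (slots 4/5 used for both sides), 3 = independent left/right tails.

static inline double phi_core(double d, double c, double w) {
  return 1.0 / (1.0 + std::exp(-4.0 * (d - c) / w));
}

static double cline_value_one(double d, int type, const double *th,
                              double xmin, double xmax) {
  const double pmin = th[2], pmax = th[3];
  if (type == 0) {
    double t = (xmax > xmin) ? (d - xmin) / (xmax - xmin) : 0.5;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    return pmin + (pmax - pmin) * t;
  }
  const double c = th[0], w = th[1];
  double phi = phi_core(d, c, w);
  if (type >= 2) {
    const double dL = th[4], tL = th[5];
    const double dR = (type == 2) ? th[4] : th[6];
    const double tR = (type == 2) ? th[5] : th[7];
    const double aL = c - dL, aR = c + dR;
    if (d <= aL) {
      // exponential left tail, C0 at the attachment point; slope ratio tauL
      const double pa = phi_core(aL, c, w);
      const double lam = tL * (4.0 / w) * (1.0 - pa); // tauL * phi'(aL)/phi(aL)
      phi = pa * std::exp(lam * (d - aL));
    } else if (d >= aR) {
      const double pa = phi_core(aR, c, w);
      const double lam = tR * (4.0 / w) * pa; // tauR * phi'(aR)/(1-phi(aR))
      phi = 1.0 - (1.0 - pa) * std::exp(-lam * (d - aR));
    }
  }
  return pmin + (pmax - pmin) * phi;
}

// [[Rcpp::export(name = ".cline_eval_cpp")]]
NumericVector cline_eval_cpp(NumericVector d, int type, NumericVector theta,
                             double xmin, double xmax) {
  const int n = d.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cline_value_one(d[i], type, theta.begin(), xmin, xmax);
  return out;
}

// kind: 0 = binomial frequency table (cols d, n, k)
//       1 = Gaussian trait table     (cols d, n, mean, var)
static double cline_loglik(int type, int kind, const NumericMatrix &data,
                           const double *th, double xmin, double xmax,
                           double eps) {
  const int nb = data.nrow();
  double ll = 0.0;
  for (int i = 0; i < nb; ++i) {
    double mu = cline_value_one(data(i, 0), type, th, xmin, xmax);
    if (kind == 0) {
      if (mu < eps) mu = eps;
      if (mu > 1.0 - eps) mu = 1.0 - eps;
      const double n = data(i, 1), k = data(i, 2);
      ll += k * std::log(mu) + (n - k) * std::log(1.0 - mu);
    } else {
      const double n = data(i, 1), m = data(i, 2), v = data(i, 3);
      ll += -0.5 * std::log(2.0 * M_PI * v / n) - n * (m - mu) * (m - mu) / (2.0 * v);
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".cline_loglik_cpp")]]
double cline_loglik_cpp(int type, int kind, NumericMatrix data,
                        NumericVector theta, double xmin, double xmax,
                        double eps) {
  return cline_loglik(type, kind, data, theta.begin(), xmin, xmax, eps);
}

// Transform map per slot: 0 identity, 1 log, 2 logit, 3 log1p
static const int TRANSFORM[8] = {0, 1, 2, 2, 3, 2, 3, 2};

static inline double to_phi(double x, int tr) {
  switch (tr) {
  case 1: return std::log(x);
  case 2: return std::log(x / (1.0 - x));
  case 3: return std::log1p(x);
  default: return x;
  }
}
static inline double from_phi(double p, int tr) {
  switch (tr) {
  case 1: return std::exp(p);
  case 2: return 1.0 / (1.0 + std::exp(-p));
  case 3: return std::expm1(p);
  default: return p;
  }
}
// log |d theta / d phi|, the Jacobian making the uniform-on-natural-scale
// prior correct when the walk lives on the transformed scale
static inline double log_jac(double x, int tr) {
  switch (tr) {
  case 1: return std::log(x);
  case 2: return std::log(x) + std::log(1.0 - x);
  case 3: return std::log1p(x);
  default: return 0.0;
  }
}

// Component-wise random-walk Metropolis-Hastings with burn-in scale
// adaptation. Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export(name = ".mh_chain_cpp")]]
List mh_chain_cpp(int type, int kind, NumericMatrix data, NumericVector init,
                  NumericVector scales, NumericMatrix bounds,
                  LogicalVector sample_mask, int nsteps, int burnin, int thin,
                  double eps, double xmin, double xmax) {
  RNGScope rng;
  double th[8], phi[8], sc[8];
  bool mask[8];
  for (int j = 0; j < 8; ++j) {
    th[j] = init[j];
    mask[j] = sample_mask[j];
    sc[j] = scales[j];
    phi[j] = mask[j] ? to_phi(th[j], TRANSFORM[j]) : 0.0;
  }
  double cur_ll = cline_loglik(type, kind, data, th, xmin, xmax, eps);
  double cur_lp = cur_ll;
  for (int j = 0; j < 8; ++j)
    if (mask[j]) cur_lp += log_jac(th[j], TRANSFORM[j]);

  double best_ll = cur_ll;
  double best_th[8];
  std::copy(th, th + 8, best_th);

  const int nsamp = (nsteps > burnin) ? (nsteps - burnin + thin - 1) / thin : 0;
  NumericMatrix samples(nsamp, 8);
  NumericVector lnl(nsamp);
  int isamp = 0;

  long acc[8] = {0}, tot[8] = {0};
  long acc_win[8] = {0}, tot_win[8] = {0};
  const int adapt_every = 50;

  for (int step = 0; step < nsteps; ++step) {
    for (int j = 0; j < 8; ++j) {
      if (!mask[j]) continue;
      const double phi_old = phi[j], th_old = th[j];
      const double phi_new = phi_old + sc[j] * norm_rand();
      const double th_new = from_phi(phi_new, TRANSFORM[j]);
      ++tot[j];
      ++tot_win[j];
      if (!std::isfinite(th_new) || th_new < bounds(j, 0) || th_new > bounds(j, 1))
        continue;
      th[j] = th_new;
      const double new_ll = cline_loglik(type, kind, data, th, xmin, xmax, eps);
      double new_lp = new_ll;
      for (int q = 0; q < 8; ++q)
        if (mask[q]) new_lp += log_jac(th[q], TRANSFORM[q]);
      if (std::isfinite(new_lp) &&
          (new_lp >= cur_lp || unif_rand() < std::exp(new_lp - cur_lp))) {
        phi[j] = phi_new;
        cur_ll = new_ll;
        cur_lp = new_lp;
        ++acc[j];
        ++acc_win[j];
        if (new_ll > best_ll) {
          best_ll = new_ll;
          std::copy(th, th + 8, best_th);
        }
      } else {
        th[j] = th_old;
      }
    }
    if (step < burnin && (step + 1) % adapt_every == 0) {
      for (int j = 0; j < 8; ++j) {
        if (!mask[j] || tot_win[j] == 0) continue;
        const double rate = (double)acc_win[j] / (double)tot_win[j];
        sc[j] *= std::exp(rate - 0.44);
        if (sc[j] < 1e-8) sc[j] = 1e-8;
        if (sc[j] > 1e6) sc[j] = 1e6;
        acc_win[j] = 0;
        tot_win[j] = 0;
      }
    }
    if (step >= burnin && (step - burnin) % thin == 0 && isamp < nsamp) {
      for (int j = 0; j < 8; ++j) samples(isamp, j) = th[j];
      lnl[isamp] = cur_ll;
      ++isamp;
    }
  }

  NumericVector best(8), acc_rate(8), sc_out(8);
  for (int j = 0; j < 8; ++j) {
    best[j] = best_th[j];
    acc_rate[j] = tot[j] > 0 ? (double)acc[j] / (double)tot[j] : NA_REAL;
    sc_out[j] = sc[j];
  }
  return List::create(_["samples"] = samples, _["lnl"] = lnl,
                      _["best"] = best, _["best_lnl"] = best_ll,
                      _["accept"] = acc_rate, _["scales"] = sc_out);
}
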