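// Hamiltonian Monte Carlo for the density-dependent selection model
//
//   2W_i ~ Poisson(lambda_i)
//   log lambda_i = beta1p + beta2 x_i + beta3 x_i^2 - N_i exp(alpha1 + alpha2 x_i)
//                  + sigma_e z_{year(i)}                       (non-centred year effect)
//
// Parameter vector (density model, J year effects):
//   theta = (beta1p, beta2, beta3, alpha1, alpha2, log_sigma, z_1..z_J)
// Period model (no density term):
//   theta = (b1p, b2, b3, log_sigma, z_1..z_J)
//
// Priors: flat on the betas; normal(-1, sd 2) on alpha1, alpha2; flat on
// sigma_e over (0, sigma_max] via the log transform (+log_sigma Jacobian).
// All randomness goes through R's RNG so set.seed() governs the draws.

#include <Rcpp.h>
using namespace Rcpp;

struct SelModel {
  const IntegerVector& w;   // 2W counts
  const NumericVector& x;   // normalised trait
  const NumericVector& N;   // population size per record
  const IntegerVector& yr;  // 0-based year index
  int J;
  bool density;             // include -N exp(a1 + a2 x) term
  double sigma_max;
  double ap_mean, ap_prec;  // normal prior on the alphas (precision = 1/sd^2)
  int npar;

  SelModel(const IntegerVector& w_, const NumericVector& x_,
           const NumericVector& N_, const IntegerVector& yr_,
           int J_, bool density_, double sigma_max_,
           double ap_mean_, double ap_sd_)
    : w(w_), x(x_), N(N_), yr(yr_), J(J_), density(density_),
      sigma_max(sigma_max_), ap_mean(ap_mean_),
      ap_prec(1.0 / (ap_sd_ * ap_sd_)) {
    npar = (density ? 6 : 4) + J;
  }

  // log posterior and gradient; returns -inf for out-of-support sigma
  double logpost_grad(const std::vector<double>& th, std::vector<double>& g) const {
    const int nfix = density ? 6 : 4;
    const double b1 = th[0], b2 = th[1], b3 = th[2];
    const double a1 = density ? th[3] : 0.0;
    const double a2 = density ? th[4] : 0.0;
    const double ls = th[nfix - 1];
    if (ls > std::log(sigma_max)) return R_NegInf;
    const double sig = std::exp(ls);

    std::fill(g.begin(), g.end(), 0.0);
    double lp = 0.0;
    const int n = w.size();
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      const double zj = th[nfix + yr[i]];
      double eta = b1 + b2 * xi + b3 * xi * xi + sig * zj;
      double G = 0.0;
      if (density) {
        G = std::exp(a1 + a2 * xi);
        eta -= N[i] * G;
      }
      if (eta > 30.0) return R_NegInf;  // guard against overflow off-support
      const double lam = std::exp(eta);
      const double r = w[i] - lam;      // d lp / d eta
      lp += w[i] * eta - lam;
      g[0] += r;
      g[1] += r * xi;
      g[2] += r * xi * xi;
      if (density) {
        g[3] += r * (-N[i] * G);
        g[4] += r * (-N[i] * xi * G);
      }
      g[nfix - 1] += r * sig * zj;      // d eta / d log_sigma = sigma z
      g[nfix + yr[i]] += r * sig;
    }
    // standard-normal year effects
    for (int j = 0; j < J; ++j) {
      const double zj = th[nfix + j];
      lp += -0.5 * zj * zj;
      g[nfix + j] += -zj;
    }
    // weakly informative normal prior on the alphas
    if (density) {
      lp += -0.5 * ap_prec * ((a1 - ap_mean) * (a1 - ap_mean) +
                              (a2 - ap_mean) * (a2 - ap_mean));
      g[3] += -ap_prec * (a1 - ap_mean);
      g[4] += -ap_prec * (a2 - ap_mean);
    }
    // flat prior on sigma > 0, sampled on the log scale: Jacobian
    lp += ls;
    g[nfix - 1] += 1.0;
    return lp;
  }
};

// One chain of HMC with dual-averaging step-size adaptation and diagonal
// mass-matrix estimation during warmup. Retains (iter - warmup)/thin draws.
// [[Rcpp::export(name = ".hmc_chain")]]
List hmc_chain(IntegerVector w, NumericVector x, NumericVector N,
               IntegerVector yr, int J, bool density,
               NumericVector init, int iter, int warmup, int thin,
               int L_max, double sigma_max, double target_accept,
               double alpha_prior_mean, double alpha_prior_sd) {
  SelModel m(w, x, N, yr, J, density, sigma_max, alpha_prior_mean, alpha_prior_sd);
  const int P = m.npar;
  if (init.size() != P) stop("init has wrong length");

  std::vector<double> th(init.begin(), init.end());
  std::vector<double> g(P), g_prop(P), th_prop(P), p(P);
  std::vector<double> inv_mass(P, 1.0);      // proposal variances
  double lp = m.logpost_grad(th, g);
  if (!R_finite(lp)) stop("initial values have zero posterior density");

  // dual averaging (Hoffman & Gelman 2014 defaults)
  double log_eps = std::log(0.1), log_eps_bar = 0.0, Hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  double mu = std::log(10.0 * std::exp(log_eps));
  int adapt_count = 0;

  // Welford accumulators for mass adaptation over the middle warmup window
  std::vector<double> mean_acc(P, 0.0), m2_acc(P, 0.0);
  long n_acc = 0;
  const int win_lo = warmup / 4, win_hi = (3 * warmup) / 4;

  const int n_keep = (iter - warmup + thin - 1) / thin;
  NumericMatrix draws(n_keep > 0 ? n_keep : 0, P);
  int keep = 0, divergences = 0;
  double accept_sum = 0.0;
  long accept_n = 0;

  RNGScope scope;
  for (int it = 0; it < iter; ++it) {
    // momentum p ~ N(0, M) with M = 1/inv_mass (diagonal)
    double H0 = -lp;
    for (int k = 0; k < P; ++k) {
      p[k] = R::norm_rand() / std::sqrt(inv_mass[k]);
      H0 += 0.5 * p[k] * p[k] * inv_mass[k];
    }
    const double eps = std::exp(it < warmup ? log_eps : log_eps_bar);
    const int L = 1 + (int)std::floor(R::unif_rand() * L_max);

    th_prop = th;
    std::copy(g.begin(), g.end(), g_prop.begin());
    double lp_prop = lp;
    bool bad = false;
    // leapfrog
    for (int s = 0; s < L; ++s) {
      for (int k = 0; k < P; ++k) p[k] += 0.5 * eps * g_prop[k];
      for (int k = 0; k < P; ++k) th_prop[k] += eps * inv_mass[k] * p[k];
      lp_prop = m.logpost_grad(th_prop, g_prop);
      if (!R_finite(lp_prop)) { bad = true; break; }
      for (int k = 0; k < P; ++k) p[k] += 0.5 * eps * g_prop[k];
    }
    double alpha;
    if (bad) {
      alpha = 0.0;
      if (it >= warmup) ++divergences;
    } else {
      double H1 = -lp_prop;
      for (int k = 0; k < P; ++k) H1 += 0.5 * p[k] * p[k] * inv_mass[k];
      const double dH = H0 - H1;
      if (dH < -1000.0 && it >= warmup) ++divergences;
      alpha = dH > 0 ? 1.0 : std::exp(dH);
      if (R::unif_rand() < alpha) {
        th.swap(th_prop);
        g.swap(g_prop);
        lp = lp_prop;
      }
    }
    if (it >= warmup) { accept_sum += alpha; ++accept_n; }

    if (it < warmup) {
      // dual averaging
      ++adapt_count;
      const double eta_t = 1.0 / (adapt_count + t0);
      Hbar = (1.0 - eta_t) * Hbar + eta_t * (target_accept - alpha);
      log_eps = mu - std::sqrt((double)adapt_count) / gamma * Hbar;
      const double wgt = std::pow((double)adapt_count, -kappa);
      log_eps_bar = wgt * log_eps + (1.0 - wgt) * log_eps_bar;
      // mass window
      if (it >= win_lo && it < win_hi) {
        ++n_acc;
        for (int k = 0; k < P; ++k) {
          const double d = th[k] - mean_acc[k];
          mean_acc[k] += d / n_acc;
          m2_acc[k] += d * (th[k] - mean_acc[k]);
        }
      }
      if (it == win_hi - 1 && n_acc > 10) {
        for (int k = 0; k < P; ++k) {
          double v = m2_acc[k] / (n_acc - 1);
          inv_mass[k] = std::max(v, 1e-8);
        }
        // restart step-size adaptation for the new metric
        adapt_count = 0; Hbar = 0.0;
        mu = std::log(10.0 * std::exp(log_eps));
      }
    } else if ((it - warmup) % thin == 0 && keep < n_keep) {
      for (int k = 0; k < P; ++k) draws(keep, k) = th[k];
      ++keep;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["draws"] = draws,
    _["divergences"] = divergences,
    _["accept_rate"] = accept_n > 0 ? accept_sum / accept_n : NA_REAL,
    _["step_size"] = std::exp(log_eps_bar));
}

// Direct evaluation of the log posterior (used by tests to validate gradients
// and by the R side for initial-value screening).
// [[Rcpp::export(name = ".sel_logpost")]]
List sel_logpost(IntegerVector w, NumericVector x, NumericVector N,
                 IntegerVector yr, int J, bool density,
                 NumericVector theta, double sigma_max,
                 double alpha_prior_mean, double alpha_prior_sd) {
  SelModel m(w, x, N, yr, J, density, sigma_max, alpha_prior_mean, alpha_prior_sd);
  if (theta.size() != m.npar) stop("theta has wrong length");
  std::vector<double> th(theta.begin(), theta.end()), g(m.npar);
  double lp = m.logpost_grad(th, g);
  return List::create(_["logpost"] = lp, _["gradient"] = NumericVector(g.begin(), g.end()));
}
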