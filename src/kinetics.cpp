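// Closed-form dual-input two-compartment kinetics and the per-subject FOCE
// inner step. Units here: volumes L, clearances L/h, times h, dose pg,
// concentrations pg/mL (amounts pg / (V1 in mL)).

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
using namespace Rcpp;

// (exp(-b t) - exp(-a t)) / (a - b), with the a -> b limit t exp(-a t)
static inline double phi_conv(double a, double b, double t) {
  double d = a - b;
  double m = std::max(std::abs(a), std::abs(b));
  if (std::abs(d) <= 1e-8 * m) return t * std::exp(-0.5 * (a + b) * t);
  return (std::exp(-b * t) - std::exp(-a * t)) / d;
}

// [ (1-exp(-b t))/b - (1-exp(-a t))/a ] / (a - b); integral of phi_conv in t.
// Limit a -> b: ((1-exp(-b t)) - b t exp(-b t)) / b^2
static inline double psi_conv(double a, double b, double t) {
  double d = a - b;
  double m = std::max(std::abs(a), std::abs(b));
  if (std::abs(d) <= 1e-8 * m) {
    double c = 0.5 * (a + b);
    return ((1.0 - std::exp(-c * t)) - c * t * std::exp(-c * t)) / (c * c);
  }
  return ((1.0 - std::exp(-b * t)) / b - (1.0 - std::exp(-a * t)) / a) / d;
}

// params: CL, V1, Q, V2, Ka1, Ka2, Bio, Tlag, D1 (interface units)
static void conc_profile_impl(const double* p, double dose,
                              const double* times, int n, double* out) {
  const double CL = p[0], V1 = p[1], Q = p[2], V2 = p[3];
  const double Ka1 = p[4], Ka2 = p[5], Bio = p[6], Tlag = p[7], D1 = p[8];
  const double k10 = CL / V1, k12 = Q / V1, k21 = Q / V2;
  const double s = k10 + k12 + k21, prod = k10 * k21;
  double disc = s * s - 4.0 * prod;
  disc = disc > 0.0 ? std::sqrt(disc) : 0.0;
  // repeated disposition roots are a measure-zero configuration; nudge apart
  if (disc < 1e-10 * s) disc = 1e-10 * s;
  const double l1 = 0.5 * (s + disc), l2 = 0.5 * (s - disc);
  const double A1 = (l1 - k21) / (l1 - l2), A2 = (k21 - l2) / (l1 - l2);
  const double R0 = Bio * dose / D1;          // zero-order rate into depot 1
  const double F2 = (1.0 - Bio) * dose;       // lagged bolus into depot 2
  const double V1mL = V1 * 1000.0;

  for (int i = 0; i < n; ++i) {
    double t = times[i];
    if (t <= 0.0) { out[i] = 0.0; continue; }
    // depot 1: zero-order infusion over [0, D1), then first-order Ka1
    double h1 = psi_conv(Ka1, l1, t), h2 = psi_conv(Ka1, l2, t);
    if (t > D1) {
      h1 -= psi_conv(Ka1, l1, t - D1);
      h2 -= psi_conv(Ka1, l2, t - D1);
    }
    double amt = R0 * Ka1 * (A1 * h1 + A2 * h2);
    // depot 2: bolus released first-order after Tlag
    if (t > Tlag) {
      double u = t - Tlag;
      amt += F2 * Ka2 * (A1 * phi_conv(Ka2, l1, u) + A2 * phi_conv(Ka2, l2, u));
    }
    out[i] = amt / V1mL;
  }
}

//' @noRd
// [[Rcpp::export(name = ".conc_profile_cpp")]]
NumericVector conc_profile_cpp(NumericVector params, double dose,
                               NumericVector times) {
  int n = times.size();
  NumericVector out(n);
  conc_profile_impl(REAL(params), dose, REAL(times), n, REAL(out));
  return out;
}

// ---------------------------------------------------------------------------
// FOCE inner step for the structural model above.
//
// p_typ   : 9 typical parameters with covariate effects already applied
// eta_idx : length-9 map, 0-based index into eta per parameter, -1 = no IIV
// bio_logit: apply the Bio eta on the logit scale (realized in (0,1))
// y       : log observed concentrations; times: matching times
// omega   : IIV variances (length = n_eta); sigma: residual SD (log scale)
// Returns eta_hat, the -2 log-likelihood contribution under the FOCE
// linearization (full 2*pi constants included), the Jacobian at eta_hat,
// and the log-scale predictions.

static const double PENALTY = 1e10;

static inline double logit(double x) { return std::log(x / (1.0 - x)); }
static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static bool ind_pred_log(const arma::vec& p_typ, const arma::ivec& eta_idx,
                         bool bio_logit, const arma::vec& eta, double dose,
                         const arma::vec& times, arma::vec& f) {
  double p[9];
  for (int j = 0; j < 9; ++j) {
    double v = p_typ[j];
    int k = eta_idx[j];
    if (k >= 0) {
      if (j == 6 && bio_logit) v = invlogit(logit(v) + eta[k]);
      else v *= std::exp(eta[k]);
    }
    p[j] = v;
  }
  int n = times.n_elem;
  std::vector<double> c(n);
  conc_profile_impl(p, dose, times.memptr(), n, c.data());
  for (int i = 0; i < n; ++i) {
    if (!(c[i] > 0.0) || !std::isfinite(c[i])) return false;
    f[i] = std::log(c[i]);
  }
  return true;
}

// penalized objective q(eta) = ||y-f||^2/sigma^2 + eta' Oinv eta
static double q_obj(const arma::vec& y, const arma::vec& f,
                    const arma::vec& eta, const arma::vec& oinv,
                    double sig2) {
  arma::vec r = y - f;
  return arma::dot(r, r) / sig2 + arma::dot(eta % oinv, eta);
}

//' @noRd
// [[Rcpp::export(name = ".foce_inner_cpp")]]
List foce_inner_cpp(NumericVector p_typ_, IntegerVector eta_idx_,
                    bool bio_logit, NumericVector y_, NumericVector times_,
                    double dose, NumericVector omega_, double sigma,
                    NumericVector eta_start_) {
  arma::vec p_typ(p_typ_.begin(), p_typ_.size());
  arma::ivec eta_idx(eta_idx_.size());
  for (int j = 0; j < eta_idx_.size(); ++j) eta_idx[j] = eta_idx_[j];
  arma::vec y(y_.begin(), y_.size());
  arma::vec times(times_.begin(), times_.size());
  arma::vec omega(omega_.begin(), omega_.size());
  const int n = y.n_elem, ne = omega.n_elem;
  const double sig2 = sigma * sigma;
  const double LOG2PI = std::log(2.0 * M_PI);

  arma::vec f(n);
  if (ne == 0) {
    // no random effects: plain log-normal residual likelihood at eta = 0
    arma::vec eta0;
    if (!ind_pred_log(p_typ, eta_idx, bio_logit, eta0, dose, times, f))
      return List::create(_["ofv"] = PENALTY, _["ok"] = false);
    arma::vec r = y - f;
    double ofv = n * (LOG2PI + std::log(sig2)) + arma::dot(r, r) / sig2;
    return List::create(_["eta"] = NumericVector(0), _["ofv"] = ofv,
                        _["f"] = Rcpp::wrap(f), _["ok"] = true,
                        _["iters"] = 0, _["grad_norm"] = 0.0);
  }

  if (n == 0) {
    // a fully censored subject contributes nothing; its mode is 0
    NumericVector eta0(ne);
    return List::create(_["eta"] = eta0, _["ofv"] = 0.0,
                        _["f"] = NumericVector(0), _["ok"] = true,
                        _["iters"] = 0, _["grad_norm"] = 0.0);
  }
  arma::vec oinv = 1.0 / omega;
  arma::vec eta(eta_start_.begin(), eta_start_.size());
  if (!ind_pred_log(p_typ, eta_idx, bio_logit, eta, dose, times, f)) {
    eta.zeros();
    if (!ind_pred_log(p_typ, eta_idx, bio_logit, eta, dose, times, f))
      return List::create(_["ofv"] = PENALTY, _["ok"] = false);
  }
  bool warm = arma::norm(eta, "inf") > 0.0;

  const double h = 1e-5;
  arma::mat J(n, ne);
  double gnorm = NA_REAL;
  int iters_used = 0;

  // damped Gauss-Newton mode search from one starting point
  auto run_gn = [&](arma::vec e, arma::vec fe, double& q_out,
                    double& gnorm_out, int& iters) -> arma::vec {
    arma::vec fp(n), eta_try(ne), f_try(n);
    double q = q_obj(y, fe, e, oinv, sig2);
    gnorm_out = NA_REAL;
    bool ok = true;
    int iter;
    for (iter = 0; iter < 50; ++iter) {
      for (int k = 0; k < ne; ++k) {
        arma::vec e2 = e; e2[k] += h;
        if (!ind_pred_log(p_typ, eta_idx, bio_logit, e2, dose, times, fp)) {
          e2[k] = e[k] - h;
          if (!ind_pred_log(p_typ, eta_idx, bio_logit, e2, dose, times, fp)) {
            ok = false; break;
          }
          J.col(k) = (fe - fp) / h;
        } else {
          J.col(k) = (fp - fe) / h;
        }
      }
      if (!ok) break;
      arma::vec r = y - fe;
      arma::vec g = -J.t() * r / sig2 + oinv % e;   // gradient of q/2
      gnorm_out = arma::norm(2.0 * g, "inf");
      if (gnorm_out < 1e-6) break;
      arma::mat H = J.t() * J / sig2 + arma::diagmat(oinv);
      // tiny scaled ridge keeps the system solvable when J is
      // rank-deficient (fewer informative points than etas)
      H.diag() += 1e-10 * H.diag().max();
      arma::vec d;
      bool solved = arma::solve(d, H, -g, arma::solve_opts::likely_sympd +
                                          arma::solve_opts::no_approx);
      if (!solved) d = -g / H.diag();  // diagonal fallback
      double alpha = 1.0;
      bool improved = false, done = false;
      for (int ls = 0; ls < 25; ++ls) {
        eta_try = e + alpha * d;
        if (ind_pred_log(p_typ, eta_idx, bio_logit, eta_try, dose, times,
                         f_try)) {
          double q_try = q_obj(y, f_try, eta_try, oinv, sig2);
          if (q_try <= q + 1e-12) {
            done = std::abs(q - q_try) < 1e-10 * (std::abs(q) + 1.0) &&
                   ls == 0;
            e = eta_try; fe = f_try; q = q_try; improved = true;
            break;
          }
        }
        alpha *= 0.5;
      }
      if (!improved || done) break;
    }
    iters = iter;
    q_out = ok ? q : std::numeric_limits<double>::infinity();
    return e;
  };

  double q1, g1; int it1 = 0;
  arma::vec eta1 = run_gn(eta, f, q1, g1, it1);
  double q_best = q1; gnorm = g1; eta = eta1; iters_used = it1;
  if (warm) {
    // the conditional density can be multimodal for sparse subjects;
    // also search from eta = 0 and keep the better mode so the objective
    // stays reproducible regardless of warm-start history
    arma::vec zero(ne, arma::fill::zeros), f0(n);
    if (ind_pred_log(p_typ, eta_idx, bio_logit, zero, dose, times, f0)) {
      double q0, g0; int it0 = 0;
      arma::vec eta0 = run_gn(zero, f0, q0, g0, it0);
      if (q0 < q_best - 1e-10) {
        q_best = q0; gnorm = g0; eta = eta0; iters_used += it0;
      }
    }
  }
  if (!std::isfinite(q_best) ||
      !ind_pred_log(p_typ, eta_idx, bio_logit, eta, dose, times, f))
    return List::create(_["ofv"] = PENALTY, _["ok"] = false);
  int iter = iters_used;

  // final Jacobian at eta_hat for the FOCE linearization
  arma::vec fp(n);
  for (int k = 0; k < ne; ++k) {
    arma::vec e2 = eta; e2[k] += h;
    if (!ind_pred_log(p_typ, eta_idx, bio_logit, e2, dose, times, fp))
      return List::create(_["ofv"] = PENALTY, _["ok"] = false);
    J.col(k) = (fp - f) / h;
  }
  // Sigma = J Omega J' + sig2 I ; r = y - f(eta_hat) + J eta_hat
  arma::mat Sig = J * arma::diagmat(omega) * J.t();
  Sig.diag() += sig2;
  arma::vec r = y - f + J * eta;
  arma::mat L;
  if (!arma::chol(L, Sig, "lower"))
    return List::create(_["ofv"] = PENALTY, _["ok"] = false);
  arma::vec z = arma::solve(arma::trimatl(L), r);
  double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  double ofv = n * LOG2PI + logdet + arma::dot(z, z);
  return List::create(_["eta"] = Rcpp::wrap(eta), _["ofv"] = ofv,
                      _["f"] = Rcpp::wrap(f), _["J"] = Rcpp::wrap(J),
                      _["ok"] = true, _["iters"] = iter,
                      _["grad_norm"] = gnorm);
}
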