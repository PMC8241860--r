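#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Adaptive Hamiltonian Monte Carlo, one chain.
//
// Warmup in three phases (fractions of n_warmup):
//   1. step-size adaptation under an identity metric,
//   2. step-size adaptation while collecting draws for the metric,
//   3. step-size re-adaptation under the dense metric estimated from phase 2.
// Step size uses Nesterov dual averaging towards `target_accept`; trajectory
// length is jittered uniformly over the upper half of {1, ..., max_L}.
// A transition with energy error > 1000 (or a non-finite Hamiltonian) is a
// divergence: it is rejected and counted.
//
// All randomness comes from R's RNG, so set.seed() on the R side makes chains
// reproducible.  model > 0 evaluates the built-in posteriors in models.cpp;
// model = 0 calls back into an R function returning list(lp=, grad=).

List lp_grad_cpp(int model, arma::vec theta_u, arma::vec y, arma::vec T,
                 arma::vec prior);

struct Target {
  int model;
  arma::vec y, T, prior;
  Function *rfun;
  long n_evals = 0;

  double eval(const arma::vec &u, arma::vec &grad) {
    ++n_evals;
    if (model > 0) {
      List res = lp_grad_cpp(model, u, y, T, prior);
      grad = as<arma::vec>(res["grad"]);
      return as<double>(res["lp"]);
    }
    List res = (*rfun)(NumericVector(u.begin(), u.end()));
    grad = as<arma::vec>(res["grad"]);
    return as<double>(res["lp"]);
  }
};

struct DualAvg {
  double mu, log_eps, log_eps_bar, h_bar;
  int m;
  double gamma = 0.05, t0 = 10.0, kappa = 0.75;

  void init(double eps0) {
    mu = std::log(10.0 * eps0);
    log_eps = std::log(eps0);
    log_eps_bar = 0.0;
    h_bar = 0.0;
    m = 0;
  }
  void update(double target, double astat) {
    ++m;
    h_bar = (1.0 - 1.0 / (m + t0)) * h_bar + (target - astat) / (m + t0);
    log_eps = mu - std::sqrt((double)m) / gamma * h_bar;
    double w = std::pow((double)m, -kappa);
    log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
  }
  double eps() const { return std::exp(log_eps); }
  double eps_final() const { return std::exp(log_eps_bar); }
};

// momentum ~ N(0, Metric^{-1}) where Metric^{-1} = Sigma = Lc Lc^T (lower chol),
// kinetic energy = 0.5 * p' Sigma p, position update uses Sigma * p.
static arma::vec draw_momentum(const arma::mat &Lc) {
  int P = Lc.n_rows;
  arma::vec z(P);
  for (int i = 0; i < P; ++i) z[i] = norm_rand();
  return arma::solve(arma::trimatu(Lc.t()), z);
}

static double kinetic(const arma::vec &p, const arma::mat &Sigma) {
  return 0.5 * arma::dot(p, Sigma * p);
}

// jittered trajectory length on the upper half of {1, ..., max_L}: short
// trajectories waste gradient evaluations without decorrelating the chain
static int draw_L(int max_L) {
  int lo = std::max(1, max_L / 2);
  return lo + (int)(unif_rand() * (max_L - lo + 1));
}

// one trajectory; returns acceptance statistic, sets q/lp/grad on accept
static double transition(Target &tgt, arma::vec &q, double &lp, arma::vec &grad,
                         double eps, int L, const arma::mat &Sigma,
                         const arma::mat &Lc, bool &divergent) {
  arma::vec p = draw_momentum(Lc);
  const double H0 = -lp + kinetic(p, Sigma);
  arma::vec q1 = q, g1 = grad, p1 = p;
  double lp1 = lp;
  divergent = false;

  for (int s = 0; s < L; ++s) {
    p1 += 0.5 * eps * g1;
    q1 += eps * (Sigma * p1);
    lp1 = tgt.eval(q1, g1);
    if (!std::isfinite(lp1) || !g1.is_finite()) { divergent = true; break; }
    p1 += 0.5 * eps * g1;
  }
  double H1 = divergent ? std::numeric_limits<double>::infinity()
                        : -lp1 + kinetic(p1, Sigma);
  double dH = H1 - H0;
  if (!std::isfinite(dH) || dH > 1000.0) divergent = true;
  double astat = divergent ? 0.0 : std::min(1.0, std::exp(-dH));
  if (!divergent && unif_rand() < astat) {
    q = q1; lp = lp1; grad = g1;
  }
  return astat;
}

// Stan-style initial step-size heuristic: double/halve until the one-step
// acceptance probability crosses 0.5
static double init_stepsize(Target &tgt, const arma::vec &q0, double lp0,
                            const arma::vec &g0, const arma::mat &Sigma,
                            const arma::mat &Lc) {
  double eps = 0.1;
  arma::vec p = draw_momentum(Lc);
  const double H0 = -lp0 + kinetic(p, Sigma);

  auto one_step_dH = [&](double e) {
    arma::vec p1 = p + 0.5 * e * g0;
    arma::vec q1 = q0 + e * (Sigma * p1);
    arma::vec g1;
    double lp1 = tgt.eval(q1, g1);
    if (!std::isfinite(lp1) || !g1.is_finite())
      return std::numeric_limits<double>::infinity();
    p1 += 0.5 * e * g1;
    return (-lp1 + kinetic(p1, Sigma)) - H0;
  };

  double dH = one_step_dH(eps);
  while (!std::isfinite(dH) && eps > 1e-10) { eps *= 0.1; dH = one_step_dH(eps); }
  if (!std::isfinite(dH)) return 1e-6;
  int dir = (std::exp(-dH) > 0.5) ? 1 : -1;
  for (int it = 0; it < 50; ++it) {
    dH = one_step_dH(eps);
    double acc = std::isfinite(dH) ? std::exp(-dH) : 0.0;
    if (dir == 1 && acc <= 0.5) break;
    if (dir == -1 && acc >= 0.5) break;
    eps *= (dir == 1) ? 2.0 : 0.5;
    if (eps < 1e-10 || eps > 1e6) break;
  }
  return eps;
}

// [[Rcpp::export]]
List hmc_chain_cpp(int model, arma::vec y, arma::vec T, arma::vec prior,
                   arma::vec init_u, int n_warmup, int n_iter,
                   double target_accept, int max_L,
                   Nullable<Function> r_lpgrad) {
  Function rf = r_lpgrad.isNotNull() ? Function(r_lpgrad.get()) : Function("identity");
  Target tgt{model, y, T, prior, &rf};
  const int P = init_u.n_elem;

  arma::vec q = init_u, grad;
  double lp = tgt.eval(q, grad);
  if (!std::isfinite(lp)) stop("non-finite log posterior at initial value");

  arma::mat Sigma = arma::eye(P, P), Lc = arma::eye(P, P);
  DualAvg da;
  da.init(init_stepsize(tgt, q, lp, grad, Sigma, Lc));

  const int w1 = std::max(15, (int)std::floor(0.15 * n_warmup));
  const int w3 = std::max(15, (int)std::floor(0.10 * n_warmup));
  const int wa = std::max(10, (int)std::floor(0.25 * n_warmup));
  const int wb = std::max(10, n_warmup - w1 - w3 - wa);

  auto set_metric = [&](const arma::mat &win_draws) {
    // dense metric from window draws, regularized towards its diagonal
    arma::mat S = arma::cov(win_draws);
    arma::vec d = S.diag();
    double mscale = arma::mean(d);
    if (!S.is_finite() || mscale <= 0) return;
    // floor near-constant directions so the metric stays well conditioned
    S = 0.85 * S + 0.15 * arma::diagmat(arma::clamp(d, 1e-5 * mscale, arma::datum::inf));
    S.diag() += 1e-6 * mscale;
    arma::mat L;
    if (arma::chol(L, S, "lower")) { Sigma = S; Lc = L; }
  };

  bool div = false;
  auto warm_iters = [&](int n_it, arma::mat *store) {
    for (int i = 0; i < n_it; ++i) {
      double astat = transition(tgt, q, lp, grad, da.eps(),
                                draw_L(max_L), Sigma, Lc, div);
      da.update(target_accept, astat);
      if (store) store->row(i) = q.t();
    }
  };

  // phase 1: step size only under identity metric
  warm_iters(w1, nullptr);
  // phase 2a: first metric window
  arma::mat win_a(wa, P);
  warm_iters(wa, &win_a);
  set_metric(win_a);
  da.init(init_stepsize(tgt, q, lp, grad, Sigma, Lc));
  // phase 2b: second, longer window under the improved metric
  arma::mat win_b(wb, P);
  warm_iters(wb, &win_b);
  set_metric(win_b);
  // phase 3: final step-size adaptation under the final metric
  da.init(init_stepsize(tgt, q, lp, grad, Sigma, Lc));
  warm_iters(w3, nullptr);

  const double eps = da.eps_final();
  arma::mat draws(n_iter, P);
  arma::vec lps(n_iter);
  int n_div = 0;
  double astat_sum = 0.0;
  for (int i = 0; i < n_iter; ++i) {
    astat_sum += transition(tgt, q, lp, grad, eps,
                            draw_L(max_L), Sigma, Lc, div);
    if (div) ++n_div;
    draws.row(i) = q.t();
    lps[i] = lp;
  }

  return List::create(
      _["draws"] = draws, _["lp"] = lps, _["stepsize"] = eps,
      _["divergences"] = n_div, _["accept_stat"] = astat_sum / n_iter,
      _["metric"] = Sigma, _["n_evals"] = (double)tgt.n_evals);
}
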