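#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Prior hyperparameter vector layout, kept in step with prior_defaults() on
// the R side:
//   [0] a shape    [1] a rate     (gamma, rate parameterization)
//   [2] b shape    [3] b rate     (gamma)
//   [4] p alpha    [5] p beta     (beta)
//   [6] sigma scale               (folded normal, location 0)
//   [7] v df       [8] v scale    (folded student-t, location 0)
//   [9] l meanlog  [10] l sdlog   (log-normal)
//
// Parameters are handled on the unconstrained scale:
//   log(a), log(b), logit(p), log(sigma) [, log(v), log(l)]
// with the log-Jacobian of the transform included, so the density being
// sampled (and later fed to the evidence estimator) is the posterior on the
// unconstrained scale.

static const double LOG_2PI = 1.8378770664093454836;

// stable logistic
static inline double logistic(double z) {
  if (z >= 0.0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

// G = 1 / (1 + exp(m)) computed stably; sigmoid mean uses m = b - a/T
static inline double inv1pexp(double m) {
  if (m <= 0.0) return 1.0 / (1.0 + std::exp(m));
  double e = std::exp(-m);
  return e / (1.0 + e);
}

// log prior densities (normalized) and d/dx on the constrained scale -------

static inline double lp_gamma(double x, double shape, double rate, double &dx) {
  dx = (shape - 1.0) / x - rate;
  return shape * std::log(rate) - std::lgamma(shape) +
         (shape - 1.0) * std::log(x) - rate * x;
}

static inline double lp_beta(double x, double a, double b, double &dx) {
  dx = (a - 1.0) / x - (b - 1.0) / (1.0 - x);
  return -(std::lgamma(a) + std::lgamma(b) - std::lgamma(a + b)) +
         (a - 1.0) * std::log(x) + (b - 1.0) * std::log(1.0 - x);
}

static inline double lp_foldnorm0(double x, double scale, double &dx) {
  dx = -x / (scale * scale);
  return std::log(2.0) - 0.5 * LOG_2PI - std::log(scale) -
         0.5 * x * x / (scale * scale);
}

static inline double lp_foldt0(double x, double df, double scale, double &dx) {
  double s2 = scale * scale;
  dx = -(df + 1.0) * x / (df * s2 + x * x);
  return std::log(2.0) + std::lgamma(0.5 * (df + 1.0)) - std::lgamma(0.5 * df) -
         0.5 * std::log(df * M_PI) - std::log(scale) -
         0.5 * (df + 1.0) * std::log1p(x * x / (df * s2));
}

static inline double lp_lognorm(double x, double mu, double sd, double &dx) {
  double z = (std::log(x) - mu) / sd;
  dx = -1.0 / x - z / (sd * x);
  return -std::log(x) - std::log(sd) - 0.5 * LOG_2PI - 0.5 * z * z;
}

// sigmoid block --------------------------------------------------------------
//
// y | a,b,p,sigma ~ iid N(S_{a,b,p}(T), sigma^2) with
// S(T) = (1-p)/(1+exp(b - a/T)) + p.  One block serves both hypotheses: the
// shared-curve model stacks both conditions, the condition-specific model is
// fit per condition (the joint posterior factorizes across conditions).

static double lp_grad_sigmoid(const arma::vec &u, const arma::vec &y,
                              const arma::vec &T, const arma::vec &pr,
                              arma::vec &grad) {
  const double a = std::exp(u[0]), b = std::exp(u[1]);
  const double p = logistic(u[2]), sg = std::exp(u[3]);
  const int n = y.n_elem;
  const double s2 = sg * sg;

  double lp = -0.5 * n * (LOG_2PI + 2.0 * std::log(sg));
  double ga = 0.0, gb = 0.0, gp = 0.0, gs = 0.0, ssq = 0.0;
  for (int j = 0; j < n; ++j) {
    const double G = inv1pexp(b - a / T[j]);
    const double S = (1.0 - p) * G + p;
    const double r = y[j] - S;
    ssq += r * r;
    const double GG = G * (1.0 - G);   // = exp(b-a/T) * G^2
    const double w = r / s2;
    ga += w * (1.0 - p) * GG / T[j];
    gb += -w * (1.0 - p) * GG;
    gp += w * (1.0 - G);
  }
  lp += -0.5 * ssq / s2;
  gs = -n / sg + ssq / (sg * s2);

  double da, db, dp, ds;
  lp += lp_gamma(a, pr[0], pr[1], da);
  lp += lp_gamma(b, pr[2], pr[3], db);
  lp += lp_beta(p, pr[4], pr[5], dp);
  lp += lp_foldnorm0(sg, pr[6], ds);
  ga += da; gb += db; gp += dp; gs += ds;

  // change of variables to the unconstrained scale
  lp += u[0] + u[1] + std::log(p) + std::log(1.0 - p) + u[3];
  grad.set_size(4);
  grad[0] = ga * a + 1.0;
  grad[1] = gb * b + 1.0;
  grad[2] = gp * p * (1.0 - p) + (1.0 - 2.0 * p);
  grad[3] = gs * sg + 1.0;
  return lp;
}

// semi-parametric block ------------------------------------------------------
//
// y ~ N(S_{a,b,p}(T), v^2 A + sigma^2 I) where A is the squared-exponential
// correlation matrix over the concatenated temperature vector (replicate
// copies at equal temperatures share full covariance), i.e. the GP deviation
// term marginalized out of the likelihood.

// smallest tiling period of T (r exact replicate copies of a D-point grid);
// returns n when T is not tiled
static int tile_period(const arma::vec &T) {
  const int n = T.n_elem;
  for (int d = 1; d <= n / 2; ++d) {
    if (n % d != 0) continue;
    bool ok = true;
    for (int i = d; i < n && ok; ++i) ok = (T[i] == T[i % d]);
    if (ok) return d;
  }
  return n;
}

// Exact reduced computation when T consists of r replicate copies of one
// D-point grid.  With K = sigma^2 I_n + v^2 (J_r  (x)  A_D)  (J_r the all-ones
// matrix: replicate copies share one GP realization), an orthogonal rotation
// of replicate space block-diagonalizes K into K_m = sigma^2 I_D + r v^2 A_D
// acting on the replicate-mean residual and sigma^2 I on the within-replicate
// deviations, reducing every factorization from n x n to D x D.
static double lp_grad_semipar_tiled(const arma::vec &u, const arma::vec &y,
                                    const arma::vec &T, const arma::vec &pr,
                                    int D, arma::vec &grad) {
  const double a = std::exp(u[0]), b = std::exp(u[1]);
  const double p = logistic(u[2]), sg = std::exp(u[3]);
  const double v = std::exp(u[4]), l = std::exp(u[5]);
  const int n = y.n_elem, r = n / D;

  arma::vec Tg = T.head(D);
  arma::vec S(D), dSa(D), dSb(D), dSp(D);
  for (int j = 0; j < D; ++j) {
    const double G = inv1pexp(b - a / Tg[j]);
    S[j] = (1.0 - p) * G + p;
    const double GG = G * (1.0 - G);
    dSa[j] = (1.0 - p) * GG / Tg[j];
    dSb[j] = -(1.0 - p) * GG;
    dSp[j] = 1.0 - G;
  }
  arma::vec rbar(D, arma::fill::zeros);
  double ssq = 0.0;
  for (int i = 0; i < n; ++i) {
    const double res = y[i] - S[i % D];
    rbar[i % D] += res;
    ssq += res * res;
  }
  rbar /= r;
  const double s_within = ssq - r * arma::dot(rbar, rbar);

  arma::mat D2(D, D);
  for (int i = 0; i < D; ++i)
    for (int j = 0; j < D; ++j) {
      const double d = Tg[i] - Tg[j];
      D2(i, j) = d * d;
    }
  arma::mat A = arma::exp(-D2 / (2.0 * l * l));
  arma::mat Km = (r * v * v) * A + (sg * sg) * arma::eye(D, D);

  grad.set_size(6);
  grad.fill(0.0);
  const double neg_inf = -std::numeric_limits<double>::infinity();
  if (!Km.is_finite()) return neg_inf;
  arma::mat R;
  double jit = 1e-10 * r * v * v;
  bool ok = arma::chol(R, Km);
  for (int t = 0; !ok && t < 3; ++t, jit *= 10.0)
    ok = arma::chol(R, Km + jit * arma::eye(D, D));
  if (!ok || !R.is_finite() || R.diag().min() <= 1e-150) return neg_inf;
  if (R.diag().min() <= 1e-7 * R.diag().max()) return neg_inf;

  arma::vec abar = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), rbar));
  const double logdet_m = 2.0 * arma::accu(arma::log(R.diag()));
  double lp = -0.5 * n * LOG_2PI - 0.5 * logdet_m -
              (n - D) * std::log(sg) -
              0.5 * (r * arma::dot(rbar, abar) + s_within / (sg * sg));

  arma::mat Rinv = arma::inv(arma::trimatu(R));
  arma::mat Kminv = Rinv * Rinv.t();
  arma::mat M = (double)r * (abar * abar.t()) - Kminv;

  double ga = r * arma::dot(abar, dSa);
  double gb = r * arma::dot(abar, dSb);
  double gp = r * arma::dot(abar, dSp);
  double gs = sg * arma::trace(M) - (n - D) / sg +
              s_within / (sg * sg * sg);
  double gv = (v > 0.0) ? r * v * arma::accu(M % A) : 0.0;
  double gl = 0.5 * (r * v * v) * arma::accu(M % (A % D2)) / (l * l * l);

  double da, db, dp, ds, dv, dl;
  lp += lp_gamma(a, pr[0], pr[1], da);
  lp += lp_gamma(b, pr[2], pr[3], db);
  lp += lp_beta(p, pr[4], pr[5], dp);
  lp += lp_foldnorm0(sg, pr[6], ds);
  lp += lp_foldt0(v, pr[7], pr[8], dv);
  lp += lp_lognorm(l, pr[9], pr[10], dl);
  ga += da; gb += db; gp += dp; gs += ds; gv += dv; gl += dl;

  lp += u[0] + u[1] + std::log(p) + std::log(1.0 - p) + u[3] + u[4] + u[5];
  grad[0] = ga * a + 1.0;
  grad[1] = gb * b + 1.0;
  grad[2] = gp * p * (1.0 - p) + (1.0 - 2.0 * p);
  grad[3] = gs * sg + 1.0;
  grad[4] = gv * v + 1.0;
  grad[5] = gl * l + 1.0;
  return lp;
}

static double lp_grad_semipar(const arma::vec &u, const arma::vec &y,
                              const arma::vec &T, const arma::vec &pr,
                              arma::vec &grad) {
  const int D_tile = tile_period(T);
  if (D_tile < (int)T.n_elem)
    return lp_grad_semipar_tiled(u, y, T, pr, D_tile, grad);
  const double a = std::exp(u[0]), b = std::exp(u[1]);
  const double p = logistic(u[2]), sg = std::exp(u[3]);
  const double v = std::exp(u[4]), l = std::exp(u[5]);
  const int n = y.n_elem;

  arma::vec S(n), dSa(n), dSb(n), dSp(n);
  for (int j = 0; j < n; ++j) {
    const double G = inv1pexp(b - a / T[j]);
    S[j] = (1.0 - p) * G + p;
    const double GG = G * (1.0 - G);
    dSa[j] = (1.0 - p) * GG / T[j];
    dSb[j] = -(1.0 - p) * GG;
    dSp[j] = 1.0 - G;
  }
  arma::vec r = y - S;

  arma::mat D2(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double d = T[i] - T[j];
      D2(i, j) = d * d;
    }
  arma::mat A = arma::exp(-D2 / (2.0 * l * l));
  arma::mat C = (v * v) * A;
  arma::mat K = C + (sg * sg) * arma::eye(n, n);

  grad.set_size(6);
  grad.fill(0.0);
  const double neg_inf = -std::numeric_limits<double>::infinity();
  if (!K.is_finite()) return neg_inf;

  // jitter escalation: 1e-10 * v^2 on the diagonal, x10 at most 3 times
  arma::mat R;
  double jit = 1e-10 * v * v;
  bool ok = arma::chol(R, K);
  for (int t = 0; !ok && t < 3; ++t, jit *= 10.0)
    ok = arma::chol(R, K + jit * arma::eye(n, n));
  if (!ok || !R.is_finite() || R.diag().min() <= 1e-150) return neg_inf;
  // reject states where the covariance is numerically singular (far tails of
  // v/sigma); the sampler treats the -inf as a divergence
  if (R.diag().min() <= 1e-7 * R.diag().max()) return neg_inf;

  arma::vec alpha = arma::solve(arma::trimatu(R),
                                arma::solve(arma::trimatl(R.t()), r));
  double logdet = 2.0 * arma::accu(arma::log(R.diag()));
  double lp = -0.5 * n * LOG_2PI - 0.5 * logdet - 0.5 * arma::dot(r, alpha);

  // K^{-1} from the (possibly jittered) Cholesky factor
  arma::mat Rinv = arma::inv(arma::trimatu(R));
  arma::mat Kinv = Rinv * Rinv.t();
  arma::mat M = alpha * alpha.t() - Kinv;

  double ga = arma::dot(alpha, dSa);
  double gb = arma::dot(alpha, dSb);
  double gp = arma::dot(alpha, dSp);
  double gs = sg * arma::trace(M);
  double gv = (v > 0.0) ? arma::accu(M % C) / v : 0.0;
  double gl = 0.5 * arma::accu(M % (C % D2)) / (l * l * l);

  double da, db, dp, ds, dv, dl;
  lp += lp_gamma(a, pr[0], pr[1], da);
  lp += lp_gamma(b, pr[2], pr[3], db);
  lp += lp_beta(p, pr[4], pr[5], dp);
  lp += lp_foldnorm0(sg, pr[6], ds);
  lp += lp_foldt0(v, pr[7], pr[8], dv);
  lp += lp_lognorm(l, pr[9], pr[10], dl);
  ga += da; gb += db; gp += dp; gs += ds; gv += dv; gl += dl;

  lp += u[0] + u[1] + std::log(p) + std::log(1.0 - p) + u[3] + u[4] + u[5];
  grad[0] = ga * a + 1.0;
  grad[1] = gb * b + 1.0;
  grad[2] = gp * p * (1.0 - p) + (1.0 - 2.0 * p);
  grad[3] = gs * sg + 1.0;
  grad[4] = gv * v + 1.0;
  grad[5] = gl * l + 1.0;
  return lp;
}

// exported -------------------------------------------------------------------

// model codes: 1 = sigmoid block, 2 = semi-parametric block

// [[Rcpp::export]]
List lp_grad_cpp(int model, arma::vec theta_u, arma::vec y, arma::vec T,
                 arma::vec prior) {
  arma::vec grad;
  double lp;
  if (model == 1)
    lp = lp_grad_sigmoid(theta_u, y, T, prior, grad);
  else if (model == 2)
    lp = lp_grad_semipar(theta_u, y, T, prior, grad);
  else
    stop("unknown model code");
  return List::create(_["lp"] = lp, _["grad"] = grad);
}
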