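// Joint log-density (Dirichlet-Multinomial likelihood + global-local shrinkage
// priors) on the unconstrained, non-centered parameter space, with analytic
// gradients, plus a No-U-Turn sampler (slice variant, dual-averaging step-size
// adaptation, windowed diagonal mass-matrix adaptation).
//
// Unconstrained layout (p covariates, J taxa):
//   [ beta0 (J) | z (p*J) | u (p*J) | v (p*J, horseshoe+ only) | t ]
// where t holds J per-taxon global scales for the horseshoe family and a
// single global rate parameter for the lasso.
// Non-centered coefficient: B = z * S, where S is the prior scale.
//   horseshoe  : local l = exp(u) ~ C+(0,1), tau = exp(t) ~ C+(0,1),
//                lambda = tau * l, S = l * tau^2
//   horseshoe+ : extra layer eta = exp(v) ~ C+(0,1), lambda = tau * eta * l,
//                S = l * eta * tau^2
//   lasso      : S = lambda = exp(u/2), lambda^2 ~ Exp(rate = tau^2/2) with
//                one global tau, tau^2 = exp(t) ~ IG(xi/2, xi*d^2/2)
// Log-scale coordinates carry the usual Jacobian terms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

enum FamilyCode { FAM_HS = 0, FAM_HSP = 1, FAM_LASSO = 2 };
enum LinkCode { LINK_INVLOGIT = 0, LINK_EXP = 1, LINK_SOFTMAX = 2 };

static const double LOG_2_OVER_PI = std::log(2.0 / M_PI);

// digamma via recurrence to x >= 6 plus asymptotic series; |err| < 1e-12 for
// x > 0, which is the only regime used here (shape parameters are positive)
static inline double fast_digamma(double x) {
  double result = 0.0;
  while (x < 6.0) {
    result -= 1.0 / x;
    x += 1.0;
  }
  double r = 1.0 / x, r2 = r * r;
  result += std::log(x) - 0.5 * r -
            r2 * (1.0 / 12.0 -
                  r2 * (1.0 / 120.0 - r2 * (1.0 / 252.0 - r2 / 240.0)));
  return result;
}

// lgamma(x + n) - lgamma(x), stable for large x where the naive difference
// cancels catastrophically (ULP of lgamma(1e16) is ~8); Stirling with the
// 1/(12x) correction is exact to ~1e-25 absolute beyond the cutoff
static inline double lgamma_diff(double x, double n) {
  if (n == 0.0) return 0.0;
  if (x < 1e8) return std::lgamma(x + n) - std::lgamma(x);
  return (x - 0.5) * std::log1p(n / x) + n * std::log(x + n) - n +
         (1.0 / (12.0 * (x + n)) - 1.0 / (12.0 * x));
}

// digamma(x + n) - digamma(x), stable for large x
static inline double digamma_diff(double x, double n) {
  if (n == 0.0) return 0.0;
  if (x < 1e8) return fast_digamma(x + n) - fast_digamma(x);
  return std::log1p(n / x) - (0.5 / (x + n) - 0.5 / x) -
         (1.0 / (12.0 * (x + n) * (x + n)) - 1.0 / (12.0 * x * x));
}

struct DMModel {
  mat Y;        // N x J counts
  mat X;        // N x p covariates
  vec ytot;     // row totals
  mat lgam_y1;  // lgamma(y + 1), precomputed
  vec lgam_n1;  // lgamma(ytot + 1)
  int N, p, J, family, link;
  double offset, conc, xi, d, s0;

  DMModel(const mat& Y_, const mat& X_, int family_, int link_,
          double offset_, double conc_, double xi_, double d_, double s0_)
      : Y(Y_), X(X_), family(family_), link(link_),
        offset(offset_), conc(conc_), xi(xi_), d(d_), s0(s0_) {
    N = Y.n_rows; J = Y.n_cols; p = X.n_cols;
    ytot = sum(Y, 1);
    lgam_y1 = Y;
    lgam_y1.transform([](double y) { return std::lgamma(y + 1.0); });
    lgam_n1 = ytot;
    lgam_n1.transform([](double n) { return std::lgamma(n + 1.0); });
  }

  int dim() const {
    // horseshoe family: per-taxon global scales (J of them); lasso: one
    // global rate parameter for the whole coefficient matrix
    int dd = J + 2 * p * J + (family == FAM_LASSO ? 1 : J);
    if (family == FAM_HSP) dd += p * J;
    return dd;
  }

  // log joint density and gradient at unconstrained theta
  double logp_grad(const vec& th, vec& g) const {
    const int pJ = p * J;
    g.set_size(dim());

    rowvec beta0 = th.subvec(0, J - 1).t();
    mat z(&th[J], p, J);
    mat u(&th[J + pJ], p, J);
    const mat* vptr = nullptr;
    mat vmat;
    int t_off = J + 2 * pJ;
    if (family == FAM_HSP) {
      vmat = mat(&th[J + 2 * pJ], p, J);
      vptr = &vmat;
      t_off += pJ;
    }
    int nGlobal = (family == FAM_LASSO) ? 1 : J;
    vec t = th.subvec(t_off, t_off + nGlobal - 1);

    // prior scale S (p x J) with B = z % S
    mat S(p, J);
    rowvec tau_sq_row(J);  // exp(2t) for HS/HSP (per taxon)
    double tau_sq = 1.0;   // exp(t) for the lasso (single global rate^2)
    if (family == FAM_LASSO) {
      S = exp(0.5 * u);    // lambda; tau enters only as the exponential rate
      tau_sq = std::exp(t[0]);
    } else {
      mat l = exp(u);
      rowvec tq = exp(2.0 * t).t();
      if (family == FAM_HSP) {
        mat le = l % exp(*vptr);
        S = le.each_row() % tq;
      } else {
        S = l.each_row() % tq;
      }
      tau_sq_row = tq;
    }

    mat B = z % S;
    mat eta = X * B;
    eta.each_row() += beta0;

    // link: a = offset + g(eta); ap = g'(eta) for elementwise links, the
    // softmax probabilities for the compositional link
    mat a(N, J), ap(N, J);
    if (link == LINK_SOFTMAX) {
      // a_i = offset + conc * softmax(eta_i): compositional shapes with
      // fixed total concentration
      for (int i = 0; i < N; ++i) {
        rowvec ce = eta.row(i);
        ce -= ce.max();
        rowvec s = exp(ce);
        s /= accu(s);
        ap.row(i) = s;
        a.row(i) = offset + conc * s;
        for (int j = 0; j < J; ++j)
          if (a(i, j) < DBL_MIN) a(i, j) = DBL_MIN;
      }
    } else if (link == LINK_INVLOGIT) {
      for (uword k = 0; k < eta.n_elem; ++k) {
        double s = 1.0 / (1.0 + std::exp(-eta[k]));
        if (s < DBL_MIN) s = DBL_MIN;
        if (s > 1.0 - 1e-16) s = 1.0 - 1e-16;
        a[k] = offset + s;
        ap[k] = s * (1.0 - s);
      }
    } else {
      // C1 linear extension above eta = 300 keeps shapes and gradients
      // finite while warmup explores the tails
      const double etaCap = 300.0, eCap = std::exp(300.0);
      for (uword k = 0; k < eta.n_elem; ++k) {
        double e, de;
        if (eta[k] > etaCap) {
          e = eCap * (1.0 + (eta[k] - etaCap));
          de = eCap;
        } else {
          e = std::exp(eta[k]);
          if (e < DBL_MIN) e = DBL_MIN;
          de = e;
        }
        a[k] = offset + e;
        ap[k] = de;
      }
    }

    // Dirichlet-Multinomial log-likelihood and d loglik / d a; cells with
    // y = 0 contribute nothing beyond the shared row total terms
    double lp = 0.0;
    mat Ga(N, J);
    vec A = sum(a, 1);
    for (int i = 0; i < N; ++i) {
      double Ai = A[i], ni = ytot[i];
      lp += lgam_n1[i] - lgamma_diff(Ai, ni);
      double common = -digamma_diff(Ai, ni);
      for (int j = 0; j < J; ++j) {
        double yij = Y(i, j);
        if (yij == 0.0) {
          Ga(i, j) = common;
          continue;
        }
        double aij = a(i, j);
        lp += lgamma_diff(aij, yij) - lgam_y1(i, j);
        Ga(i, j) = common + digamma_diff(aij, yij);
      }
    }
    if (!std::isfinite(lp)) { g.zeros(); return -datum::inf; }

    mat Geta(N, J);
    if (link == LINK_SOFTMAX) {
      // d a_ij / d eta_ik = conc * s_j (delta_jk - s_k)
      vec gs = sum(Ga % ap, 1);  // sum_j Ga_ij s_ij per sample
      Geta = conc * (ap % (Ga.each_col() - gs));
    } else {
      Geta = Ga % ap;
    }
    mat GB = X.t() * Geta;           // d loglik / d B
    rowvec gbeta0 = sum(Geta, 0);

    // intercept prior N(0, s0^2)
    lp += accu(-0.5 * square(beta0) / (s0 * s0)) -
          J * (0.5 * std::log(2.0 * M_PI) + std::log(s0));
    gbeta0 -= beta0 / (s0 * s0);

    // z ~ N(0,1)
    lp += -0.5 * accu(square(z)) - 0.5 * pJ * std::log(2.0 * M_PI);
    mat gz = GB % S - z;

    mat T = GB % B;  // chain-rule building block for log-scale coords
    mat gu(p, J);
    rowvec gt(nGlobal);

    if (family == FAM_LASSO) {
      // standard Bayesian-lasso mixture: B = z * lambda with
      // lambda^2 = exp(u) ~ Exp(rate = tau^2 / 2), one global tau, so
      // beta | tau is Laplace with rate tau; Jacobian exp(u)
      mat lam2 = exp(u);
      mat rl = 0.5 * tau_sq * lam2;  // rate * lambda^2
      lp += accu(-rl + u) + p * J * (t[0] - std::log(2.0));
      gu = 0.5 * T + 1.0 - rl;
      // tau^2 = exp(t) ~ IG(xi/2, xi d^2/2), Jacobian exp(t)
      double a0 = 0.5 * xi, b0 = 0.5 * xi * d * d;
      lp += a0 * std::log(b0) - std::lgamma(a0) - a0 * t[0] -
            b0 * std::exp(-t[0]);
      gt[0] = p * J - accu(rl) - a0 + b0 * std::exp(-t[0]);
    } else {
      // l = exp(u) ~ C+(0,1) with Jacobian
      mat l2 = exp(2.0 * u);
      lp += accu(LOG_2_OVER_PI - log1p(l2) + u);
      gu = T + 1.0 - 2.0 * l2 / (1.0 + l2);
      if (family == FAM_HSP) {
        mat e2 = exp(2.0 * (*vptr));
        lp += accu(LOG_2_OVER_PI - log1p(e2) + (*vptr));
        mat gv = T + 1.0 - 2.0 * e2 / (1.0 + e2);
        g.subvec(J + 2 * pJ, J + 3 * pJ - 1) = vectorise(gv);
      }
      // tau = exp(t) ~ C+(0,1)
      vec tq = tau_sq_row.t();
      lp += accu(LOG_2_OVER_PI - log1p(tq) + t);
      gt = 2.0 * sum(T, 0) + 1.0 - (2.0 * tq / (1.0 + tq)).t();
    }

    g.subvec(0, J - 1) = gbeta0.t();
    g.subvec(J, J + pJ - 1) = vectorise(gz);
    g.subvec(J + pJ, J + 2 * pJ - 1) = vectorise(gu);
    g.subvec(t_off, t_off + nGlobal - 1) = gt.t();

    if (!g.is_finite()) { g.zeros(); return -datum::inf; }
    return lp;
  }
};

// ---------------------------------------------------------------------------
// Generic NUTS over a log-density-with-gradient target
// ---------------------------------------------------------------------------

typedef std::function<double(const vec&, vec&)> Target;

struct NutsSampler {
  Target target;
  int dim;
  vec inv_mass;  // diagonal of inverse mass matrix (posterior variance scale)
  double eps;
  int max_depth;
  double delta;  // target acceptance
  // dual averaging state
  double da_mu, da_logeps, da_logeps_bar, da_Hbar;
  int da_m;
  static constexpr double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  // per-trajectory bookkeeping
  double sum_alpha; int n_alpha; bool divergent;

  NutsSampler(Target tgt, int dim_, double delta_, int max_depth_)
      : target(tgt), dim(dim_), eps(1.0), max_depth(max_depth_), delta(delta_) {
    inv_mass = ones<vec>(dim);
  }

  double kinetic(const vec& r) const { return 0.5 * dot(inv_mass, square(r)); }

  vec sample_momentum() const {
    vec r(dim);
    for (int k = 0; k < dim; ++k) r[k] = ::norm_rand() / std::sqrt(inv_mass[k]);
    return r;
  }

  // one leapfrog step; returns logp at the new point
  double leapfrog(vec& th, vec& r, vec& grad, double direction) const {
    double e = direction * eps;
    r += 0.5 * e * grad;
    th += e * (inv_mass % r);
    double lp = target(th, grad);
    r += 0.5 * e * grad;
    return lp;
  }

  void find_reasonable_eps(const vec& th0) {
    eps = 1.0;
    vec grad0(dim);
    double lp0 = target(th0, grad0);
    vec r0 = sample_momentum();
    double H0 = lp0 - kinetic(r0);
    vec th = th0, r = r0, grad = grad0;
    double lp = leapfrog(th, r, grad, 1.0);
    double ratio = std::exp((lp - kinetic(r)) - H0);
    if (!std::isfinite(ratio)) ratio = 0.0;
    double aexp = (ratio > 0.5) ? 1.0 : -1.0;
    for (int it = 0; it < 60; ++it) {
      eps *= std::pow(2.0, aexp);
      th = th0; r = r0; grad = grad0;
      lp = leapfrog(th, r, grad, 1.0);
      ratio = std::exp((lp - kinetic(r)) - H0);
      if (!std::isfinite(ratio)) ratio = 0.0;
      if (std::pow(ratio, aexp) <= std::pow(2.0, -aexp)) break;
    }
    if (!std::isfinite(eps) || eps <= 0) eps = 1e-3;
    if (eps < 1e-8) eps = 1e-8;
    if (eps > 1e6) eps = 1e6;
  }

  void da_init() {
    da_mu = std::log(10.0 * eps);
    da_logeps = std::log(eps);
    da_logeps_bar = std::log(eps);
    da_Hbar = 0.0;
    da_m = 0;
  }

  void da_update() {
    da_m += 1;
    double alpha = (n_alpha > 0) ? sum_alpha / n_alpha : 0.0;
    double w = 1.0 / (da_m + da_t0);
    da_Hbar = (1.0 - w) * da_Hbar + w * (delta - alpha);
    da_logeps = da_mu - std::sqrt((double)da_m) / da_gamma * da_Hbar;
    double w2 = std::pow((double)da_m, -da_kappa);
    da_logeps_bar = w2 * da_logeps + (1.0 - w2) * da_logeps_bar;
    eps = std::exp(da_logeps);
  }

  struct Tree {
    vec th_minus, r_minus, grad_minus;
    vec th_plus, r_plus, grad_plus;
    vec th_prop;
    double n;    // number of valid points
    bool s;      // no U-turn / no divergence
  };

  bool no_uturn(const vec& th_plus, const vec& th_minus, const vec& r_plus,
                const vec& r_minus) const {
    vec dth = th_plus - th_minus;
    return dot(dth, inv_mass % r_minus) >= 0 &&
           dot(dth, inv_mass % r_plus) >= 0;
  }

  Tree build_tree(const vec& th, const vec& r, const vec& grad, double logu,
                  double direction, int depth, double H0) {
    Tree tr;
    if (depth == 0) {
      vec th1 = th, r1 = r, grad1 = grad;
      double lp = leapfrog(th1, r1, grad1, direction);
      double joint = lp - kinetic(r1);
      if (!std::isfinite(joint)) joint = -datum::inf;
      tr.n = (logu <= joint) ? 1.0 : 0.0;
      tr.s = (logu < joint + 1000.0);
      if (!tr.s) divergent = true;
      double acc = std::exp(std::min(0.0, joint - H0));
      sum_alpha += std::isfinite(acc) ? acc : 0.0;
      n_alpha += 1;
      tr.th_minus = th1; tr.r_minus = r1; tr.grad_minus = grad1;
      tr.th_plus = th1; tr.r_plus = r1; tr.grad_plus = grad1;
      tr.th_prop = th1;
      return tr;
    }
    Tree t1 = build_tree(th, r, grad, logu, direction, depth - 1, H0);
    if (!t1.s) return t1;
    Tree t2 = (direction > 0)
                  ? build_tree(t1.th_plus, t1.r_plus, t1.grad_plus, logu,
                               direction, depth - 1, H0)
                  : build_tree(t1.th_minus, t1.r_minus, t1.grad_minus, logu,
                               direction, depth - 1, H0);
    Tree tr2;
    if (direction > 0) {
      tr2.th_minus = t1.th_minus; tr2.r_minus = t1.r_minus;
      tr2.grad_minus = t1.grad_minus;
      tr2.th_plus = t2.th_plus; tr2.r_plus = t2.r_plus;
      tr2.grad_plus = t2.grad_plus;
    } else {
      tr2.th_minus = t2.th_minus; tr2.r_minus = t2.r_minus;
      tr2.grad_minus = t2.grad_minus;
      tr2.th_plus = t1.th_plus; tr2.r_plus = t1.r_plus;
      tr2.grad_plus = t1.grad_plus;
    }
    double ntot = t1.n + t2.n;
    tr2.th_prop = t1.th_prop;
    if (t2.s && ntot > 0 && ::unif_rand() < t2.n / ntot)
      tr2.th_prop = t2.th_prop;
    tr2.n = ntot;
    tr2.s = t2.s && no_uturn(tr2.th_plus, tr2.th_minus, tr2.r_plus, tr2.r_minus);
    return tr2;
  }

  // one NUTS transition; updates th in place, returns tree depth used
  int transition(vec& th) {
    vec grad(dim);
    double lp = target(th, grad);
    vec r = sample_momentum();
    double H0 = lp - kinetic(r);
    double logu = H0 - ::exp_rand();
    vec th_minus = th, th_plus = th, r_minus = r, r_plus = r;
    vec grad_minus = grad, grad_plus = grad;
    vec th_prop = th;
    double n = 1.0;
    bool s = true;
    int depth = 0;
    sum_alpha = 0.0; n_alpha = 0; divergent = false;
    while (s && depth < max_depth) {
      double direction = (::unif_rand() < 0.5) ? -1.0 : 1.0;
      Tree tr = (direction > 0)
                    ? build_tree(th_plus, r_plus, grad_plus, logu, direction,
                                 depth, H0)
                    : build_tree(th_minus, r_minus, grad_minus, logu, direction,
                                 depth, H0);
      if (direction > 0) {
        th_plus = tr.th_plus; r_plus = tr.r_plus; grad_plus = tr.grad_plus;
      } else {
        th_minus = tr.th_minus; r_minus = tr.r_minus;
        grad_minus = tr.grad_minus;
      }
      if (tr.s && tr.n > 0 && ::unif_rand() < std::min(1.0, tr.n / n))
        th_prop = tr.th_prop;
      n += tr.n;
      s = tr.s && no_uturn(th_plus, th_minus, r_plus, r_minus);
      depth += 1;
    }
    th = th_prop;
    return depth;
  }
};

// Stan-style warmup window schedule: step-size-only init buffer, doubling
// variance-estimation windows, step-size-only terminal buffer.
struct WarmupSchedule {
  int init_buffer = 0;
  std::vector<int> ends;  // iteration indices (1-based) at which windows close
};

static WarmupSchedule warmup_schedule(int warmup) {
  WarmupSchedule ws;
  ws.init_buffer = warmup;
  if (warmup < 20) return ws;
  int ib = 75, tb = 50, base = 25;
  if (ib + tb + base > warmup) {
    ib = (int)(0.15 * warmup);
    tb = (int)(0.10 * warmup);
    base = warmup - ib - tb;
  }
  ws.init_buffer = ib;
  int start = ib, w = base;
  while (start + w < warmup - tb) {
    if (start + w + 2 * w >= warmup - tb) break;  // extend last window
    ws.ends.push_back(start + w);
    start += w;
    w *= 2;
  }
  ws.ends.push_back(warmup - tb);
  return ws;
}

static Rcpp::List run_nuts_chain(Target target, const vec& init, int iter,
                                 int warmup, double target_accept,
                                 int max_depth, bool adapt_mass) {
  int dim = init.n_elem;
  NutsSampler s(target, dim, target_accept, max_depth);
  vec th = init;

  {
    vec g(dim);
    double lp0 = target(th, g);
    if (!std::isfinite(lp0))
      Rcpp::stop("non-finite log-density at initialization (lp = %f)", lp0);
  }

  WarmupSchedule ws = adapt_mass ? warmup_schedule(warmup) : WarmupSchedule();
  if (!adapt_mass) ws.init_buffer = warmup;
  const std::vector<int>& wends = ws.ends;
  size_t wnext = 0;
  // Welford accumulators over the current variance window
  vec wf_mean = zeros<vec>(dim), wf_m2 = zeros<vec>(dim);
  int wf_n = 0;
  int wf_from = wends.empty() ? warmup : ws.init_buffer;

  s.find_reasonable_eps(th);
  s.da_init();

  int kept = iter - warmup;
  mat draws(kept, dim);
  int divergences = 0, div_warmup = 0;
  double sum_accept = 0.0;
  double sum_depth = 0.0;

  for (int m = 0; m < iter; ++m) {
    if (m % 64 == 0) Rcpp::checkUserInterrupt();
    int depth = s.transition(th);
    bool in_warmup = m < warmup;
    if (in_warmup) {
      s.da_update();
      if (s.divergent) ++div_warmup;
      if (!wends.empty() && m >= wf_from) {
        ++wf_n;
        vec delta = th - wf_mean;
        wf_mean += delta / wf_n;
        wf_m2 += delta % (th - wf_mean);
      }
      if (wnext < wends.size() && (m + 1) == wends[wnext]) {
        if (wf_n > 1) {
          vec var = wf_m2 / (wf_n - 1.0);
          // regularize toward unit scale as the sample is small
          double nr = wf_n;
          s.inv_mass = (nr / (nr + 5.0)) * var +
                       (5.0 / (nr + 5.0)) * 1e-3 * ones<vec>(dim);
          s.inv_mass = clamp(s.inv_mass, 1e-10, 1e10);
        }
        wf_mean.zeros(); wf_m2.zeros(); wf_n = 0;
        s.find_reasonable_eps(th);
        s.da_init();
        ++wnext;
      }
      if (m + 1 == warmup) s.eps = std::exp(s.da_logeps_bar);
    } else {
      if (s.divergent) ++divergences;
      double alpha = (s.n_alpha > 0) ? s.sum_alpha / s.n_alpha : 0.0;
      sum_accept += alpha;
      sum_depth += depth;
      draws.row(m - warmup) = th.t();
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("draws") = draws,
      Rcpp::Named("stepsize") = s.eps,
      Rcpp::Named("divergences") = divergences,
      Rcpp::Named("divergences_warmup") = div_warmup,
      Rcpp::Named("mean_accept") = kept > 0 ? sum_accept / kept : NA_REAL,
      Rcpp::Named("mean_treedepth") = kept > 0 ? sum_depth / kept : NA_REAL,
      Rcpp::Named("inv_mass") = s.inv_mass);
}

// [[Rcpp::export(name = ".dm_logp_grad")]]
Rcpp::List dm_logp_grad(const arma::mat& Y, const arma::mat& X, int family,
                        int link, double offset, double link_conc, double xi,
                        double d, double intercept_sd,
                        const arma::vec& theta) {
  DMModel mod(Y, X, family, link, offset, link_conc, xi, d, intercept_sd);
  if ((int)theta.n_elem != mod.dim())
    Rcpp::stop("theta has length %d, model dimension is %d", theta.n_elem,
               mod.dim());
  vec g(mod.dim());
  double lp = mod.logp_grad(theta, g);
  return Rcpp::List::create(Rcpp::Named("logp") = lp,
                            Rcpp::Named("grad") = g);
}

// [[Rcpp::export(name = ".dm_model_dim")]]
int dm_model_dim(int p, int J, int family) {
  int dd = J + 2 * p * J + (family == FAM_LASSO ? 1 : J);
  if (family == FAM_HSP) dd += p * J;
  return dd;
}

// [[Rcpp::export(name = ".dm_nuts_chain")]]
Rcpp::List dm_nuts_chain(const arma::mat& Y, const arma::mat& X, int family,
                         int link, double offset, double link_conc, double xi,
                         double d, double intercept_sd, int iter, int warmup,
                         double target_accept, int max_depth,
                         const arma::vec& init) {
  DMModel mod(Y, X, family, link, offset, link_conc, xi, d, intercept_sd);
  if ((int)init.n_elem != mod.dim())
    Rcpp::stop("init has length %d, model dimension is %d", init.n_elem,
               mod.dim());
  Target tgt = [&mod](const vec& th, vec& g) { return mod.logp_grad(th, g); };
  return run_nuts_chain(tgt, init, iter, warmup, target_accept, max_depth,
                        true);
}

// [[Rcpp::export(name = ".nuts_gaussian_chain")]]
Rcpp::List nuts_gaussian_chain(int dim, int iter, int warmup,
                               double target_accept, int max_depth,
                               const arma::vec& init) {
  Target tgt = [](const vec& th, vec& g) {
    g = -th;
    return -0.5 * dot(th, th);
  };
  return run_nuts_chain(tgt, init, iter, warmup, target_accept, max_depth,
                        true);
}
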