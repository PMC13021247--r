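#include <Rcpp.h>
using namespace Rcpp;

// Wiener first-passage-time machinery for the two-boundary diffusion with
// drift v, boundary separation a, relative start z (fraction of a),
// nondecision time t0, diffusion coefficient fixed at 1.
//
// The defective density of absorption at the LOWER boundary at decision time
// u is evaluated through the standardized process (a = 1, v = 0) at
// normalized time tt = u / a^2 using two truncated series (small-time /
// large-time), with term counts chosen adaptively so the truncation error of
// the standardized density is below EPS_SERIES. The upper-boundary density
// follows by the reflection v -> -v, z -> 1 - z.

static const double EPS_SERIES = 1e-10;

// standardized lower-boundary density at normalized time tt, start w.
// regime: 0 = auto (cheaper series), 1 = force small-time, 2 = force large-time
static double ft_std(double tt, double w, int regime) {
  if (tt <= 0.0 || !R_FINITE(tt)) return 0.0;

  // adaptive term counts
  double ks = 2.0;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * EPS_SERIES < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * EPS_SERIES * std::sqrt(2.0 * M_PI * tt)));
    double lo = std::sqrt(tt) + 1.0;
    if (ks < lo) ks = lo;
  }
  double kl = 1.0 / (M_PI * std::sqrt(tt));
  if (M_PI * tt * EPS_SERIES < 1.0) {
    double cand = std::sqrt(-2.0 * std::log(M_PI * tt * EPS_SERIES) /
                            (M_PI * M_PI * tt));
    if (cand > kl) kl = cand;
  }

  bool small_time = (regime == 1) || (regime == 0 && ks < kl);
  double f = 0.0;
  if (small_time) {
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double x = w + 2.0 * k;
      f += x * std::exp(-x * x / (2.0 * tt));
    }
    f /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
           std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// full defective density at clock time rt; upper = 1 for the upper boundary
static double dwfpt_one(double rt, int upper, double v, double a, double z,
                        double t0, int regime) {
  double u = rt - t0;
  if (u <= 0.0) return 0.0;
  double vv = v, w = z;
  if (upper) { vv = -v; w = 1.0 - z; }
  double tt = u / (a * a);
  double f = ft_std(tt, w, regime);
  if (f <= 0.0) return 0.0;
  double lg = -vv * a * w - vv * vv * u / 2.0;
  return f / (a * a) * std::exp(lg);
}

// [[Rcpp::export]]
NumericVector dwfpt_cpp(NumericVector rt, IntegerVector upper, double v,
                        double a, double z, double t0, int regime) {
  int n = rt.size();
  NumericVector out(n);
  bool rec = upper.size() == 1;
  for (int i = 0; i < n; ++i) {
    int up = rec ? upper[0] : upper[i];
    out[i] = dwfpt_one(rt[i], up, v, a, z, t0, regime);
  }
  return out;
}

// contaminant-mixture log-density of one trial
static inline double ll_one(double rt, int up, double v, double a, double z,
                            double t0, double p_out, double cdens) {
  double d = (1.0 - p_out) * dwfpt_one(rt, up, v, a, z, t0, 0);
  if (cdens > 0.0) d += cdens;
  return d > 0.0 ? std::log(d) : R_NegInf;
}

// sum of mixture log-densities over a contiguous range with common params
static double ll_range(const double* rt, const int* ch, int n, double v,
                       double a, double z, double t0, double p_out,
                       double tmax) {
  double c = (p_out > 0.0 && tmax > 0.0) ? p_out * 0.5 / tmax : 0.0;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double cd = (c > 0.0 && rt[i] <= tmax) ? c : 0.0;
    ll += ll_one(rt[i], ch[i], v, a, z, t0, p_out, cd);
    if (!R_FINITE(ll)) return R_NegInf;
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector loglik_mix_cpp(NumericVector rt, IntegerVector choice, double v,
                             double a, double z, double t0, double p_out,
                             double tmax) {
  int n = rt.size();
  NumericVector out(n);
  double c = (p_out > 0.0 && tmax > 0.0) ? p_out * 0.5 / tmax : 0.0;
  for (int i = 0; i < n; ++i) {
    double cd = (c > 0.0 && rt[i] <= tmax) ? c : 0.0;
    out[i] = ll_one(rt[i], choice[i], v, a, z, t0, p_out, cd);
  }
  return out;
}

// Per-subject-per-cell data log-likelihood for the whole sample.
// Trials are sorted by subject then morph cell; off is S x (C+1) 0-based
// offsets. v is S x C; zt/la/lt0 are unconstrained subject parameters.
// [[Rcpp::export]]
NumericMatrix loglik_cells_cpp(NumericVector rt, IntegerVector choice,
                               IntegerMatrix off, NumericMatrix v,
                               NumericVector zt, NumericVector la,
                               NumericVector lt0, double p_out, double tmax) {
  int S = off.nrow(), C = off.ncol() - 1;
  NumericMatrix out(S, C);
  const double* prt = REAL(rt);
  const int* pch = INTEGER(choice);
  for (int s = 0; s < S; ++s) {
    double z = 1.0 / (1.0 + std::exp(-zt[s]));
    double a = std::exp(la[s]);
    double t0 = std::exp(lt0[s]);
    for (int c = 0; c < C; ++c) {
      int i0 = off(s, c), n = off(s, c + 1) - off(s, c);
      out(s, c) = ll_range(prt + i0, pch + i0, n, v(s, c), a, z, t0, p_out,
                           tmax);
    }
  }
  return out;
}

// One full Metropolis-within-Gibbs sweep over all subject-level parameters.
// Random-walk proposals on unconstrained scales with per-parameter scales;
// group-level normals supply the (partial-pooling) prior. Cached per-cell
// data log-likelihoods cll are maintained across updates. Uses R's RNG.
// [[Rcpp::export]]
List mh_sweep_cpp(NumericVector rt, IntegerVector choice, IntegerMatrix off,
                  NumericMatrix v_in, NumericVector zt_in, NumericVector la_in,
                  NumericVector lt0_in, NumericMatrix cll_in,
                  NumericMatrix mu_v, NumericMatrix sd_v, NumericVector mu_z,
                  NumericVector sd_z, NumericVector mu_a, NumericVector sd_a,
                  NumericVector mu_t, NumericVector sd_t, NumericMatrix sc_v,
                  NumericVector sc_z, NumericVector sc_a, NumericVector sc_t,
                  bool sample_z, double p_out, double tmax) {
  int S = off.nrow(), C = off.ncol() - 1;
  NumericMatrix v = clone(v_in), cll = clone(cll_in);
  NumericVector zt = clone(zt_in), la = clone(la_in), lt0 = clone(lt0_in);
  IntegerMatrix acc_v(S, C);
  IntegerVector acc_z(S), acc_a(S), acc_t(S);
  const double* prt = REAL(rt);
  const int* pch = INTEGER(choice);
  std::vector<double> prop(C);

  for (int s = 0; s < S; ++s) {
    double z = 1.0 / (1.0 + std::exp(-zt[s]));
    double a = std::exp(la[s]);
    double t0 = std::exp(lt0[s]);

    // drift per morph cell
    for (int c = 0; c < C; ++c) {
      int i0 = off(s, c), n = off(s, c + 1) - off(s, c);
      double vp = v(s, c) + R::norm_rand() * sc_v(s, c);
      double llp = ll_range(prt + i0, pch + i0, n, vp, a, z, t0, p_out, tmax);
      double lr = llp - cll(s, c) +
                  R::dnorm(vp, mu_v(s, c), sd_v(s, c), 1) -
                  R::dnorm(v(s, c), mu_v(s, c), sd_v(s, c), 1);
      if (R_FINITE(lr) && (lr >= 0.0 || R::unif_rand() < std::exp(lr))) {
        v(s, c) = vp;
        cll(s, c) = llp;
        acc_v(s, c) = 1;
      }
    }

    // starting point (logit scale)
    if (sample_z) {
      double ztp = zt[s] + R::norm_rand() * sc_z[s];
      double zp = 1.0 / (1.0 + std::exp(-ztp));
      double lr = R::dnorm(ztp, mu_z[s], sd_z[s], 1) -
                  R::dnorm(zt[s], mu_z[s], sd_z[s], 1);
      for (int c = 0; c < C; ++c) {
        int i0 = off(s, c), n = off(s, c + 1) - off(s, c);
        prop[c] = ll_range(prt + i0, pch + i0, n, v(s, c), a, zp, t0, p_out,
                           tmax);
        lr += prop[c] - cll(s, c);
      }
      if (R_FINITE(lr) && (lr >= 0.0 || R::unif_rand() < std::exp(lr))) {
        zt[s] = ztp;
        z = zp;
        for (int c = 0; c < C; ++c) cll(s, c) = prop[c];
        acc_z[s] = 1;
      }
    }

    // boundary separation (log scale)
    {
      double lap = la[s] + R::norm_rand() * sc_a[s];
      double ap = std::exp(lap);
      double lr = R::dnorm(lap, mu_a[s], sd_a[s], 1) -
                  R::dnorm(la[s], mu_a[s], sd_a[s], 1);
      for (int c = 0; c < C; ++c) {
        int i0 = off(s, c), n = off(s, c + 1) - off(s, c);
        prop[c] = ll_range(prt + i0, pch + i0, n, v(s, c), ap, z, t0, p_out,
                           tmax);
        lr += prop[c] - cll(s, c);
      }
      if (R_FINITE(lr) && (lr >= 0.0 || R::unif_rand() < std::exp(lr))) {
        la[s] = lap;
        a = ap;
        for (int c = 0; c < C; ++c) cll(s, c) = prop[c];
        acc_a[s] = 1;
      }
    }

    // nondecision time (log scale)
    {
      double ltp = lt0[s] + R::norm_rand() * sc_t[s];
      double t0p = std::exp(ltp);
      double lr = R::dnorm(ltp, mu_t[s], sd_t[s], 1) -
                  R::dnorm(lt0[s], mu_t[s], sd_t[s], 1);
      for (int c = 0; c < C; ++c) {
        int i0 = off(s, c), n = off(s, c + 1) - off(s, c);
        prop[c] = ll_range(prt + i0, pch + i0, n, v(s, c), a, z, t0p, p_out,
                           tmax);
        lr += prop[c] - cll(s, c);
      }
      if (R_FINITE(lr) && (lr >= 0.0 || R::unif_rand() < std::exp(lr))) {
        lt0[s] = ltp;
        for (int c = 0; c < C; ++c) cll(s, c) = prop[c];
        acc_t[s] = 1;
      }
    }
  }

  return List::create(_["v"] = v, _["zt"] = zt, _["la"] = la, _["lt0"] = lt0,
                      _["cll"] = cll, _["acc_v"] = acc_v, _["acc_z"] = acc_z,
                      _["acc_a"] = acc_a, _["acc_t"] = acc_t);
}

// Euler-Maruyama trial simulator: validation oracle only (never used by the
// pipeline simulator, which inverts the series density).
// [[Rcpp::export]]
List sim_ddm_euler_cpp(int n, double v, double a, double z, double t0,
                       double dt, double t_cap) {
  NumericVector rt(n);
  IntegerVector choice(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = z * a, t = 0.0;
    int up = -1;
    while (t < t_cap) {
      x += v * dt + sdt * R::norm_rand();
      t += dt;
      if (x >= a) { up = 1; break; }
      if (x <= 0.0) { up = 0; break; }
    }
    if (up < 0) up = x >= a / 2.0 ? 1 : 0;  // censored at t_cap (rare)
    rt[i] = t0 + t;
    choice[i] = up;
  }
  return List::create(_["rt"] = rt, _["choice"] = choice);
}
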