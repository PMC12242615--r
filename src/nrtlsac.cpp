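#include <Rcpp.h>
using namespace Rcpp;

// Segment order everywhere: X, Y-, Y+, Z.
static const int NSEG = 4;
static const double RGAS = 8.314;        // J mol^-1 K^-1
static const double XFLOOR = 1e-12;      // mole-fraction floor for the dilute limit

// Local-composition ln Gamma_m for all four segments given segment fractions xs
// (entries may be zero; segments absent from every molecule drop out of all sums
// because every term is xs-weighted, so no special casing is needed).
static void local_lngamma(const double* xs, const double* tau, const double* G,
                          double* lnGam) {
  double denom[NSEG], num[NSEG];
  for (int m = 0; m < NSEG; ++m) {
    double d = 0.0, n = 0.0;
    for (int k = 0; k < NSEG; ++k) {
      d += xs[k] * G[k + NSEG * m];
      n += xs[k] * G[k + NSEG * m] * tau[k + NSEG * m];
    }
    denom[m] = d;
    num[m] = n;
  }
  for (int m = 0; m < NSEG; ++m) {
    double v = num[m] / denom[m];
    for (int mp = 0; mp < NSEG; ++mp) {
      v += xs[mp] * G[m + NSEG * mp] / denom[mp] *
           (tau[m + NSEG * mp] - num[mp] / denom[mp]);
    }
    lnGam[m] = v;
  }
}

// [[Rcpp::export(name = ".cpp_local_lngamma")]]
NumericVector cpp_local_lngamma(NumericVector xs, NumericMatrix tau, NumericMatrix G) {
  double out[NSEG];
  local_lngamma(REAL(xs), REAL(tau), REAL(G), out);
  return NumericVector(out, out + NSEG);
}

// Residual + combinatorial ln gamma for every component of a mixture.
// Rm: n x 4 matrix of segment numbers; x: mole fractions (sum to 1).
// Returns n x 3 matrix: columns (residual, combinatorial, total).
// [[Rcpp::export(name = ".cpp_lngamma_components")]]
NumericMatrix cpp_lngamma_components(NumericMatrix Rm, NumericVector x,
                                     NumericMatrix tau, NumericMatrix G) {
  const int n = Rm.nrow();
  NumericMatrix out(n, 3);

  // mixture segment fractions (Eq 9) and total-segment sum S = sum_J r_J x_J
  double xs[NSEG];
  double S = 0.0;
  for (int j = 0; j < NSEG; ++j) {
    double num = 0.0;
    for (int I = 0; I < n; ++I) num += x[I] * Rm(I, j);
    xs[j] = num;
    S += num;
  }
  if (S <= 0.0) stop("degenerate mixture: total segment number is zero");
  for (int j = 0; j < NSEG; ++j) xs[j] /= S;

  double lnGmix[NSEG];
  local_lngamma(xs, REAL(tau), REAL(G), lnGmix);

  for (int I = 0; I < n; ++I) {
    double rI = 0.0;
    for (int j = 0; j < NSEG; ++j) rI += Rm(I, j);
    if (rI <= 0.0) stop("component %d has zero total segment number", I + 1);

    // pure-component reference (Eq 7 with Eq 10 fractions)
    double xsI[NSEG], lnGpure[NSEG];
    for (int j = 0; j < NSEG; ++j) xsI[j] = Rm(I, j) / rI;
    local_lngamma(xsI, REAL(tau), REAL(G), lnGpure);

    double res = 0.0;
    for (int j = 0; j < NSEG; ++j) res += Rm(I, j) * (lnGmix[j] - lnGpure[j]);

    // Flory-Huggins term; phi_J / r_J = x_J / S so sum_J phi_J/r_J = 1/S,
    // and phi_I/x_I = r_I/S holds also in the x_I -> 0 limit.
    double t = rI / S;
    double comb = 1.0 + std::log(t) - t;

    out(I, 0) = res;
    out(I, 1) = comb;
    out(I, 2) = res + comb;
  }
  return out;
}

// ln gamma of the solute in a binary solute(x) + solvent(1-x) mixture.
static double lngamma_solute_binary(double x, const double* rs, const double* rv,
                                    const double* tau, const double* G) {
  double rs_sum = 0.0, rv_sum = 0.0;
  for (int j = 0; j < NSEG; ++j) { rs_sum += rs[j]; rv_sum += rv[j]; }
  double S = x * rs_sum + (1.0 - x) * rv_sum;

  double xs[NSEG], xsI[NSEG];
  for (int j = 0; j < NSEG; ++j) {
    xs[j]  = (x * rs[j] + (1.0 - x) * rv[j]) / S;
    xsI[j] = rs[j] / rs_sum;
  }
  double lnGmix[NSEG], lnGpure[NSEG];
  local_lngamma(xs, tau, G, lnGmix);
  local_lngamma(xsI, tau, G, lnGpure);

  double res = 0.0;
  for (int j = 0; j < NSEG; ++j) res += rs[j] * (lnGmix[j] - lnGpure[j]);
  double t = rs_sum / S;
  return res + 1.0 + std::log(t) - t;
}

// [[Rcpp::export(name = ".cpp_lngamma_binary")]]
double cpp_lngamma_binary(double x, NumericVector rs, NumericVector rv,
                          NumericMatrix tau, NumericMatrix G) {
  return lngamma_solute_binary(x, REAL(rs), REAL(rv), REAL(tau), REAL(G));
}

// Solve ln x = ln x_ideal - ln gamma(x) for the saturation mole fraction.
// Damped successive substitution from the ideal point, with a bisection
// fallback on the residual g(lnx) = lnx - lnx_ideal + lngamma(exp(lnx)).
// Returns (x_sat, lngamma_sat, converged, iterations).
// [[Rcpp::export(name = ".cpp_solve_saturation")]]
NumericVector cpp_solve_saturation(NumericVector rs, NumericVector rv,
                                   double lnx_ideal, NumericMatrix tau,
                                   NumericMatrix G, double tol = 1e-10,
                                   int maxit = 500, double damping = 0.5) {
  const double lnlo = std::log(XFLOOR), lnhi = 0.0;
  const double* prs = REAL(rs);
  const double* prv = REAL(rv);
  const double* pt = REAL(tau);
  const double* pg = REAL(G);

  double lnx = std::min(std::max(lnx_ideal, lnlo), lnhi);
  int it = 0;
  bool ok = false;
  double lg = 0.0;
  for (; it < maxit; ++it) {
    lg = lngamma_solute_binary(std::exp(lnx), prs, prv, pt, pg);
    double target = lnx_ideal - lg;
    double resid = lnx - target;
    if (std::fabs(resid) <= tol) { ok = true; break; }
    lnx += damping * (target - lnx);
    lnx = std::min(std::max(lnx, lnlo), lnhi);
  }

  if (!ok) {
    // bisection on the residual over [lnlo, lnhi]
    auto g = [&](double l) {
      return l - lnx_ideal + lngamma_solute_binary(std::exp(l), prs, prv, pt, pg);
    };
    double a = lnlo, b = lnhi, ga = g(a), gb = g(b);
    if (ga * gb <= 0.0) {
      for (int k = 0; k < 300; ++k) {
        double m = 0.5 * (a + b), gm = g(m);
        if (std::fabs(gm) <= tol) { lnx = m; ok = true; break; }
        if (ga * gm <= 0.0) { b = m; gb = gm; } else { a = m; ga = gm; }
        ++it;
      }
      if (!ok) {
        double m = 0.5 * (a + b);
        if (std::fabs(g(m)) <= tol) { lnx = m; ok = true; }
      }
    }
    lg = lngamma_solute_binary(std::exp(lnx), prs, prv, pt, pg);
  }

  return NumericVector::create(std::exp(lnx), lg, ok ? 1.0 : 0.0, (double)it);
}

// Half sum-of-squares objective over a dataset (Eq 14 form); non-converged or
// out-of-domain model points contribute a constant penalty.
// theta = (r_X, r_Y-, r_Y+, r_Z, dH_fus [kJ/mol], T_mp [K]).
// solvR: ndata x 4 segment numbers of the solvent of each record.
// [[Rcpp::export(name = ".cpp_sse_objective")]]
double cpp_sse_objective(NumericVector theta, NumericMatrix solvR,
                         NumericVector temperature, NumericVector x_exp,
                         NumericMatrix tau, NumericMatrix G,
                         double tol = 1e-10, int maxit = 500,
                         double penalty = 1e6, bool log_residuals = false) {
  const int nd = solvR.nrow();
  double rs[NSEG];
  for (int j = 0; j < NSEG; ++j) rs[j] = theta[j];
  double rsum = rs[0] + rs[1] + rs[2] + rs[3];
  const double dH = theta[4] * 1000.0;  // kJ/mol -> J/mol
  const double Tmp = theta[5];

  if (rsum <= 0.0) return nd * penalty;

  double ss = 0.0;
  double rv[NSEG];
  for (int i = 0; i < nd; ++i) {
    const double T = temperature[i];
    const double lnx_ideal = dH / RGAS * (1.0 / Tmp - 1.0 / T);
    if (lnx_ideal > 0.0) { ss += penalty; continue; }  // T above melting: no solid
    for (int j = 0; j < NSEG; ++j) rv[j] = solvR(i, j);
    NumericVector rvv(rv, rv + NSEG), rss(rs, rs + NSEG);
    NumericVector sol = cpp_solve_saturation(rss, rvv, lnx_ideal, tau, G, tol, maxit, 0.5);
    if (sol[2] < 0.5) { ss += penalty; continue; }
    double resid = log_residuals ? (std::log(x_exp[i]) - std::log(sol[0]))
                                 : (x_exp[i] - sol[0]);
    ss += 0.5 * resid * resid;
  }
  return ss;
}
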