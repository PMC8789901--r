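// Compiled stage engine for the monotone CABARET scheme.
//
// Mirrors, operation for operation, the R reference path in R/cabaret-steps.R
// and R/cabaret-run.R for the closed-form model family: mobility-ratio
// fractional flow with power-law relative permeabilities and power/affine
// healthy-bed response curves.  The R path stays the canonical definition;
// tests assert both paths agree on identical stages.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

constexpr double DYN_PER_MMHG = 1333.22;
constexpr double S_RATIO_FLOOR = 1e-12;
constexpr double THETA_SWITCH = 1e-8;
constexpr double CFL_A_FRAC = 1e-2;   // occluded cells do not bind the CFL step

struct Flux {
  double a, b, eb, ee;            // alpha_b, alpha_e, eta_b, eta_e
  std::vector<double> tabF;       // f on a uniform S-grid, for inverse seeding
  int ntab;

  double f(double S) const {
    double lb = std::pow(S, a) / eb;
    double le = std::pow(1.0 - S, b) / ee;
    return lb / (lb + le);
  }
  double df(double S) const {
    double lb = std::pow(S, a) / eb;
    double le = std::pow(1.0 - S, b) / ee;
    double dlb = a * std::pow(S, a - 1.0) / eb;
    double dle = -b * std::pow(1.0 - S, b - 1.0) / ee;
    double s = lb + le;
    return (dlb * le - lb * dle) / (s * s);
  }
  void build_table(int n = 4097) {
    ntab = n;
    tabF.resize(n);
    for (int i = 0; i < n; ++i) tabF[i] = f((double)i / (n - 1));
  }
  // safeguarded Newton from a table-seeded bracket; residual ~1e-14
  double finv(double y) const {
    if (y <= 0.0) return 0.0;
    if (y >= 1.0) return 1.0;
    int lo = 0, hi = ntab - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (tabF[mid] < y) lo = mid; else hi = mid;
    }
    double Slo = (double)lo / (ntab - 1), Shi = (double)hi / (ntab - 1);
    double Flo = tabF[lo], Fhi = tabF[hi];
    double S = Slo + (Shi - Slo) * (y - Flo) / (Fhi - Flo + 1e-300);
    for (int it = 0; it < 6; ++it) {
      double fs = f(S);
      if (std::fabs(fs - y) < 1e-14) break;
      if (fs < y) { Slo = S; } else { Shi = S; }
      double d = df(S);
      double Sn = (d > 0.0) ? S - (fs - y) / d : 0.5 * (Slo + Shi);
      if (Sn <= Slo || Sn >= Shi) Sn = 0.5 * (Slo + Shi);
      S = Sn;
    }
    return S;
  }
};

struct Bed {
  double q_base, q_floor, q_shape, p_base, p_drop;
  double qb(double V) const {
    V = std::min(std::max(V, 0.0), 1.0);
    return q_base * (q_floor + (1.0 - q_floor) * std::pow(V, q_shape));
  }
  double p2(double V) const {
    V = std::min(std::max(V, 0.0), 1.0);
    return p_base - p_drop * (1.0 - V);
  }
};

struct Control {
  double gamma, theta1, theta2, eps, Qstart, D;
  double qe(double s) const {
    double E = 0.0;
    if (theta1 > THETA_SWITCH) {
      if (s <= theta1) E = s / theta1;
      if (s >= theta1 && s <= D - eps) E = 1.0;
    } else {
      if (s > 0.0 && s <= D - eps) E = 1.0;
    }
    if (s > D - eps) E = (D - s) / eps;
    E = std::min(std::max(E, 0.0), 1.0);
    return gamma * Qstart * E;
  }
};

inline double clamp01(double x) { return std::min(std::max(x, 0.0), 1.0); }

} // namespace

// [[Rcpp::export(name = ".cabaret_stage_cpp")]]
List cabaret_stage_cpp(int J, double h, double L,
                       NumericVector m_nodes, NumericVector m_half,
                       NumericVector Ai_nodes, NumericVector Ai_half,
                       NumericVector A1_nodes, NumericVector A1_half,
                       double alpha_b, double alpha_e,
                       double eta_b, double eta_e, double K,
                       double q_base, double q_floor, double q_shape,
                       double p_base, double p_drop,
                       double gamma, double theta1, double theta2,
                       double eps, double Qstart,
                       double df_max, double r, int max_steps, bool record) {
  Flux fx{alpha_b, alpha_e, eta_b, eta_e};
  fx.build_table();
  Bed bed{q_base, q_floor, q_shape, p_base, p_drop};
  Control ctl{gamma, theta1, theta2, eps, Qstart, theta1 + theta2 + eps};
  const double D = ctl.D;

  std::vector<double> bps;
  for (double b : {theta1, D - eps, D})
    if (b > 0.0 && b <= D) bps.push_back(b);
  std::sort(bps.begin(), bps.end());
  bps.erase(std::unique(bps.begin(), bps.end()), bps.end());

  std::vector<double> u(J + 1, 1.0), U(J, 1.0);
  std::vector<double> Uh(J), flux(J), sflux(J), U1(J), u1(J + 1);
  std::vector<double> fu(J + 1), fU(J);
  std::vector<double> trace;  // 7 columns per row
  trace.reserve(record ? 7 * 1024 : 7);

  const double Ai0 = std::max(Ai_nodes[0], CFL_A_FRAC * A1_nodes[0]);
  const double inlet_coef = (gamma > 0.0)
    ? df_max / (m_nodes[0] * Ai0) : 0.0;

  double t = 0.0, max_p1 = -1e300, min_out = 1e300;
  int n = 0;

  auto vbar_of = [&](const std::vector<double>& W) {
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += W[j] * Ai_half[j] / A1_half[j];
    return (h / L) * s;
  };
  auto push_row = [&](double t0, double tau, double Q, double p1, double Vb) {
    double tv = 0.0;
    for (int j = 0; j < J; ++j) tv += std::fabs(u[j + 1] - u[j]);
    trace.push_back(t0); trace.push_back(tau); trace.push_back(Q);
    trace.push_back(p1); trace.push_back(Vb); trace.push_back(u[J]);
    trace.push_back(tv);
  };

  for (;;) {
    double Vbar = vbar_of(U);
    double Q = ctl.qe(t) + bed.qb(Vbar);
    if (!(Q > 0.0)) stop("mixture flow must stay positive");
    // inlet pressure (midpoint Darcy quadrature, converted to mmHg)
    double darcy = 0.0;
    for (int j = 0; j < J; ++j) {
      double V = U[j] * Ai_half[j] / A1_half[j];
      double Vf = std::max(V, S_RATIO_FLOOR);
      darcy += fx.f(Vf) / std::pow(Vf, alpha_b) * h / A1_half[j];
    }
    double p1 = bed.p2(Vbar) + Q * eta_b / K * darcy / DYN_PER_MMHG;
    if (p1 > max_p1) max_p1 = p1;
    if (u[J] < min_out) min_out = u[J];
    bool done = (t >= D - 1e-12);
    if (record || done)
      push_row(t, done ? NA_REAL : 0.0, Q, p1, Vbar);
    if (done) break;

    // CFL step with inlet-wave speed and breakpoint clipping
    double amax = Q * inlet_coef;
    for (int j = 0; j < J; ++j) {
      double Ai_eff = std::max(Ai_half[j], CFL_A_FRAC * A1_half[j]);
      double a = Q * fx.df(U[j]) / (m_half[j] * Ai_eff);
      if (a > amax) amax = a;
    }
    double tau = (amax > 0.0) ? r * h / amax : 1e300;
    tau = std::max(tau, D / 200000.0);    // per-stage resolution budget
    for (double b : bps)
      if (b > t + 1e-12) { tau = std::min(tau, b - t); break; }
    if (!(tau > 0.0) || tau > 1e200)
      stop("maximum characteristic speed is zero and no breakpoint lies ahead");
    if (record) trace[trace.size() - 6] = tau;

    for (int j = 0; j <= J; ++j) fu[j] = fx.f(u[j]);
    for (int j = 0; j < J; ++j) fU[j] = fx.f(U[j]);

    // half-time predictor for the conservative variables
    for (int j = 0; j < J; ++j)
      Uh[j] = U[j] - 0.5 * tau * Q / (m_half[j] * Ai_half[j]) *
              (fu[j + 1] - fu[j]) / h;
    double Vbar_h = vbar_of(Uh);
    double qe_n = ctl.qe(t);
    double f0_h = bed.qb(Vbar_h) / (qe_n + bed.qb(Vbar_h));

    // interior fluxes: extrapolate, two-sided limit, monotonicity cap;
    // the S-space preimage of each flux is tracked to avoid inversions
    double rn = tau / h;
    for (int j = 0; j < J; ++j) {           // flux node j+1
      double ubar = 2.0 * Uh[j] - u[j];
      double mid = clamp01(0.5 * (u[j + 1] + ubar));
      double fb = fx.f(mid);
      double s = mid;
      double lo, hi, slo, shi;
      if (fU[j] <= fu[j + 1]) { lo = fU[j]; slo = U[j]; hi = fu[j + 1]; shi = u[j + 1]; }
      else                    { lo = fu[j + 1]; slo = u[j + 1]; hi = fU[j]; shi = U[j]; }
      if (fb <= lo) { fb = lo; s = slo; }
      else if (fb >= hi) { fb = hi; s = shi; }
      if (j >= 1) {                         // four-point monotone stencil
        double a1 = fU[j - 1], a2 = fu[j], a3 = fU[j], a4 = fu[j + 1];
        bool nondec = (a1 <= a2 && a2 <= a3 && a3 <= a4);
        bool noninc = (!nondec && a1 >= a2 && a2 >= a3 && a3 >= a4);
        if (nondec || noninc) {
          double phi = Ai_nodes[j] * m_nodes[j] * (U[j] - u[j]) / (rn * Q);
          double cap = a2 + phi;
          if (nondec && fb > cap) { fb = cap; s = fx.finv(clamp01(cap)); }
          else if (noninc && fb < cap) { fb = cap; s = fx.finv(clamp01(cap)); }
        }
      }
      flux[j] = fb;
      sflux[j] = s;
    }

    double Q_h = ctl.qe(t + 0.5 * tau) + bed.qb(Vbar_h);

    // full conservative update
    for (int j = 0; j < J; ++j) {
      double fl = (j == 0) ? f0_h : flux[j - 1];
      U1[j] = clamp01(U[j] - tau * Q_h / (m_half[j] * Ai_half[j]) *
                      (flux[j] - fl) / h);
    }
    double Vbar_1 = vbar_of(U1);
    double f0_1 = bed.qb(Vbar_1) / (qe_n + bed.qb(Vbar_1));

    // flux-variable update with two-sided limiting by the new cells
    u1[0] = fx.finv(f0_1);
    for (int j = 1; j <= J; ++j) {
      double util = 2.0 * sflux[j - 1] - u[j];
      double lo, hi;
      if (j < J) {
        lo = std::min(U1[j - 1], U1[j]); hi = std::max(U1[j - 1], U1[j]);
      } else {
        lo = std::min(U1[J - 1], u[J]); hi = std::max(U1[J - 1], u[J]);
      }
      u1[j] = clamp01(std::min(std::max(util, lo), hi));
    }

    u.assign(u1.begin(), u1.end());
    U.assign(U1.begin(), U1.end());
    t += tau;
    if (++n > max_steps) stop("step cap exceeded; runaway time step");
  }

  int nrow = trace.size() / 7;
  NumericMatrix tr(nrow, 7);
  for (int i = 0; i < nrow; ++i)
    for (int c = 0; c < 7; ++c) tr(i, c) = trace[7 * i + c];
  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["U"] = NumericVector(U.begin(), U.end()),
                      _["trace"] = tr, _["steps"] = n,
                      _["max_p1"] = max_p1, _["min_S_outlet"] = min_out);
}
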