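#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Moving-mesh explicit-Euler core.  Mirrors the pure-R reference step in
// R/solver.R (euler_step + regrid + diagnostics); the two are
// cross-checked in the test suite.

namespace {

struct Pars {
  double delta_D, delta_T, delta_C, delta_I12, delta_Ta, delta_A, delta_B;
  double sigma0, eta, mu_PA, mu_TaB;
  double rho_P, rho_L, rho_M, rho_G, eps_C, alpha_L, alpha_T, alpha_MA;
  double lambda_DC_D0, lambda_TI12_T0, lambda_C, lambda_I12D, lambda_TaT;
  double A_Ta, d_D, d_T, d_C, d_I12, d_Ta, d_A, d_B;
  double K_D, K_T, K_C, K_I12, K_Ta, K_A, K_TQ1, K_TQ2;
  double C_M, T_hat, rho_tot;
};

Pars read_pars(const List& par, double lambda_C) {
  Pars p;
  p.delta_D = par["delta_D"]; p.delta_T = par["delta_T"];
  p.delta_C = par["delta_C"]; p.delta_I12 = par["delta_I12"];
  p.delta_Ta = par["delta_Ta"]; p.delta_A = par["delta_A"];
  p.delta_B = par["delta_B"];
  p.sigma0 = par["sigma0"]; p.eta = par["eta"];
  p.mu_PA = par["mu_PA"]; p.mu_TaB = par["mu_TaB"];
  p.rho_P = par["rho_P"]; p.rho_L = par["rho_L"]; p.rho_M = par["rho_M"];
  p.rho_G = par["rho_G"]; p.eps_C = par["eps_C"];
  p.alpha_L = par["alpha_L"]; p.alpha_T = par["alpha_T"];
  p.alpha_MA = par["alpha_MA"];
  p.lambda_DC_D0 = par["lambda_DC_D0"];
  p.lambda_TI12_T0 = par["lambda_TI12_T0"];
  p.lambda_C = lambda_C;
  p.lambda_I12D = par["lambda_I12D"]; p.lambda_TaT = par["lambda_TaT"];
  p.A_Ta = par["A_Ta"];
  p.d_D = par["d_D"]; p.d_T = par["d_T"]; p.d_C = par["d_C"];
  p.d_I12 = par["d_I12"]; p.d_Ta = par["d_Ta"];
  p.d_A = par["d_A"]; p.d_B = par["d_B"];
  p.K_D = par["K_D"]; p.K_T = par["K_T"]; p.K_C = par["K_C"];
  p.K_I12 = par["K_I12"]; p.K_Ta = par["K_Ta"]; p.K_A = par["K_A"];
  p.K_TQ1 = par["K_TQ1"]; p.K_TQ2 = par["K_TQ2"];
  p.C_M = par["C_M"]; p.T_hat = par["T_hat"];
  p.rho_tot = par["rho_tot"];
  return p;
}

typedef std::vector<double> vec;

// pulse-decay dose rate: events with day < t contribute
double dose_at(double t, const vec& days, const vec& gam, double beta) {
  double s = 0.0;
  for (size_t i = 0; i < days.size(); ++i)
    if (days[i] < t) s += gam[i] * std::exp(-beta * (t - days[i]));
  return s;
}

// printed nonuniform three-point formulas (h1 > 0 > hm1)
inline void fd3(double xm, double xc, double xp, double h1, double hm1,
                double& Xr, double& Xrr) {
  Xr = (hm1 * hm1 * xp - h1 * h1 * xm + (h1 * h1 - hm1 * hm1) * xc) /
       (h1 * (hm1 * hm1 - h1 * hm1));
  Xrr = 2.0 * (hm1 * xp - h1 * xm + (h1 - hm1) * xc) /
        (h1 * (h1 * hm1 - hm1 * hm1));
}

// radial Laplacian d2/dr2 + (2/r) d/dr; symmetry limit at r = 0
void radial_laplacian(const vec& x, const vec& r, vec& lap) {
  const int n = (int)r.size();
  double h1 = r[1] - r[0];
  lap[0] = 6.0 * (x[1] - x[0]) / (h1 * h1);
  for (int i = 1; i < n - 1; ++i) {
    double Xr, Xrr;
    fd3(x[i - 1], x[i], x[i + 1], r[i + 1] - r[i], r[i - 1] - r[i], Xr,
        Xrr);
    lap[i] = Xrr + 2.0 / r[i] * Xr;
  }
  lap[n - 1] = 0.0;
}

// cumulative integral of S(s) s^2 (S piecewise linear), then u = I / r^2
void velocity(const vec& S, const vec& r, vec& u) {
  const int n = (int)r.size();
  double I = 0.0;
  u[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    double a = r[i - 1], b = r[i], h = b - a;
    double c3 = (b * b * b - a * a * a) / 3.0;
    double c4 = (b * b * b * b - a * a * a * a) / 4.0;
    I += S[i - 1] * c3 + (S[i] - S[i - 1]) / h * (c4 - a * c3);
    u[i] = I / (r[i] * r[i]);
  }
}

double vol_average(const vec& x, const vec& r) {
  const int n = (int)r.size();
  double I = 0.0;
  for (int i = 1; i < n; ++i) {
    double a = r[i - 1], b = r[i], h = b - a;
    double c3 = (b * b * b - a * a * a) / 3.0;
    double c4 = (b * b * b * b - a * a * a * a) / 4.0;
    I += x[i - 1] * c3 + (x[i] - x[i - 1]) / h * (c4 - a * c3);
  }
  double R = r[n - 1];
  return 3.0 * I / (R * R * R);
}

// linear interpolation with constant extrapolation (approx rule = 2)
void interp_to(const vec& r_old, const vec& x, const vec& r_new,
               vec& out) {
  const int n = (int)r_old.size();
  int j = 0;
  for (int i = 0; i < (int)r_new.size(); ++i) {
    double q = r_new[i];
    if (q <= r_old[0]) { out[i] = x[0]; continue; }
    if (q >= r_old[n - 1]) { out[i] = x[n - 1]; continue; }
    while (j < n - 2 && r_old[j + 1] < q) ++j;
    while (j > 0 && r_old[j] > q) --j;
    double w = (q - r_old[j]) / (r_old[j + 1] - r_old[j]);
    out[i] = (1.0 - w) * x[j] + w * x[j + 1];
  }
}

struct State {
  vec r;
  vec D, T, C, I12, Ta, P, A, B;
};

void apply_bcs(State& s, const Pars& p) {
  const int n = (int)s.r.size();
  double h = s.r[n - 1] - s.r[n - 2];
  s.D[n - 1] = s.D[n - 2];
  s.I12[n - 1] = s.I12[n - 2];
  s.Ta[n - 1] = s.Ta[n - 2];
  s.A[n - 1] = s.A[n - 2];
  s.B[n - 1] = s.B[n - 2];
  double sigT = p.sigma0 * s.I12[n - 1] / (p.K_I12 + s.I12[n - 1]);
  s.T[n - 1] = (s.T[n - 2] + h * sigT * p.T_hat) / (1.0 + h * sigT);
  s.P[n - 1] = (s.P[n - 2] + h * sigT * p.rho_P * p.T_hat) /
               (1.0 + h * sigT);
  s.C[n - 1] = p.rho_tot - s.D[n - 1] - s.T[n - 1];
}

long clip_negatives(State& s) {
  long clips = 0;
  vec* fs[8] = {&s.D, &s.T, &s.C, &s.I12, &s.Ta, &s.P, &s.A, &s.B};
  for (int k = 0; k < 8; ++k)
    for (size_t i = 0; i < fs[k]->size(); ++i)
      if ((*fs[k])[i] < 0.0) { (*fs[k])[i] = 0.0; ++clips; }
  return clips;
}

// one explicit Euler step; returns number of clipped values
long step(State& s, const Pars& p, double tau, double gA, double gB,
          double eps_T) {
  const int n = (int)s.r.size();
  vec L(n), TM(n), fQ1(n), fQ2(n);
  vec FD(n), FT(n), FC(n), FI(n), FTa(n), FP(n), FA(n), FB(n), S(n),
      u(n), lap(n);

  for (int i = 0; i < n; ++i) {
    double satTa = s.Ta[i] / (p.K_Ta + s.Ta[i]);
    L[i] = p.rho_L * (s.T[i] + p.eps_C * s.C[i]) *
           (1.0 + p.alpha_L * satTa);
    TM[i] = p.rho_M * s.T[i] *
            (1.0 + p.alpha_T * satTa *
                       (1.0 + p.alpha_MA * s.A[i] / (p.K_A + s.A[i])));
    double G = p.rho_G * s.C[i];
    fQ1[i] = 1.0 / (1.0 + s.P[i] * L[i] / p.K_TQ1);
    fQ2[i] = 1.0 / (1.0 + TM[i] * G / p.K_TQ2);

    double act_T = p.lambda_TI12_T0 * s.I12[i] / (p.K_I12 + s.I12[i]) *
                   fQ1[i] * fQ2[i];
    FD[i] = p.lambda_DC_D0 * s.C[i] / (p.K_C + s.C[i]) - p.d_D * s.D[i];
    FT[i] = act_T - p.d_T * s.T[i];
    FC[i] = p.lambda_C * s.C[i] * (1.0 - s.C[i] / p.C_M) -
            p.eta * s.T[i] * s.C[i] - p.d_C * s.C[i];
    FI[i] = p.lambda_I12D * s.D[i] - p.d_I12 * s.I12[i];
    FTa[i] = p.A_Ta + p.lambda_TaT * s.T[i] -
             p.mu_TaB * s.Ta[i] * s.B[i] - p.d_Ta * s.Ta[i];
    double Tg = s.T[i] > eps_T ? s.T[i] : eps_T;
    FP[i] = s.P[i] / Tg * FT[i] - p.mu_PA * s.P[i] * s.A[i];
    FA[i] = gA - p.mu_PA * s.P[i] * s.A[i] - p.d_A * s.A[i];
    FB[i] = gB - p.mu_TaB * s.Ta[i] * s.B[i] - p.d_B * s.B[i];
    S[i] = (FD[i] + FT[i] + FC[i]) / p.rho_tot;
  }
  velocity(S, s.r, u);

  vec r_new(n);
  for (int i = 0; i < n; ++i) r_new[i] = s.r[i] + u[i] * tau;

  // cell fields: Lagrangian update (advection absorbed by node motion)
  struct CellF { vec* x; vec* F; double delta; };
  CellF cells[4] = {{&s.D, &FD, p.delta_D}, {&s.T, &FT, p.delta_T},
                    {&s.C, &FC, p.delta_C}, {&s.P, &FP, p.delta_T}};
  for (int k = 0; k < 4; ++k) {
    vec& x = *cells[k].x;
    radial_laplacian(x, s.r, lap);
    for (int i = 0; i < n - 1; ++i)
      x[i] += tau * (cells[k].delta * lap[i] + (*cells[k].F)[i] -
                     x[i] * S[i]);
  }
  // cytokines/drugs: Eulerian update, then re-interpolated to moved mesh
  struct CytF { vec* x; vec* F; double delta; };
  CytF cyt[4] = {{&s.I12, &FI, p.delta_I12}, {&s.Ta, &FTa, p.delta_Ta},
                 {&s.A, &FA, p.delta_A}, {&s.B, &FB, p.delta_B}};
  vec tmp(n);
  for (int k = 0; k < 4; ++k) {
    vec& x = *cyt[k].x;
    radial_laplacian(x, s.r, lap);
    for (int i = 0; i < n - 1; ++i)
      tmp[i] = x[i] + tau * (cyt[k].delta * lap[i] + (*cyt[k].F)[i]);
    tmp[n - 1] = tmp[n - 2];  // Neumann on the old mesh
    interp_to(s.r, tmp, r_new, x);
  }
  s.r = r_new;
  apply_bcs(s, p);
  return clip_negatives(s);
}

void do_regrid_uniform(State& s, int N) {
  const int n = (int)s.r.size();
  double R = s.r[n - 1];
  vec r_new(N + 1);
  for (int i = 0; i <= N; ++i) r_new[i] = R * i / (double)N;
  r_new[0] = 0.0;
  vec* fs[8] = {&s.D, &s.T, &s.C, &s.I12, &s.Ta, &s.P, &s.A, &s.B};
  vec tmp(N + 1);
  for (int k = 0; k < 8; ++k) {
    interp_to(s.r, *fs[k], r_new, tmp);
    *fs[k] = tmp;
  }
  s.r = r_new;
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(NumericVector r, NumericVector D, NumericVector Tc,
                  NumericVector C, NumericVector I12, NumericVector Ta,
                  NumericVector P, NumericVector A, NumericVector B,
                  List par, double lambda_C, NumericVector daysA,
                  NumericVector gammaA, NumericVector daysB,
                  NumericVector gammaB, double beta,
                  NumericVector out_times, int N, double safety,
                  double regrid_ratio, double regrid_growth,
                  double cons_tol, double r_min, double eps_T,
                  double fixed_tau, double max_steps, bool do_regrid) {
  Pars p = read_pars(par, lambda_C);
  State s;
  s.r = as<vec>(r);
  s.D = as<vec>(D); s.T = as<vec>(Tc); s.C = as<vec>(C);
  s.I12 = as<vec>(I12); s.Ta = as<vec>(Ta); s.P = as<vec>(P);
  s.A = as<vec>(A); s.B = as<vec>(B);
  vec dA = as<vec>(daysA), gA = as<vec>(gammaA);
  vec dB = as<vec>(daysB), gB = as<vec>(gammaB);
  vec outs = as<vec>(out_times);

  const double Dmax =
      std::max({p.delta_D, p.delta_T, p.delta_C, p.delta_I12, p.delta_Ta,
                p.delta_A, p.delta_B});
  const int nout = (int)outs.size();
  NumericMatrix avg(nout, 8);
  NumericVector Rout(nout), consdev(nout);
  long clips = 0, n_steps = 0, n_regrids = 0;
  bool collapsed = false;

  double t = 0.0;
  int iout = 0;
  double R_ref = s.r.back();

  auto record = [&](int k) {
    const int n = (int)s.r.size();
    vec* fs[8] = {&s.D, &s.T, &s.C, &s.I12, &s.Ta, &s.P, &s.A, &s.B};
    for (int f = 0; f < 8; ++f) {
      double a = vol_average(*fs[f], s.r);
      if (!std::isfinite(a))
        stop("simulation aborted: non-finite field average at t = %f", t);
      avg(k, f) = a;
    }
    Rout[k] = s.r[n - 1];
    double dev = 0.0;
    for (int i = 0; i < n; ++i)
      dev = std::max(dev,
                     std::fabs(s.D[i] + s.T[i] + s.C[i] - p.rho_tot));
    consdev[k] = dev;
    if (dev > cons_tol * p.rho_tot)
      stop("simulation aborted: conservation violation %g at t = %f", dev,
           t);
  };

  // output times are assumed sorted, starting at 0
  if (std::fabs(outs[0] - t) < 1e-12) { record(0); iout = 1; }
  const double t_end = outs[nout - 1];

  while (t < t_end - 1e-12) {
    // time step: diffusion bound, reaction-rate cap, land on next output
    double tau;
    if (fixed_tau > 0.0) {
      tau = fixed_tau;
    } else {
      double hmin = 1e300;
      for (size_t i = 1; i < s.r.size(); ++i)
        hmin = std::min(hmin, s.r[i] - s.r[i - 1]);
      if (hmin <= 0.0) stop("degenerate mesh at t = %f", t);
      tau = safety * hmin * hmin / (2.0 * Dmax);
      double Bmax = 0.0, Tamax = 0.0, Pmax = 0.0;
      for (size_t i = 0; i < s.B.size(); ++i) {
        Bmax = std::max(Bmax, s.B[i]);
        Tamax = std::max(Tamax, s.Ta[i]);
        Pmax = std::max(Pmax, s.P[i]);
      }
      double rmax = std::max(
          {p.d_Ta + p.mu_TaB * Bmax, p.d_B + p.mu_TaB * Tamax,
           p.d_A + p.mu_PA * Pmax, p.d_I12, p.d_T, p.d_D, p.d_C,
           p.lambda_C});
      tau = std::min(tau, safety / rmax);
      if (iout < nout) tau = std::min(tau, outs[iout] - t);
    }

    double dra = dose_at(t, dA, gA, beta);
    double drb = dose_at(t, dB, gB, beta);
    clips += step(s, p, tau, dra, drb, eps_T);
    t += tau;
    ++n_steps;
    if (!std::isfinite(s.r.back()))
      stop("simulation aborted: non-finite boundary radius at t = %f", t);

    if (do_regrid) {
      double hmin = 1e300, hmax = 0.0;
      for (size_t i = 1; i < s.r.size(); ++i) {
        double h = s.r[i] - s.r[i - 1];
        hmin = std::min(hmin, h);
        hmax = std::max(hmax, h);
      }
      if (hmin <= 0.0 || hmax / hmin > regrid_ratio ||
          std::fabs(s.r.back() - R_ref) > regrid_growth * R_ref) {
        do_regrid_uniform(s, N);
        R_ref = s.r.back();
        ++n_regrids;
      }
    }

    while (iout < nout && t >= outs[iout] - 1e-9) {
      record(iout);
      ++iout;
    }

    if (s.r.back() < r_min) {  // tumor effectively eliminated
      collapsed = true;
      while (iout < nout) { record(iout); ++iout; }
      break;
    }
    if (max_steps > 0 && n_steps >= (long)max_steps) break;
    if (n_steps % 100000 == 0) checkUserInterrupt();
  }

  return List::create(
      _["avg"] = avg, _["R"] = Rout, _["consdev"] = consdev,
      _["clips"] = (double)clips, _["n_steps"] = (double)n_steps,
      _["n_regrids"] = (double)n_regrids, _["collapsed"] = collapsed,
      _["t"] = t, _["r_final"] = wrap(s.r),
      _["fields_final"] = List::create(wrap(s.D), wrap(s.T), wrap(s.C),
                                       wrap(s.I12), wrap(s.Ta), wrap(s.P),
                                       wrap(s.A), wrap(s.B)));
}
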