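#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Generalized Hodgkin-Huxley rate family. Each forward/backward rate is one of
//   type 0 (linoid):      A * (v - Vh) / (1 - exp(-(v - Vh)/k))
//   type 1 (exponential): A * exp((v - Vh)/k)
//   type 2 (sigmoid):     A / (1 + exp(-(v - Vh)/k))
// with v in mV and rates in 1/ms.

struct Scheme {
  double rt[6][4];   // rows: alpha_m, beta_m, alpha_h, beta_h, alpha_n, beta_n
  double phi;        // global rate multiplier (temperature-like scaling)
  double vshift;     // global voltage shift applied to all rate evaluations
  double kin_vhalf, kin_slope, kin_tau; // K+ slow-inactivation gate
};

static inline double rate_eval(const double* p, double v) {
  const double A = p[1], Vh = p[2], k = p[3];
  const double x = (v - Vh) / k;
  if (p[0] < 0.5) {                       // linoid; series limit near v == Vh
    if (std::fabs(x) < 1e-7) return A * k * (1.0 + 0.5 * x);
    return A * (v - Vh) / (1.0 - std::exp(-x));
  } else if (p[0] < 1.5) {                // exponential
    return A * std::exp(x);
  }
  return A / (1.0 + std::exp(-x));        // sigmoid
}

static Scheme unpack_scheme(const List& s) {
  Scheme sc;
  NumericMatrix r = s["rates"];
  if (r.nrow() != 6 || r.ncol() != 4)
    stop("gating scheme 'rates' must be a 6 x 4 matrix");
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 4; ++j) sc.rt[i][j] = r(i, j);
  sc.phi = as<double>(s["phi"]);
  sc.vshift = as<double>(s["vshift"]);
  NumericVector kp = s["kinact"];
  sc.kin_vhalf = kp[0];
  sc.kin_slope = kp[1];
  sc.kin_tau = kp[2];
  return sc;
}

static inline void rates_at(const Scheme& sc, double v, double* a, double* b) {
  const double u = v - sc.vshift;
  for (int g = 0; g < 3; ++g) {
    a[g] = sc.phi * rate_eval(sc.rt[2 * g], u);
    b[g] = sc.phi * rate_eval(sc.rt[2 * g + 1], u);
  }
}

static inline double kinf_at(const Scheme& sc, double v) {
  return 1.0 / (1.0 + std::exp((v - sc.kin_vhalf) / sc.kin_slope));
}

// [[Rcpp::export]]
List gating_rates_cpp(NumericVector v, List scheme) {
  Scheme sc = unpack_scheme(scheme);
  const int n = v.size();
  NumericMatrix alpha(n, 3), beta(n, 3);
  NumericVector kinf(n);
  for (int i = 0; i < n; ++i) {
    double a[3], b[3];
    rates_at(sc, v[i], a, b);
    for (int g = 0; g < 3; ++g) { alpha(i, g) = a[g]; beta(i, g) = b[g]; }
    kinf[i] = kinf_at(sc, v[i]);
  }
  colnames(alpha) = CharacterVector::create("m", "h", "n");
  colnames(beta) = CharacterVector::create("m", "h", "n");
  return List::create(_["alpha"] = alpha, _["beta"] = beta,
                      _["kinf"] = kinf, _["ktau"] = sc.kin_tau);
}

// Implicit integration of the compartmental cable equation on an unbranched
// chain. Units: mV, ms, uF, mS (so conductance * voltage = uA and
// capacitance * mV / ms = uA); stimulus amplitudes arrive in nA and recorded
// currents are returned in nA. Sign convention: outward membrane current
// positive, so at every recorded instant
//   I_cap + I_Na + I_K + I_leak + I_axial_net - I_stim = 0.
//
// method: 0 = backward Euler, 1 = Crank-Nicolson. Gates are advanced with the
// exact exponential update at the start-of-step voltage (operator splitting).
// For Crank-Nicolson the ionic and axial currents are recorded at the
// mid-step voltage so the conservation identity holds exactly for the scheme.
// [[Rcpp::export]]
List integrate_cpp(NumericVector v0, NumericVector cap,
                   NumericVector gna, NumericVector gk, NumericVector gl,
                   NumericVector ena, NumericVector ek, NumericVector el,
                   NumericVector gax,
                   double dt, int nsteps, int method,
                   IntegerVector rec, int record_every,
                   bool record_currents, bool record_gates,
                   IntegerVector stim_site, NumericVector stim_amp,
                   NumericVector stim_onset, NumericVector stim_dur,
                   List scheme, bool use_kinact, double baseline_t) {
  const int n = v0.size();
  if (gax.size() != n - 1) stop("gax must have length n - 1");
  if (dt <= 0.0) stop("dt must be positive");
  Scheme sc = unpack_scheme(scheme);

  std::vector<double> v(v0.begin(), v0.end()), vold(n);
  std::vector<double> m(n), h(n), nn(n), kin(n);
  for (int i = 0; i < n; ++i) {
    double a[3], b[3];
    rates_at(sc, v[i], a, b);
    m[i] = a[0] / (a[0] + b[0]);
    h[i] = a[1] / (a[1] + b[1]);
    nn[i] = a[2] / (a[2] + b[2]);
    kin[i] = use_kinact ? kinf_at(sc, v[i]) : 1.0;
  }

  const int nrec = rec.size();
  const int nt = nsteps / record_every + 1;
  NumericVector time(nt);
  NumericMatrix vm(nt, nrec);
  NumericMatrix ina, ik, il, icap, iax, ist, gm, gh, gn, gkin;
  if (record_currents) {
    ina = NumericMatrix(nt, nrec); ik = NumericMatrix(nt, nrec);
    il = NumericMatrix(nt, nrec);  icap = NumericMatrix(nt, nrec);
    iax = NumericMatrix(nt, nrec); ist = NumericMatrix(nt, nrec);
  }
  if (record_gates) {
    gm = NumericMatrix(nt, nrec); gh = NumericMatrix(nt, nrec);
    gn = NumericMatrix(nt, nrec); gkin = NumericMatrix(nt, nrec);
  }

  NumericVector vmax(n, R_NegInf), tmax(n, NA_REAL), vbase(n), vfinal(n);
  const int baseline_step = (int)std::llround(baseline_t / dt);

  std::vector<double> gna_eff(n), gk_eff(n), istim(n);
  std::vector<double> diag(n), rhs(n), cw(n), dw(n), off(n - 1);

  // axial current (outward-positive, nA) at voltage vector u
  auto axial_at = [&](const std::vector<double>& u, int i) {
    double s = 0.0;
    if (i > 0) s += gax[i - 1] * (u[i] - u[i - 1]);
    if (i < n - 1) s += gax[i] * (u[i] - u[i + 1]);
    return s;
  };

  auto record_row = [&](int row, double t) {
    time[row] = t;
    for (int r = 0; r < nrec; ++r) {
      const int i = rec[r];
      vm(row, r) = v[i];
      if (record_gates) {
        gm(row, r) = m[i]; gh(row, r) = h[i];
        gn(row, r) = nn[i]; gkin(row, r) = kin[i];
      }
    }
  };

  // row 0: voltages and ionic currents at the initial condition; the
  // capacitive current at t = 0 is taken from the governing equation.
  record_row(0, 0.0);
  if (record_currents) {
    for (int r = 0; r < nrec; ++r) {
      const int i = rec[r];
      const double gna_i = gna[i] * m[i] * m[i] * m[i] * h[i];
      const double gk_i = gk[i] * nn[i] * nn[i] * nn[i] * nn[i] * kin[i];
      ina(0, r) = 1000.0 * gna_i * (v[i] - ena[i]);
      ik(0, r) = 1000.0 * gk_i * (v[i] - ek[i]);
      il(0, r) = 1000.0 * gl[i] * (v[i] - el[i]);
      iax(0, r) = 1000.0 * axial_at(v, i);
      ist(0, r) = 0.0;
      icap(0, r) = -(ina(0, r) + ik(0, r) + il(0, r) + iax(0, r));
    }
  }
  if (baseline_step <= 0)
    for (int i = 0; i < n; ++i) { vbase[i] = v[i]; vmax[i] = v[i]; tmax[i] = 0.0; }

  const double half = (method == 1) ? 0.5 : 1.0;
  for (int i = 0; i < n - 1; ++i) off[i] = -half * gax[i];

  for (int s = 1; s <= nsteps; ++s) {
    const double t1 = s * dt;
    const double tmid = t1 - 0.5 * dt;

    // stimulus (nA -> uA), evaluated at mid-step time
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int e = 0; e < stim_site.size(); ++e)
      if (tmid >= stim_onset[e] && tmid < stim_onset[e] + stim_dur[e])
        istim[stim_site[e]] += stim_amp[e] * 1e-3;

    // gating: exact exponential relaxation at the start-of-step voltage
    for (int i = 0; i < n; ++i) {
      double a[3], b[3];
      rates_at(sc, v[i], a, b);
      double sab = a[0] + b[0];
      m[i] += (a[0] / sab - m[i]) * (1.0 - std::exp(-dt * sab));
      sab = a[1] + b[1];
      h[i] += (a[1] / sab - h[i]) * (1.0 - std::exp(-dt * sab));
      sab = a[2] + b[2];
      nn[i] += (a[2] / sab - nn[i]) * (1.0 - std::exp(-dt * sab));
      if (use_kinact)
        kin[i] += (kinf_at(sc, v[i]) - kin[i]) * (1.0 - std::exp(-dt / sc.kin_tau));
      gna_eff[i] = gna[i] * m[i] * m[i] * m[i] * h[i];
      gk_eff[i] = gk[i] * nn[i] * nn[i] * nn[i] * nn[i] * kin[i];
    }

    // assemble tridiagonal system
    for (int i = 0; i < n; ++i) {
      const double gsum = gna_eff[i] + gk_eff[i] + gl[i];
      const double esum = gna_eff[i] * ena[i] + gk_eff[i] * ek[i] + gl[i] * el[i];
      double gax_sum = 0.0;
      if (i > 0) gax_sum += gax[i - 1];
      if (i < n - 1) gax_sum += gax[i];
      const double cd = cap[i] / dt;
      diag[i] = cd + half * (gsum + gax_sum);
      if (method == 1) {
        // Crank-Nicolson: (C/dt + (G+A)/2) v' = (C/dt - (G+A)/2) v + b
        double av = 0.0;
        if (i > 0) av += gax[i - 1] * (v[i] - v[i - 1]);
        if (i < n - 1) av += gax[i] * (v[i] - v[i + 1]);
        rhs[i] = cd * v[i] - 0.5 * (gsum * v[i] + av) + esum + istim[i];
      } else {
        rhs[i] = cd * v[i] + esum + istim[i];
      }
    }

    // Thomas algorithm
    cw[0] = off.empty() ? 0.0 : off[0] / diag[0];
    dw[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      const double den = diag[i] - off[i - 1] * cw[i - 1];
      cw[i] = (i < n - 1) ? off[i] / den : 0.0;
      dw[i] = (rhs[i] - off[i - 1] * dw[i - 1]) / den;
    }
    vold = v;
    v[n - 1] = dw[n - 1];
    for (int i = n - 2; i >= 0; --i) v[i] = dw[i] - cw[i] * v[i + 1];

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(v[i]))
        return List::create(_["ok"] = false, _["err_segment"] = i + 1,
                            _["err_time"] = t1);
    }

    if (s == baseline_step)
      for (int i = 0; i < n; ++i) { vbase[i] = v[i]; vmax[i] = v[i]; tmax[i] = t1; }
    if (s >= baseline_step)
      for (int i = 0; i < n; ++i)
        if (v[i] > vmax[i]) { vmax[i] = v[i]; tmax[i] = t1; }

    if (s % record_every == 0) {
      const int row = s / record_every;
      record_row(row, t1);
      if (record_currents) {
        for (int r = 0; r < nrec; ++r) {
          const int i = rec[r];
          // backward Euler: currents at the end-of-step voltage;
          // Crank-Nicolson: at the mid-step (average) voltage
          const double ve = (method == 1) ? 0.5 * (v[i] + vold[i]) : v[i];
          ina(row, r) = 1000.0 * gna_eff[i] * (ve - ena[i]);
          ik(row, r) = 1000.0 * gk_eff[i] * (ve - ek[i]);
          il(row, r) = 1000.0 * gl[i] * (ve - el[i]);
          double ax = 0.0;
          if (i > 0) {
            const double va = (method == 1) ? 0.5 * (v[i - 1] + vold[i - 1]) : v[i - 1];
            ax += gax[i - 1] * (ve - va);
          }
          if (i < n - 1) {
            const double vb = (method == 1) ? 0.5 * (v[i + 1] + vold[i + 1]) : v[i + 1];
            ax += gax[i] * (ve - vb);
          }
          iax(row, r) = 1000.0 * ax;
          icap(row, r) = 1000.0 * cap[i] * (v[i] - vold[i]) / dt;
          ist(row, r) = 1000.0 * istim[i];
        }
      }
    }
  }

  for (int i = 0; i < n; ++i) vfinal[i] = v[i];

  List out = List::create(
      _["ok"] = true, _["time"] = time, _["vm"] = vm,
      _["vmax"] = vmax, _["tmax"] = tmax, _["vbase"] = vbase,
      _["vfinal"] = vfinal);
  if (record_currents) {
    out["i_na"] = ina; out["i_k"] = ik; out["i_leak"] = il;
    out["i_cap"] = icap; out["i_axial"] = iax; out["i_stim"] = ist;
  }
  if (record_gates) {
    out["gate_m"] = gm; out["gate_h"] = gh;
    out["gate_n"] = gn; out["gate_kinact"] = gkin;
  }
  return out;
}
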