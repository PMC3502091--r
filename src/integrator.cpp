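#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout: {f_i, f_a, f_vrg, f_mus, f_fat}, all vol% of 1 atm.
// Time unit: minutes.

struct Model {
  double vc, frc, lbg;
  double q[3];   // absolute tissue blood flows, L/min
  double vl[3];  // tissue capacities V_i * lambda_i, L
  double qp;     // total perfused flow, sum(q)
};

static inline double mixed_venous(const double *ft, const Model &m) {
  return (m.q[0] * ft[0] + m.q[1] * ft[1] + m.q[2] * ft[2]) / m.qp;
}

static inline void deriv(const double *s, double f_d, double fgf, double va,
                         const Model &m, double *ds) {
  double fv = mixed_venous(s + 2, m);
  ds[0] = (fgf * (f_d - s[0]) + va * (s[1] - s[0])) / m.vc;
  ds[1] = (va * (s[0] - s[1]) - m.lbg * m.qp * (s[1] - fv)) / m.frc;
  for (int i = 0; i < 3; ++i)
    ds[2 + i] = m.lbg * m.q[i] * (s[1] - s[2 + i]) / m.vl[i];
}

// One classical RK4 step with delivered pressure held at f_d.  The two
// accumulators (agent volume delivered by fresh gas, agent volume leaving
// the circuit with excess gas) are integrated with the same stage weights,
// so the discrete amount balance holds to rounding error.
static void rk4_fixed(double *s, double dt, double f_d, double fgf, double va,
                      const Model &m, double *e_in, double *e_out) {
  double k1[5], k2[5], k3[5], k4[5], tmp[5];
  deriv(s, f_d, fgf, va, m, k1);
  for (int i = 0; i < 5; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
  double fi2 = tmp[0];
  deriv(tmp, f_d, fgf, va, m, k2);
  for (int i = 0; i < 5; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
  double fi3 = tmp[0];
  deriv(tmp, f_d, fgf, va, m, k3);
  for (int i = 0; i < 5; ++i) tmp[i] = s[i] + dt * k3[i];
  double fi4 = tmp[0];
  deriv(tmp, f_d, fgf, va, m, k4);
  double fi1 = s[0];
  for (int i = 0; i < 5; ++i)
    s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  *e_in  += dt * fgf * f_d;
  *e_out += dt / 6.0 * fgf * (fi1 + 2.0 * fi2 + 2.0 * fi3 + fi4);
}

static inline void tissue_deriv(const double *ft, double fa, const Model &m,
                                double *dft) {
  for (int i = 0; i < 3; ++i)
    dft[i] = m.lbg * m.q[i] * (fa - ft[i]) / m.vl[i];
}

// Algebraic alveolar clamp: F_A is held at `target`; only the tissue ODEs
// are integrated.  F_I is the value required for a zero alveolar balance
// and F_D is back-computed from the circuit balance, bounded to
// [0, fd_max].  Returns the delivered pressure actually applied.
static double clamp_sync(double *s, double target, double fgf, double va,
                         double fd_max, const Model &m) {
  s[1] = target;
  double fv = mixed_venous(s + 2, m);
  s[0] = target + m.lbg * m.qp * (target - fv) / va;
  double dft[3];
  tissue_deriv(s + 2, target, m, dft);
  double dfv = (m.q[0] * dft[0] + m.q[1] * dft[1] + m.q[2] * dft[2]) / m.qp;
  double dfi = -m.lbg * m.qp / va * dfv;
  double f_d = s[0] + (m.vc * dfi - va * (target - s[0])) / fgf;
  if (f_d < 0.0) f_d = 0.0;
  if (f_d > fd_max) f_d = fd_max;
  return f_d;
}

static double rk4_clamped(double *s, double dt, double target, double fgf,
                          double va, double fd_max, const Model &m,
                          double *e_in, double *e_out) {
  double fi0 = s[0];
  double fd0 = clamp_sync(s, target, fgf, va, fd_max, m);
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  double *ft = s + 2;
  tissue_deriv(ft, target, m, k1);
  for (int i = 0; i < 3; ++i) tmp[i] = ft[i] + 0.5 * dt * k1[i];
  tissue_deriv(tmp, target, m, k2);
  for (int i = 0; i < 3; ++i) tmp[i] = ft[i] + 0.5 * dt * k2[i];
  tissue_deriv(tmp, target, m, k3);
  for (int i = 0; i < 3; ++i) tmp[i] = ft[i] + dt * k3[i];
  tissue_deriv(tmp, target, m, k4);
  for (int i = 0; i < 3; ++i)
    ft[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  double fd1 = clamp_sync(s, target, fgf, va, fd_max, m);
  *e_in  += dt * fgf * 0.5 * (fd0 + fd1);
  *e_out += dt * fgf * 0.5 * (fi0 + s[0]);
  return fd1;
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector init, DataFrame phases, List agent, List body,
                  double dt, int rep_every, double t0) {
  Model m;
  m.vc  = as<double>(body["v_circuit"]);
  m.frc = as<double>(body["frc"]);
  double qt = as<double>(body["q_total"]);
  double fr[3] = {as<double>(body["f_vrg"]), as<double>(body["f_mus"]),
                  as<double>(body["f_fat"])};
  double vol[3] = {as<double>(body["v_vrg"]), as<double>(body["v_mus"]),
                   as<double>(body["v_fat"])};
  double lam[3] = {as<double>(agent["lambda_vrg"]), as<double>(agent["lambda_mus"]),
                   as<double>(agent["lambda_fat"])};
  m.lbg = as<double>(agent["lambda_blood"]);
  m.qp = 0.0;
  for (int i = 0; i < 3; ++i) {
    m.q[i] = fr[i] * qt;
    m.vl[i] = vol[i] * lam[i];
    if (m.vl[i] <= 0.0) stop("tissue capacity V_i * lambda_i must be positive");
    m.qp += m.q[i];
  }
  if (m.vc <= 0.0 || m.frc <= 0.0) stop("circuit and alveolar volumes must be positive");
  if (m.qp <= 0.0) stop("perfused blood flow must be positive");

  NumericVector p_mode = phases["mode_i"], p_fd = phases["f_d"],
      p_fgf = phases["fgf"], p_va = phases["v_a"],
      p_target = phases["clamp_target"], p_fdmax = phases["fd_max"],
      p_endkind = phases["end_kind_i"], p_dur = phases["duration_min"],
      p_until = phases["until_min"], p_var = phases["end_var_i"],
      p_cmp = phases["end_cmp_i"], p_level = phases["end_level"],
      p_cap = phases["cap_min"];
  int np = p_mode.size();

  // Conservative upper bound on internal steps for allocation.
  double tmax_rel = 0.0;
  double tcur_bound = t0;
  for (int p = 0; p < np; ++p) {
    int k = (int)p_endkind[p];
    if (k == 0) { tmax_rel += p_dur[p]; tcur_bound += p_dur[p]; }
    else if (k == 1) {
      double d = p_until[p] - t0;  // loosest bound: phase could span from t0
      if (d > 0) tmax_rel += d;
      tcur_bound = p_until[p];
    } else { tmax_rel += p_cap[p]; tcur_bound += p_cap[p]; }
  }
  long max_steps = (long)std::llround(tmax_rel / dt) + np + 4;
  long max_rows = max_steps / rep_every + np + 8;

  NumericMatrix out(max_rows, 12);
  long row = 0;
  double s[5];
  for (int i = 0; i < 5; ++i) s[i] = init[i];
  double e_in = 0.0, e_out = 0.0;
  double t = t0;
  long gstep = 0;

  NumericVector ph_start(np), ph_end(np);
  IntegerVector ph_reason(np);  // 0 duration/until reached, 1 threshold met, 2 cap hit

  // record(): one row of the report grid
  #define RECORD(FD, FGF, VA) do {                                   \
    if (row >= max_rows) stop("internal: trace buffer overflow");    \
    out(row, 0) = t;  out(row, 1) = (FD); out(row, 2) = (FGF);       \
    out(row, 3) = (VA);                                              \
    for (int i = 0; i < 5; ++i) out(row, 4 + i) = s[i];              \
    out(row, 9) = mixed_venous(s + 2, m);                            \
    out(row, 10) = e_in; out(row, 11) = e_out;                       \
    ++row;                                                           \
  } while (0)

  bool recorded_last = false;
  for (int p = 0; p < np; ++p) {
    int mode = (int)p_mode[p];
    int ek = (int)p_endkind[p];
    double fgf = p_fgf[p], va = p_va[p];
    double f_d = p_fd[p];
    double target = p_target[p], fd_max = p_fdmax[p];
    ph_start[p] = t;
    if (mode == 1) {
      if (fgf <= 0.0) stop("alveolar clamp requires positive fresh gas flow");
      f_d = clamp_sync(s, target, fgf, va, fd_max, m);
    }
    if (p == 0 && gstep % rep_every == 0) RECORD(f_d, fgf, va);

    long nsteps;
    bool threshold_phase = (ek == 2);
    if (ek == 0) nsteps = std::llround(p_dur[p] / dt);
    else if (ek == 1) {
      nsteps = std::llround((p_until[p] - t) / dt);
      if (nsteps < 0) stop("phase 'until' time precedes current time");
    } else nsteps = std::llround(p_cap[p] / dt);

    int reason = threshold_phase ? 2 : 0;
    int evar = (int)p_var[p];
    double ecmp = p_cmp[p], elevel = p_level[p];
    for (long st = 0; st < nsteps; ++st) {
      if (mode == 1)
        f_d = rk4_clamped(s, dt, target, fgf, va, fd_max, m, &e_in, &e_out);
      else
        rk4_fixed(s, dt, f_d, fgf, va, m, &e_in, &e_out);
      ++gstep;
      t = t0 + (double)gstep * dt;
      recorded_last = (gstep % rep_every == 0);
      if (recorded_last) {
        RECORD(f_d, fgf, va);
        if (!std::isfinite(s[1]) || !std::isfinite(s[2]))
          stop("integration diverged (non-finite state); reduce dt");
      }
      if (threshold_phase) {
        double v = s[evar];
        if ((ecmp > 0 && v >= elevel) || (ecmp < 0 && v <= elevel)) {
          reason = 1;
          if (!recorded_last) { RECORD(f_d, fgf, va); recorded_last = true; }
          break;
        }
      }
    }
    if (!recorded_last && nsteps > 0) { RECORD(f_d, fgf, va); recorded_last = true; }
    ph_end[p] = t;
    ph_reason[p] = reason;
  }
  #undef RECORD

  return List::create(
    _["trace"] = out(Range(0, row > 0 ? row - 1 : 0), Range(0, 11)),
    _["phase_start"] = ph_start,
    _["phase_end"] = ph_end,
    _["phase_reason"] = ph_reason);
}
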