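// 1D pulse-wave solver coupled to 0D lumped elements.
//
// Interior nodes of every vessel advance with the explicit MacCormack
// predictor-corrector applied to the 1D continuity and momentum
// equations closed by the Olufsen elastic tube law. Boundary values are
// closed with the method of characteristics: the outgoing characteristic
// invariant, linearised at its foot, is solved simultaneously with the
// attached 0D relation (junction with nodal resistance, four-compartment
// RLC peripheral bed, or the lumped heart with ideal-diode valves).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int MAXNS = 12; // small dense systems

// -------- small dense linear solver (partial pivoting) --------------
static bool solve_dense(int n, double M[MAXNS][MAXNS], double b[MAXNS],
                        double x[MAXNS]) {
  for (int k = 0; k < n; ++k) {
    int imax = k; double amax = std::fabs(M[k][k]);
    for (int i = k + 1; i < n; ++i) {
      double a = std::fabs(M[i][k]);
      if (a > amax) { amax = a; imax = i; }
    }
    if (amax < 1e-300) return false;
    if (imax != k) {
      for (int j = 0; j < n; ++j) std::swap(M[k][j], M[imax][j]);
      std::swap(b[k], b[imax]);
    }
    for (int i = k + 1; i < n; ++i) {
      double f = M[i][k] / M[k][k];
      if (f == 0.0) continue;
      for (int j = k; j < n; ++j) M[i][j] -= f * M[k][j];
      b[i] -= f * b[k];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < n; ++j) s -= M[i][j] * x[j];
    x[i] = s / M[i][i];
  }
  return true;
}

// -------- wall law -------------------------------------------------
struct Wall {
  double rho, p0;
};

static inline double pres(double A, double A0, double f0, const Wall &w) {
  return w.p0 + (4.0 / 3.0) * f0 * (1.0 - std::sqrt(A0 / A));
}
static inline double area_from_p(double p, double A0, double f0,
                                 const Wall &w, bool &ok) {
  double s = 1.0 - 3.0 * (p - w.p0) / (4.0 * f0);
  if (s < 0.05) { ok = false; return A0; }
  return A0 / (s * s);
}
static inline double wspeed(double A, double A0, double f0, const Wall &w) {
  return std::sqrt((2.0 / (3.0 * w.rho)) * f0 * std::sqrt(A0 / A));
}

// -------- segment --------------------------------------------------
struct Segment {
  int n;
  double dx;
  std::vector<double> A0, f0;   // per node (tapered)
  std::vector<double> A, q;     // state
  std::vector<double> As, qs, ps, pcur; // scratch
  std::vector<double> An, qn;   // next state
  int prox_node, dist_node;
};

// characteristic foot linearisation at a segment end.
// end = 0 (prox): outgoing lambda- ; end = 1 (dist): outgoing lambda+ .
// Returns W and Zc such that   p_b = W + sgn * Zc * q_b
// with sgn = +1 at the proximal end and -1 at the distal end.
struct CharRel { double W, Zc; bool ok; };

static CharRel char_rel(const Segment &s, int end, double dt, double KR,
                        const Wall &w) {
  CharRel r; r.ok = true;
  int i0 = (end == 0) ? 0 : s.n - 1;
  int i1 = (end == 0) ? 1 : s.n - 2;
  int i2 = (end == 0) ? 2 : s.n - 3;
  double u0 = s.q[i0] / s.A[i0];
  double c0 = wspeed(s.A[i0], s.A0[i0], s.f0[i0], w);
  double lam = (end == 0) ? (c0 - u0) : (u0 + c0); // foot distance/dt
  double th = lam * dt / s.dx;
  if (th < 0.0) th = 0.0;
  if (th > 1.0) { r.ok = false; th = 1.0; }
  // quadratic interpolation at the characteristic foot (three nodes
  // inward from the boundary) keeps the boundary closure second-order
  // consistent with the interior scheme
  double w0 = (1.0 - th) * (1.0 - th / 2.0);
  double w1 = th * (2.0 - th);
  double w2 = th * (th - 1.0) / 2.0;
  double Af  = w0 * s.A[i0]  + w1 * s.A[i1]  + w2 * s.A[i2];
  double qf  = w0 * s.q[i0]  + w1 * s.q[i1]  + w2 * s.q[i2];
  double A0f = w0 * s.A0[i0] + w1 * s.A0[i1] + w2 * s.A0[i2];
  double f0f = w0 * s.f0[i0] + w1 * s.f0[i1] + w2 * s.f0[i2];
  double pf = pres(Af, A0f, f0f, w);
  double cf = wspeed(Af, A0f, f0f, w);
  double Zc = w.rho * cf / Af;
  double Fu = -KR * qf / (Af * Af); // friction in velocity form
  if (end == 0) {
    // along lambda-: p_b - rho c u_b = p_f - rho c u_f - rho c Fu dt
    r.W = pf - Zc * qf - w.rho * cf * Fu * dt;
  } else {
    // along lambda+: p_b + rho c u_b = p_f + rho c u_f + rho c Fu dt
    r.W = pf + Zc * qf + w.rho * cf * Fu * dt;
  }
  r.Zc = Zc;
  return r;
}

// MacCormack predictor-corrector on interior nodes
static void maccormack_interior(Segment &s, double dt, double KR,
                                const Wall &w) {
  int n = s.n;
  double rdx = 1.0 / s.dx;
  for (int i = 0; i < n; ++i)
    s.pcur[i] = pres(s.A[i], s.A0[i], s.f0[i], w);
  // predictor: forward differences
  for (int i = 0; i < n - 1; ++i) {
    double Fq0 = s.q[i] * s.q[i] / s.A[i];
    double Fq1 = s.q[i + 1] * s.q[i + 1] / s.A[i + 1];
    s.As[i] = s.A[i] - dt * rdx * (s.q[i + 1] - s.q[i]);
    s.qs[i] = s.q[i] - dt * rdx * (Fq1 - Fq0)
      - dt * (s.A[i] / w.rho) * rdx * (s.pcur[i + 1] - s.pcur[i])
      - dt * KR * s.q[i] / s.A[i];
  }
  s.As[n - 1] = s.A[n - 1];
  s.qs[n - 1] = s.q[n - 1];
  for (int i = 0; i < n; ++i)
    s.ps[i] = (s.As[i] > 0) ? pres(s.As[i], s.A0[i], s.f0[i], w) : NA_REAL;
  // corrector: backward differences, averaged
  for (int i = 1; i < n - 1; ++i) {
    double Fq0 = s.qs[i - 1] * s.qs[i - 1] / s.As[i - 1];
    double Fq1 = s.qs[i] * s.qs[i] / s.As[i];
    double Ac = s.As[i] - dt * rdx * (s.qs[i] - s.qs[i - 1]);
    double qc = s.qs[i] - dt * rdx * (Fq1 - Fq0)
      - dt * (s.As[i] / w.rho) * rdx * (s.ps[i] - s.ps[i - 1])
      - dt * KR * s.qs[i] / s.As[i];
    s.An[i] = 0.5 * (s.A[i] + Ac);
    s.qn[i] = 0.5 * (s.q[i] + qc);
  }
}

// -------- peripheral bed -------------------------------------------
// Four RLC compartments (arteriolar, capillary, venular, venous). Each
// compartment is a capacitor node at its entry followed by a series
// R-L branch; the arteriolar capacitor sits directly at the 1D
// interface (classic Windkessel placement) and the venous branch
// drains to the fixed venous pressure.
struct Bed {
  int seg;                 // attached segment (its distal end)
  double r[4], c[4], l[4], p_ven;
  bool coronary;
  double alpha, beta;
  // state
  double qf[4];   // branch flows out of each compartment
  double pi[4];   // compartment (capacitor) pressures; pi[0] = inlet
  double ncor_old;        // previous modulation input (charge bookkeeping)
  double in_acc, out_acc; // cycle accumulators
};

// solve one implicit step of a bed coupled to the distal characteristic
static bool bed_step(Bed &b, const CharRel &cr, double dt, double ncor,
                     double &qb, double &pb) {
  double M[MAXNS][MAXNS] = {{0}}, rhs[MAXNS] = {0}, x[MAXNS];
  double R[4], C[4], C_old[4];
  for (int i = 0; i < 4; ++i) {
    double fr = (b.coronary && i < 2) ? (1.0 + b.alpha * ncor) : 1.0;
    double fc = (b.coronary && i < 2) ? (1.0 + b.beta * ncor) : 1.0;
    double fco = (b.coronary && i < 2) ? (1.0 + b.beta * b.ncor_old) : 1.0;
    R[i] = b.r[i] * fr;
    C[i] = b.c[i] * fc;
    C_old[i] = b.c[i] * fco;
  }
  // unknowns: x = [q0 q1 q2 q3 pi0 pi1 pi2 pi3]
  //   q0..q3: flows through the R-L branch leaving compartment i
  //   pi_i: capacitor pressures; inlet flow from the 1D end is
  //   q_in = (W - pi0)/Zc from the characteristic relation.
  // Capacitors conserve charge Q = C(t) * pi, so the implicit update is
  // (C_new pi_new - C_old pi_old)/dt = q_in - q_out; for the coronary
  // bed the pi dC/dt part is the intramyocardial pumping term.
  // C0: (C0 pi0 - C0_old pi0_n)/dt = (W - pi0)/Zc - q0
  M[4][4] = C[0] / dt + 1.0 / cr.Zc; M[4][0] = 1.0;
  rhs[4] = C_old[0] / dt * b.pi[0] + cr.W / cr.Zc;
  // branch i: (Li/dt + Ri) qi - pi_i + pi_{i+1} = (Li/dt) qi_n
  for (int i = 0; i < 4; ++i) {
    M[i][i] = b.l[i] / dt + R[i];
    M[i][4 + i] = -1.0;
    if (i < 3) M[i][4 + i + 1] = 1.0;
    rhs[i] = b.l[i] / dt * b.qf[i] + (i == 3 ? -b.p_ven : 0.0);
  }
  // C1..C3
  for (int i = 1; i < 4; ++i) {
    M[4 + i][4 + i] = C[i] / dt;
    M[4 + i][i - 1] = -1.0;
    M[4 + i][i] = 1.0;
    rhs[4 + i] = C_old[i] / dt * b.pi[i];
  }
  if (!solve_dense(8, M, rhs, x)) return false;
  for (int i = 0; i < 4; ++i) { b.qf[i] = x[i]; b.pi[i] = x[4 + i]; }
  b.ncor_old = ncor;
  pb = b.pi[0];
  qb = (cr.W - pb) / cr.Zc;
  b.in_acc += qb * dt;
  b.out_acc += b.qf[3] * dt;
  return true;
}

// -------- heart -----------------------------------------------------
struct Heart {
  double hr, t_rise, t_relax; // absolute times within the period
  double e_min_lv, e_max_lv, v0_lv;
  double e_min_rv, e_max_rv, v0_rv;
  double e_la, v0_la;
  double p_ra;
  double r_av, l_av;   // arterial (aortic/pulmonary) valve R, L
  double r_mv, l_mv;   // atrioventricular (mitral/tricuspid) valve R, L
  double r_p, c_pul, r_pv;
  // state
  double V_rv, V_lv, V_la, p_pa;
  double q_tr, q_pvv, q_mv, q_av;
  bool o_tr, o_pvv, o_mv, o_av;
};

static inline double elastance_shape(double t, double T, double tr,
                                     double trel) {
  double tt = t - T * std::floor(t / T);
  if (tt < tr) return 0.5 * (1.0 - std::cos(M_PI * tt / tr));
  if (tt < tr + trel)
    return 0.5 * (1.0 + std::cos(M_PI * (tt - tr) / trel));
  return 0.0;
}

// solve one implicit heart step against the aortic-root characteristic
static bool heart_step(Heart &h, const CharRel &cr, double t, double dt,
                       double &q_root, double &p_root) {
  double T = 1.0 / h.hr;
  double e = elastance_shape(t, T, h.t_rise, h.t_relax);
  double Erv = h.e_min_rv + (h.e_max_rv - h.e_min_rv) * e;
  double Elv = h.e_min_lv + (h.e_max_lv - h.e_min_lv) * e;
  double Ela = h.e_la;
  bool o[4] = {h.o_tr, h.o_pvv, h.o_mv, h.o_av};
  double x[MAXNS];
  for (int it = 0; it < 24; ++it) {
    double M[MAXNS][MAXNS] = {{0}}, b[MAXNS] = {0};
    // x = [V_rv V_lv V_la p_pa q_tr q_pvv q_mv q_av]
    M[0][0] = 1; M[0][4] = -dt; M[0][5] = dt; b[0] = h.V_rv;
    M[1][1] = 1; M[1][6] = -dt; M[1][7] = dt; b[1] = h.V_lv;
    M[2][2] = 1 + dt * Ela / h.r_pv; M[2][3] = -dt / h.r_pv; M[2][6] = dt;
    b[2] = h.V_la + dt * Ela * h.v0_la / h.r_pv;
    M[3][3] = h.c_pul / dt + 1.0 / h.r_pv; M[3][2] = -Ela / h.r_pv;
    M[3][5] = -1.0;
    b[3] = h.c_pul / dt * h.p_pa - Ela * h.v0_la / h.r_pv;
    if (o[0]) { // tricuspid: L(q-qn)/dt = p_ra - Erv(Vrv-v0) - R q
      M[4][4] = h.l_mv / dt + h.r_mv; M[4][0] = Erv;
      b[4] = h.l_mv / dt * h.q_tr + h.p_ra + Erv * h.v0_rv;
    } else { M[4][4] = 1; b[4] = 0; }
    if (o[1]) { // pulmonary valve: = Erv(Vrv-v0) - p_pa - R q
      M[5][5] = h.l_av / dt + h.r_av; M[5][0] = -Erv; M[5][3] = 1.0;
      b[5] = h.l_av / dt * h.q_pvv - Erv * h.v0_rv;
    } else { M[5][5] = 1; b[5] = 0; }
    if (o[2]) { // mitral: = Ela(Vla-v0) - Elv(Vlv-v0) - R q
      M[6][6] = h.l_mv / dt + h.r_mv; M[6][2] = -Ela; M[6][1] = Elv;
      b[6] = h.l_mv / dt * h.q_mv - Ela * h.v0_la + Elv * h.v0_lv;
    } else { M[6][6] = 1; b[6] = 0; }
    if (o[3]) { // aortic: = Elv(Vlv-v0) - (W + Zc q) - R q
      M[7][7] = h.l_av / dt + h.r_av + cr.Zc; M[7][1] = -Elv;
      b[7] = h.l_av / dt * h.q_av - Elv * h.v0_lv - cr.W;
    } else { M[7][7] = 1; b[7] = 0; }
    if (!solve_dense(8, M, b, x)) return false;
    double p_rv = Erv * (x[0] - h.v0_rv);
    double p_lv = Elv * (x[1] - h.v0_lv);
    double p_la = Ela * (x[2] - h.v0_la);
    double p_pa = x[3];
    double proot = cr.W + cr.Zc * (o[3] ? x[7] : 0.0);
    bool no_[4];
    no_[0] = o[0] ? (x[4] > 0) : (h.p_ra - p_rv > 0);
    no_[1] = o[1] ? (x[5] > 0) : (p_rv - p_pa > 0);
    no_[2] = o[2] ? (x[6] > 0) : (p_la - p_lv > 0);
    no_[3] = o[3] ? (x[7] > 0) : (p_lv - proot > 0);
    bool same = (no_[0] == o[0] && no_[1] == o[1] &&
                 no_[2] == o[2] && no_[3] == o[3]);
    for (int k = 0; k < 4; ++k) o[k] = no_[k];
    if (same) break;
  }
  h.o_tr = o[0]; h.o_pvv = o[1]; h.o_mv = o[2]; h.o_av = o[3];
  h.V_rv = x[0]; h.V_lv = x[1]; h.V_la = x[2]; h.p_pa = x[3];
  h.q_tr = o[0] ? x[4] : 0.0;
  h.q_pvv = o[1] ? x[5] : 0.0;
  h.q_mv = o[2] ? x[6] : 0.0;
  h.q_av = o[3] ? x[7] : 0.0;
  q_root = h.q_av;
  p_root = cr.W + cr.Zc * q_root;
  return true;
}

// -------- junction --------------------------------------------------
struct JuncEnd { int seg; int end; }; // end: 0 prox, 1 dist
struct Junction {
  std::vector<JuncEnd> ends;
  double r_half; // nodal resistance per end (R_node / 2)
  double resid_max, qscale;
};

// ==================================================================
// full patient run
// ==================================================================

// [[Rcpp::export]]
List cpp_run_patient(List model, List controls) {
  Wall w;
  List cst = model["constants"];
  w.rho = as<double>(cst["rho"]);
  w.p0 = as<double>(cst["p0"]);
  double KR = as<double>(cst["kr"]);
  double p_lv_norm = as<double>(cst["coronary_p_norm"]);
  // warm start near the expected operating point shortens the
  // transient towards the periodic solution
  double p_init = as<double>(controls["init_p"]);

  // segments
  List segl = model["segments"];
  int nseg = segl.size();
  std::vector<Segment> S(nseg);
  for (int k = 0; k < nseg; ++k) {
    List sk = segl[k];
    Segment &s = S[k];
    s.n = as<int>(sk["n"]);
    s.dx = as<double>(sk["dx"]);
    s.A0 = as<std::vector<double> >(sk["A0"]);
    s.f0 = as<std::vector<double> >(sk["f0"]);
    s.prox_node = as<int>(sk["prox_node"]);
    s.dist_node = as<int>(sk["dist_node"]);
    s.A.resize(s.n);
    for (int i = 0; i < s.n; ++i) {
      bool ok = true;
      s.A[i] = area_from_p(p_init, s.A0[i], s.f0[i], w, ok);
    }
    s.q.assign(s.n, 0.0);
    s.As.resize(s.n); s.qs.resize(s.n); s.ps.resize(s.n);
    s.pcur.resize(s.n);
    s.An = s.A; s.qn = s.q;
  }

  // junctions
  List junl = model["junctions"];
  std::vector<Junction> J(junl.size());
  for (int k = 0; k < (int)junl.size(); ++k) {
    List jk = junl[k];
    IntegerMatrix em = jk["ends"]; // columns: seg, end
    Junction &j = J[k];
    for (int i = 0; i < em.nrow(); ++i) {
      JuncEnd e; e.seg = em(i, 0); e.end = em(i, 1);
      j.ends.push_back(e);
    }
    j.r_half = as<double>(jk["r_node"]) / 2.0;
    j.resid_max = 0.0; j.qscale = 0.0;
  }

  // terminal beds
  List bedl = model["beds"];
  std::vector<Bed> B(bedl.size());
  for (int k = 0; k < (int)bedl.size(); ++k) {
    List bk = bedl[k];
    Bed &b = B[k];
    b.seg = as<int>(bk["seg"]);
    NumericVector r = bk["r"], c = bk["c"], l = bk["l"];
    for (int i = 0; i < 4; ++i) { b.r[i] = r[i]; b.c[i] = c[i]; b.l[i] = l[i]; }
    b.p_ven = as<double>(bk["p_ven"]);
    b.coronary = as<bool>(bk["coronary"]);
    b.alpha = as<double>(bk["alpha"]);
    b.beta = as<double>(bk["beta"]);
    // initialise at the steady operating point for pressure p_init:
    // uniform through-flow and the matching resistive divider profile
    double tot = b.r[0] + b.r[1] + b.r[2] + b.r[3];
    double q_ss = (p_init - b.p_ven) / tot;
    b.ncor_old = 0.0;
    double cum = 0.0;
    for (int i = 0; i < 4; ++i) {
      b.qf[i] = q_ss;
      b.pi[i] = p_init - q_ss * cum;
      cum += b.r[i];
    }
    b.in_acc = b.out_acc = 0.0;
  }

  // heart
  List hl = model["heart"];
  Heart h;
  h.hr = as<double>(hl["hr"]);
  double T = 1.0 / h.hr;
  h.t_rise = as<double>(hl["t_rise_frac"]) * T;
  h.t_relax = as<double>(hl["t_relax_frac"]) * T;
  h.e_min_lv = as<double>(hl["e_min_lv"]);
  h.e_max_lv = as<double>(hl["e_max_lv"]);
  h.v0_lv = as<double>(hl["v0_lv"]);
  h.e_min_rv = as<double>(hl["e_min_rv"]);
  h.e_max_rv = as<double>(hl["e_max_rv"]);
  h.v0_rv = as<double>(hl["v0_rv"]);
  h.e_la = as<double>(hl["e_la"]);
  h.v0_la = as<double>(hl["v0_la"]);
  h.p_ra = as<double>(hl["p_ra"]);
  h.r_av = as<double>(hl["r_av"]);
  h.l_av = as<double>(hl["l_av"]);
  h.r_mv = as<double>(hl["r_mv"]);
  h.l_mv = as<double>(hl["l_mv"]);
  h.r_p = as<double>(hl["r_p"]);
  h.c_pul = as<double>(hl["c_pul"]);
  h.r_pv = as<double>(hl["r_pv"]);
  int root_seg = as<int>(hl["root_seg"]);
  // initial lumped state: modest filling pressures, all valves closed
  h.V_rv = h.v0_rv + 1000.0 / h.e_min_rv;
  h.V_lv = h.v0_lv + 1000.0 / h.e_min_lv;
  h.V_la = h.v0_la + 1000.0 / h.e_la;
  h.p_pa = 2000.0;
  h.q_tr = h.q_pvv = h.q_mv = h.q_av = 0.0;
  h.o_tr = h.o_pvv = h.o_mv = h.o_av = false;

  // sites
  List sitel = model["sites"];
  int nsite = sitel.size();
  std::vector<int> site_seg(nsite), site_node(nsite);
  for (int k = 0; k < nsite; ++k) {
    List sk = sitel[k];
    site_seg[k] = as<int>(sk["seg"]);
    site_node[k] = as<int>(sk["node"]);
  }

  double safety = as<double>(controls["safety"]);
  int max_cycles = as<int>(controls["max_cycles"]);
  double tol = as<double>(controls["periodicity_tol"]);

  // time step from the initial state; the wave speed of this tube law
  // decreases with distension, so the initial bound plus a fixed
  // allowance for the convective velocity holds throughout
  const double u_allow = 2.0; // m/s, upper bound on |q|/A in practice
  double dtmin = 1e30;
  for (int k = 0; k < nseg; ++k) {
    for (int i = 0; i < S[k].n; ++i) {
      double c = wspeed(S[k].A[i], S[k].A0[i], S[k].f0[i], w);
      double d = S[k].dx / (c + u_allow);
      if (d < dtmin) dtmin = d;
    }
  }
  double dt = safety * dtmin;
  int nsteps = (int)std::ceil(T / dt);
  dt = T / nsteps;

  NumericMatrix site_p(nsteps, nsite), site_q(nsteps, nsite);
  NumericVector root_prev(nsteps), root_cur(nsteps);
  NumericVector ser_plv(nsteps), ser_pla(nsteps), ser_ppa(nsteps),
    ser_qav(nsteps), ser_vlv(nsteps), ser_proot(nsteps);

  std::string reason = "";
  bool failed = false, converged = false;
  int cycles_run = 0;
  double err = NA_REAL;
  double co = NA_REAL;
  double p_lv_prev = h.e_min_lv * (h.V_lv - h.v0_lv);

  for (int cycle = 1; cycle <= max_cycles && !failed && !converged; ++cycle) {
    double root_q_acc = 0.0;
    for (int k = 0; k < (int)B.size(); ++k) B[k].in_acc = B[k].out_acc = 0.0;
    for (int k = 0; k < (int)J.size(); ++k) { J[k].resid_max = 0.0; J[k].qscale = 0.0; }

    for (int istep = 0; istep < nsteps && !failed; ++istep) {
      double t_new = (cycle - 1) * T + (istep + 1) * dt;
      double ncor = p_lv_prev / p_lv_norm;
      if (ncor < 0) ncor = 0;
      if (ncor > 1) ncor = 1;

      // interior update
      for (int k = 0; k < nseg; ++k) maccormack_interior(S[k], dt, KR, w);

      // characteristic relations at all segment ends
      std::vector<CharRel> crp(nseg), crd(nseg);
      for (int k = 0; k < nseg; ++k) {
        crp[k] = char_rel(S[k], 0, dt, KR, w);
        crd[k] = char_rel(S[k], 1, dt, KR, w);
        if (!crp[k].ok || !crd[k].ok) {
          failed = true; reason = "characteristic foot outside segment";
        }
      }
      if (failed) break;

      bool ok = true;

      // junctions: mass conservation with nodal-resistance drops
      for (int k = 0; k < (int)J.size(); ++k) {
        Junction &j = J[k];
        double num = 0.0, den = 0.0;
        for (size_t e = 0; e < j.ends.size(); ++e) {
          const CharRel &cr = (j.ends[e].end == 1) ? crd[j.ends[e].seg]
                                                   : crp[j.ends[e].seg];
          num += cr.W / (cr.Zc + j.r_half);
          den += 1.0 / (cr.Zc + j.r_half);
        }
        double p_node = num / den;
        double resid = 0.0, qs = 0.0;
        for (size_t e = 0; e < j.ends.size(); ++e) {
          int sg = j.ends[e].seg, en = j.ends[e].end;
          Segment &s = S[sg];
          const CharRel &cr = (en == 1) ? crd[sg] : crp[sg];
          double qb, pb;
          if (en == 1) {
            qb = (cr.W - p_node) / (cr.Zc + j.r_half);
            pb = cr.W - cr.Zc * qb;
            resid += qb; qs += std::fabs(qb);
          } else {
            qb = (p_node - cr.W) / (cr.Zc + j.r_half);
            pb = cr.W + cr.Zc * qb;
            resid -= qb; qs += std::fabs(qb);
          }
          bool aok = true;
          int idx = (en == 1) ? s.n - 1 : 0;
          s.An[idx] = area_from_p(pb, s.A0[idx], s.f0[idx], w, aok);
          s.qn[idx] = qb;
          if (!aok) ok = false;
        }
        if (std::fabs(resid) > j.resid_max) j.resid_max = std::fabs(resid);
        if (qs > j.qscale) j.qscale = qs;
      }

      // terminal beds
      for (int k = 0; k < (int)B.size() && ok; ++k) {
        Bed &b = B[k];
        Segment &s = S[b.seg];
        double qb, pb;
        if (!bed_step(b, crd[b.seg], dt, ncor, qb, pb)) { ok = false; break; }
        bool aok = true;
        s.An[s.n - 1] = area_from_p(pb, s.A0[s.n - 1], s.f0[s.n - 1], w, aok);
        s.qn[s.n - 1] = qb;
        if (!aok) ok = false;
      }

      // heart at the aortic root
      double q_root = 0.0, p_root = 0.0;
      if (ok) {
        Segment &s = S[root_seg];
        if (!heart_step(h, crp[root_seg], t_new, dt, q_root, p_root)) {
          ok = false;
        } else {
          bool aok = true;
          s.An[0] = area_from_p(p_root, s.A0[0], s.f0[0], w, aok);
          s.qn[0] = q_root;
          if (!aok) ok = false;
        }
      }

      if (!ok) { failed = true; reason = "0D element solve failed"; break; }

      // commit, with divergence checks
      for (int k = 0; k < nseg && !failed; ++k) {
        Segment &s = S[k];
        for (int i = 0; i < s.n; ++i) {
          double a = s.An[i], qv = s.qn[i];
          if (!std::isfinite(a) || !std::isfinite(qv) || a <= 0.0 ||
              std::fabs(qv) > 1e-1) {
            failed = true; reason = "divergent 1D state"; break;
          }
          s.A[i] = a; s.q[i] = qv;
        }
      }
      if (h.V_lv < 0 || h.V_rv < 0 || h.V_la < 0 ||
          !std::isfinite(h.V_lv) || !std::isfinite(h.p_pa)) {
        failed = true; reason = "divergent lumped state";
      }
      if (failed) break;

      double e = elastance_shape(t_new, T, h.t_rise, h.t_relax);
      double Elv = h.e_min_lv + (h.e_max_lv - h.e_min_lv) * e;
      p_lv_prev = Elv * (h.V_lv - h.v0_lv);

      // recording (current cycle)
      Segment &rs = S[root_seg];
      double proot_now = pres(rs.A[0], rs.A0[0], rs.f0[0], w);
      root_cur[istep] = proot_now;
      root_q_acc += rs.q[0];
      for (int k = 0; k < nsite; ++k) {
        Segment &s = S[site_seg[k]];
        int i = site_node[k];
        site_p(istep, k) = pres(s.A[i], s.A0[i], s.f0[i], w);
        site_q(istep, k) = s.q[i];
      }
      ser_plv[istep] = p_lv_prev;
      ser_pla[istep] = h.e_la * (h.V_la - h.v0_la);
      ser_ppa[istep] = h.p_pa;
      ser_qav[istep] = h.q_av;
      ser_vlv[istep] = h.V_lv;
      ser_proot[istep] = proot_now;
    }

    if (failed) break;
    cycles_run = cycle;
    co = root_q_acc / nsteps;
    if (cycle >= 2) {
      double num = 0.0, den = 0.0;
      for (int i = 0; i < nsteps; ++i) {
        double d = root_cur[i] - root_prev[i];
        num += d * d;
        den += root_prev[i] * root_prev[i];
      }
      err = std::sqrt(num / den);
      if (err < tol) converged = true;
    }
    for (int i = 0; i < nsteps; ++i) root_prev[i] = root_cur[i];
  }
  // diagnostics
  int nb = B.size();
  NumericVector bed_in(nb), bed_out(nb);
  for (int k = 0; k < nb; ++k) {
    bed_in[k] = B[k].in_acc / T;
    bed_out[k] = B[k].out_acc / T;
  }
  double jres = 0.0;
  for (size_t k = 0; k < J.size(); ++k) {
    if (J[k].qscale > 0) {
      double r = J[k].resid_max / J[k].qscale;
      if (r > jres) jres = r;
    }
  }

  return List::create(
    _["converged"] = converged,
    _["failed"] = failed,
    _["reason"] = reason,
    _["cycles"] = cycles_run,
    _["dt"] = dt,
    _["period"] = T,
    _["periodicity_err"] = err,
    _["site_p"] = site_p,
    _["site_q"] = site_q,
    _["co"] = co,
    _["bed_inflow"] = bed_in,
    _["bed_outflow"] = bed_out,
    _["junction_resid"] = jres,
    _["heart"] = List::create(
      _["p_lv"] = ser_plv, _["p_la"] = ser_pla, _["p_pa"] = ser_ppa,
      _["q_av"] = ser_qav, _["v_lv"] = ser_vlv, _["p_root"] = ser_proot));
}

// ==================================================================
// single-tube experiments (scheme verification oracles)
// ==================================================================

// prox_bc: 0 = prescribed inflow (vector), 1 = blocked (q = 0)
// dist_bc: 0 = non-reflecting, 1 = blocked, 2 = resistance to p_out
// [[Rcpp::export]]
List cpp_tube_sim(int n, double dx, NumericVector A0, NumericVector f0,
                  double rho, double p0, double kr, double dt, int nsteps,
                  int prox_bc, NumericVector inflow, int dist_bc,
                  double r_dist, double p_out,
                  Nullable<NumericVector> A_init = R_NilValue,
                  int record_every = 1) {
  Wall w; w.rho = rho; w.p0 = p0;
  Segment s;
  s.n = n; s.dx = dx;
  s.A0 = as<std::vector<double> >(A0);
  s.f0 = as<std::vector<double> >(f0);
  s.A = s.A0;
  if (A_init.isNotNull()) s.A = as<std::vector<double> >(A_init.get());
  s.q.assign(n, 0.0);
  s.As.resize(n); s.qs.resize(n); s.ps.resize(n); s.pcur.resize(n);
  s.An = s.A; s.qn = s.q;
  double p_init = pres(s.A0[n - 1], s.A0[n - 1], s.f0[n - 1], w);

  int nrec = nsteps / record_every;
  NumericMatrix recA(nrec, n), recQ(nrec, n), recP(nrec, n);
  NumericVector vol(nrec);
  int ir = 0;
  bool failed = false;

  for (int istep = 0; istep < nsteps && !failed; ++istep) {
    maccormack_interior(s, dt, kr, w);
    CharRel cp = char_rel(s, 0, dt, kr, w);
    CharRel cd = char_rel(s, 1, dt, kr, w);
    bool aok = true;
    // proximal
    double qb, pb;
    if (prox_bc == 0) {
      qb = inflow[istep % inflow.size()];
      pb = cp.W + cp.Zc * qb;
    } else {
      qb = 0.0; pb = cp.W;
    }
    s.An[0] = area_from_p(pb, s.A0[0], s.f0[0], w, aok);
    s.qn[0] = qb;
    // distal
    if (dist_bc == 0) {
      qb = (cd.W - p_init) / (2.0 * cd.Zc);
      pb = cd.W - cd.Zc * qb;
    } else if (dist_bc == 1) {
      qb = 0.0; pb = cd.W;
    } else {
      qb = (cd.W - p_out) / (cd.Zc + r_dist);
      pb = cd.W - cd.Zc * qb;
    }
    s.An[n - 1] = area_from_p(pb, s.A0[n - 1], s.f0[n - 1], w, aok);
    s.qn[n - 1] = qb;
    if (!aok) { failed = true; break; }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(s.An[i]) || s.An[i] <= 0) { failed = true; break; }
      s.A[i] = s.An[i]; s.q[i] = s.qn[i];
    }
    if (!failed && (istep + 1) % record_every == 0 && ir < nrec) {
      double v = 0.0;
      for (int i = 0; i < n; ++i) {
        recA(ir, i) = s.A[i]; recQ(ir, i) = s.q[i];
        recP(ir, i) = pres(s.A[i], s.A0[i], s.f0[i], w);
        v += s.A[i] * ((i == 0 || i == n - 1) ? 0.5 : 1.0);
      }
      vol[ir] = v * dx; // trapezoidal volume
      ++ir;
    }
  }
  return List::create(_["A"] = recA, _["q"] = recQ, _["p"] = recP,
                      _["volume"] = vol, _["failed"] = failed,
                      _["dt"] = dt);
}

// [[Rcpp::export]]
double cpp_cfl_dt(double dx, NumericVector A, NumericVector q,
                  NumericVector A0, NumericVector f0, double rho,
                  double p0, double safety) {
  Wall w; w.rho = rho; w.p0 = p0;
  double dtmin = 1e30;
  for (int i = 0; i < A.size(); ++i) {
    double c = wspeed(A[i], A0[i], f0[i], w);
    double u = std::fabs(q[i] / A[i]);
    double d = dx / (u + c);
    if (d < dtmin) dtmin = d;
  }
  return safety * dtmin;
}
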