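// Method-of-lines core for the coupled polarity / A-motor model.
//
// State packing (length 6 + 8*n):
//   y[0..5]  = A_l, A_r, B_l, B_r, R_l, R_r          (polar pools, amount)
//   y[6..]   = a, b, r, M_i, M_ap, M_am, M_ep, M_em  (densities, amount/um,
//              each a contiguous block of n grid cells)
//
// Time stepping: Strang splitting.  Diffusion (a, b, r, M_i) is advanced by
// Crank-Nicolson half-steps (unconditionally stable, tridiagonal solves);
// reactions, polar exchange and upwind advection are advanced by an explicit
// Heun (RK2) step limited by the advective CFL condition.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  // geometry
  double L, pole_width, dx;
  int n;
  // totals
  double A_tot, B_tot, R_tot, M_tot;
  // motor kinetics
  double v_a, v_c_max_s, k_sw, k_act, k_deact, k_eng, k_dis, k_dis_pole, K_v;
  // diffusion
  double D_i, D_A, D_B, D_R;
  // polarity kinetics
  double k_Aon, k_Aoff_basal, k_Aoff, k_Bon, k_Boff, k_Ron, k_Roff;
  double beta, gamma;
  double K_AB, K_BA, K_RA, K_BB;
  double n_AB, n_BA, n_RA, n_BB;
  // options
  bool act_split_half;     // true: new active motors split 50/50 +/-
  bool freeze_regulators;  // pools held constant, no polar exchange of a,b,r
  bool freeze_velocity;    // engaged advection at fixed_v_cell
  double fixed_v_cell;
  // polar overlap weights (fraction of each cell inside a pole region)
  std::vector<double> wl, wr;
};

inline double hill_up(double x, double K, double nh) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, nh), Kn = std::pow(K, nh);
  return xn / (Kn + xn);
}
inline double hill_down(double x, double K, double nh) {
  if (x <= 0.0) return 1.0;
  double xn = std::pow(x, nh), Kn = std::pow(K, nh);
  return Kn / (Kn + xn);
}
inline double sgn(double x) { return (x > 0.0) - (x < 0.0); }

Pars unpack_pars(const List& par) {
  Pars p;
  p.L = par["L"]; p.pole_width = par["pole_width"];
  p.n = as<int>(par["n_cells"]); p.dx = p.L / p.n;
  p.A_tot = par["A_tot"]; p.B_tot = par["B_tot"];
  p.R_tot = par["R_tot"]; p.M_tot = par["M_tot"];
  p.v_a = par["v_a"];
  p.v_c_max_s = as<double>(par["v_c_max"]) / 60.0;  // um/min -> um/s
  p.k_sw = par["k_sw"]; p.k_act = par["k_act"]; p.k_deact = par["k_deact"];
  p.k_eng = par["k_eng"]; p.k_dis = par["k_dis"];
  p.k_dis_pole = par["k_dis_pole"]; p.K_v = par["K_v"];
  p.D_i = par["D_i"]; p.D_A = par["D_A"]; p.D_B = par["D_B"]; p.D_R = par["D_R"];
  p.k_Aon = par["k_Aon"]; p.k_Aoff_basal = par["k_Aoff_basal"];
  p.k_Aoff = par["k_Aoff"]; p.k_Bon = par["k_Bon"]; p.k_Boff = par["k_Boff"];
  p.k_Ron = par["k_Ron"]; p.k_Roff = par["k_Roff"];
  p.beta = par["beta"]; p.gamma = par["gamma"];
  p.K_AB = par["K_AB"]; p.K_BA = par["K_BA"];
  p.K_RA = par["K_RA"]; p.K_BB = par["K_BB"];
  p.n_AB = par["n_AB"]; p.n_BA = par["n_BA"];
  p.n_RA = par["n_RA"]; p.n_BB = par["n_BB"];
  p.act_split_half = as<std::string>(par["act_split"]) == "half";
  p.freeze_regulators = false;
  p.freeze_velocity = false;
  p.fixed_v_cell = 0.0;
  p.wl.assign(p.n, 0.0); p.wr.assign(p.n, 0.0);
  for (int j = 0; j < p.n; ++j) {
    double x0 = j * p.dx, x1 = (j + 1) * p.dx;
    double ol = std::max(0.0, std::min(x1, p.pole_width) - x0);
    double orr = std::max(0.0, x1 - std::max(x0, p.L - p.pole_width));
    p.wl[j] = ol / p.dx; p.wr[j] = orr / p.dx;
  }
  return p;
}

// Explicit part of the RHS: polar exchange, motor kinetics, advection.
// Returns the signed cell velocity (um/s) used for engaged-motor advection.
double explicit_rhs(const Pars& p, const double* y, double* dy) {
  const int n = p.n;
  const double dx = p.dx, W = p.pole_width;
  const double A_l = y[0], A_r = y[1], B_l = y[2], B_r = y[3],
               R_l = y[4], R_r = y[5];
  const double* a   = y + 6;
  const double* b   = a + n;
  const double* r   = b + n;
  const double* Mi  = r + n;
  const double* Map = Mi + n;
  const double* Mam = Map + n;
  const double* Mep = Mam + n;
  const double* Mem = Mep + n;
  double* da   = dy + 6;
  double* db   = da + n;
  double* dr   = db + n;
  double* dMi  = dr + n;
  double* dMap = dMi + n;
  double* dMam = dMap + n;
  double* dMep = dMam + n;
  double* dMem = dMep + n;
  for (int i = 0; i < 6 + 8 * n; ++i) dy[i] = 0.0;

  // ---- cell velocity from engaged motors ----
  double E = 0.0;
  for (int j = 0; j < n; ++j) E += (Mep[j] + Mem[j]) * dx;
  double dirn = sgn(A_r - A_l);
  double vmag = p.v_c_max_s * E / (E + p.K_v);
  double v_cell = p.freeze_velocity ? p.fixed_v_cell : dirn * vmag;
  double u_e = -v_cell;  // engaged motors drift toward the trailing pole

  // ---- polarity: pool on/off coefficients ----
  // J_on(A,p) = k_Aon * a_p * hill_up(R_p,K_RA) * hill_down(B_p,K_BA)
  // J_off(A,p) = (k_Aoff_basal + k_Aoff*hill_up(B_p,K_BA)) * A_p
  // J_on(B,p) = k_Bon * b_p * hill_down(A_p,K_AB) * (1 + beta*hill_up(B_p,K_BB))
  // J_off(B,p) = k_Boff * B_p
  // J_on(R,p) = k_Ron * r_p * (1 + gamma*hill_up(B_p,K_BB))
  // J_off(R,p) = k_Roff * R_p
  double coefA[2], offA[2], coefB[2], offB[2], coefR[2], offR[2];
  const double Apool[2] = {A_l, A_r}, Bpool[2] = {B_l, B_r}, Rpool[2] = {R_l, R_r};
  for (int s = 0; s < 2; ++s) {
    coefA[s] = p.k_Aon * hill_up(Rpool[s], p.K_RA, p.n_RA)
                       * hill_down(Bpool[s], p.K_BA, p.n_BA);
    offA[s]  = (p.k_Aoff_basal + p.k_Aoff * hill_up(Bpool[s], p.K_BA, p.n_BA))
               * Apool[s];
    coefB[s] = p.k_Bon * hill_down(Apool[s], p.K_AB, p.n_AB)
                       * (1.0 + p.beta * hill_up(Bpool[s], p.K_BB, p.n_BB));
    offB[s]  = p.k_Boff * Bpool[s];
    coefR[s] = p.k_Ron * (1.0 + p.gamma * hill_up(Bpool[s], p.K_BB, p.n_BB));
    offR[s]  = p.k_Roff * Rpool[s];
  }

  // polar-region averages of free species (amount / um)
  double Sa[2] = {0, 0}, Sb[2] = {0, 0}, Sr[2] = {0, 0}, SMi[2] = {0, 0},
         SMa[2] = {0, 0};
  for (int j = 0; j < n; ++j) {
    Sa[0] += p.wl[j] * a[j] * dx;   Sa[1] += p.wr[j] * a[j] * dx;
    Sb[0] += p.wl[j] * b[j] * dx;   Sb[1] += p.wr[j] * b[j] * dx;
    Sr[0] += p.wl[j] * r[j] * dx;   Sr[1] += p.wr[j] * r[j] * dx;
    SMi[0] += p.wl[j] * Mi[j] * dx; SMi[1] += p.wr[j] * Mi[j] * dx;
    SMa[0] += p.wl[j] * (Map[j] + Mam[j]) * dx;
    SMa[1] += p.wr[j] * (Map[j] + Mam[j]) * dx;
  }

  double JonA[2], JonB[2], JonR[2], act[2], deact[2];
  for (int s = 0; s < 2; ++s) {
    JonA[s] = coefA[s] * Sa[s] / W;
    JonB[s] = coefB[s] * Sb[s] / W;
    JonR[s] = coefR[s] * Sr[s] / W;
    act[s] = p.k_act * Apool[s] * SMi[s];      // consumes one polar MglA each
    deact[s] = p.k_deact * Bpool[s] * SMa[s];  // returns one MglA to the pool
  }

  if (!p.freeze_regulators) {
    dy[0] = JonA[0] - offA[0] - act[0] + deact[0];
    dy[1] = JonA[1] - offA[1] - act[1] + deact[1];
    dy[2] = JonB[0] - offB[0];
    dy[3] = JonB[1] - offB[1];
    dy[4] = JonR[0] - offR[0];
    dy[5] = JonR[1] - offR[1];
  }

  // ---- per-cell terms ----
  for (int j = 0; j < n; ++j) {
    double wlj = p.wl[j], wrj = p.wr[j];
    double cj = 1.0 - wlj - wrj;                 // non-polar fraction of cell
    double depL = wlj / W, depR = wrj / W;       // uniform polar deposition
    if (!p.freeze_regulators) {
      // on-flux removes mass proportional to local density; off-flux is
      // deposited uniformly over the polar region (locally conserving)
      da[j] += -coefA[0] * wlj * a[j] / W - coefA[1] * wrj * a[j] / W
               + offA[0] * depL + offA[1] * depR;
      db[j] += -coefB[0] * wlj * b[j] / W - coefB[1] * wrj * b[j] / W
               + offB[0] * depL + offB[1] * depR;
      dr[j] += -coefR[0] * wlj * r[j] / W - coefR[1] * wrj * r[j] / W
               + offR[0] * depL + offR[1] * depR;
    }
    double actL = p.k_act * A_l * wlj * Mi[j];
    double actR = p.k_act * A_r * wrj * Mi[j];
    double kdeact_j = p.k_deact * (B_l * wlj + B_r * wrj);
    double kdis_j = p.k_dis * cj + p.k_dis_pole * (1.0 - cj);
    dMi[j] += -(actL + actR) + kdeact_j * (Map[j] + Mam[j]);
    double toMap, toMam;
    if (p.act_split_half) {
      toMap = 0.5 * (actL + actR); toMam = toMap;
    } else {  // "away": new active motors leave their pole
      toMap = actL; toMam = actR;
    }
    dMap[j] += toMap - p.k_sw * Map[j] + p.k_sw * Mam[j]
               - p.k_eng * cj * Map[j] + kdis_j * Mep[j] - kdeact_j * Map[j];
    dMam[j] += toMam + p.k_sw * Map[j] - p.k_sw * Mam[j]
               - p.k_eng * cj * Mam[j] + kdis_j * Mem[j] - kdeact_j * Mam[j];
    dMep[j] += p.k_eng * cj * Map[j] - kdis_j * Mep[j];
    dMem[j] += p.k_eng * cj * Mam[j] - kdis_j * Mem[j];
  }

  // ---- first-order upwind advection, zero-flux walls ----
  // field q with signed velocity u: interface flux F_{j+1/2} = u * q_upwind
  auto advect = [&](const double* q, double* dq, double u) {
    if (u == 0.0) return;
    if (u > 0.0) {
      // F_{j+1/2} = u q[j], outer walls closed
      dq[0] += -u * q[0] / dx;
      for (int j = 1; j < n - 1; ++j) dq[j] += u * (q[j - 1] - q[j]) / dx;
      dq[n - 1] += u * q[n - 2] / dx;  // accumulates at the right wall
    } else {
      dq[0] += -u * q[1] / dx;
      for (int j = 1; j < n - 1; ++j) dq[j] += -u * (q[j + 1] - q[j]) / dx;
      dq[n - 1] += u * q[n - 1] / dx;
    }
  };
  advect(Map, dMap, p.v_a);
  advect(Mam, dMam, -p.v_a);
  advect(Mep, dMep, u_e);
  advect(Mem, dMem, u_e);

  return v_cell;
}

// Neumann-BC Laplacian applied explicitly (for the full-RHS oracle export)
void add_diffusion(const Pars& p, const double* q, double* dq, double D) {
  if (D <= 0.0) return;
  const int n = p.n;
  const double c = D / (p.dx * p.dx);
  dq[0] += c * (q[1] - q[0]);
  for (int j = 1; j < n - 1; ++j) dq[j] += c * (q[j - 1] - 2.0 * q[j] + q[j + 1]);
  dq[n - 1] += c * (q[n - 2] - q[n - 1]);
}

// Crank-Nicolson half-step solver for one diffusing field (Neumann BCs).
struct CNSolver {
  int n; double kap;
  std::vector<double> cp;  // Thomas forward-sweep factors (precomputed)
  void init(int n_, double D, double h, double dx) {
    n = n_; kap = D * h / (2.0 * dx * dx);
    cp.assign(n, 0.0);
    // diag: 1+kap (ends), 1+2kap (interior); off-diag: -kap
    double bb = 1.0 + kap;
    cp[0] = -kap / bb;
    for (int i = 1; i < n; ++i) {
      double diag = (i == n - 1) ? (1.0 + kap) : (1.0 + 2.0 * kap);
      cp[i] = -kap / (diag + kap * cp[i - 1]);
    }
  }
  void step(double* q, std::vector<double>& rhs) const {
    if (kap == 0.0) return;
    rhs[0] = q[0] + kap * (q[1] - q[0]);
    for (int i = 1; i < n - 1; ++i)
      rhs[i] = q[i] + kap * (q[i - 1] - 2.0 * q[i] + q[i + 1]);
    rhs[n - 1] = q[n - 1] + kap * (q[n - 2] - q[n - 1]);
    // Thomas solve (A q_new = rhs)
    double bb = 1.0 + kap;
    rhs[0] /= bb;
    for (int i = 1; i < n; ++i) {
      double diag = (i == n - 1) ? (1.0 + kap) : (1.0 + 2.0 * kap);
      rhs[i] = (rhs[i] + kap * rhs[i - 1]) / (diag + kap * cp[i - 1]);
    }
    q[n - 1] = rhs[n - 1];
    for (int i = n - 2; i >= 0; --i) q[i] = rhs[i] - cp[i] * q[i + 1];
  }
};

void totals_of(const Pars& p, const double* y, double* tot) {
  const int n = p.n;
  const double* a = y + 6;
  double sa = 0, sb = 0, sr = 0, sm = 0, sma = 0;
  for (int j = 0; j < n; ++j) {
    sa += a[j]; sb += a[n + j]; sr += a[2 * n + j];
    sm += a[3 * n + j] + a[4 * n + j] + a[5 * n + j] + a[6 * n + j] + a[7 * n + j];
    sma += a[4 * n + j] + a[5 * n + j] + a[6 * n + j] + a[7 * n + j];
  }
  tot[0] = y[0] + y[1] + (sa + sma) * p.dx;  // MglA incl. motor-bound
  tot[1] = y[2] + y[3] + sb * p.dx;
  tot[2] = y[4] + y[5] + sr * p.dx;
  tot[3] = sm * p.dx;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_rhs(List par, NumericVector y) {
  Pars p = unpack_pars(par);
  if ((int)y.size() != 6 + 8 * p.n) stop("state length does not match grid");
  NumericVector dy(y.size());
  explicit_rhs(p, y.begin(), dy.begin());
  double* base = dy.begin() + 6;
  const double* yb = y.begin() + 6;
  add_diffusion(p, yb, base, p.D_A);
  add_diffusion(p, yb + p.n, base + p.n, p.D_B);
  add_diffusion(p, yb + 2 * p.n, base + 2 * p.n, p.D_R);
  add_diffusion(p, yb + 3 * p.n, base + 3 * p.n, p.D_i);
  return dy;
}

// [[Rcpp::export]]
List cpp_simulate(List par, NumericVector y0, double t_end, double output_dt,
                  double snapshot_dt, List opts) {
  Pars p = unpack_pars(par);
  const int n = p.n, m = 6 + 8 * n;
  if ((int)y0.size() != m) stop("initial state length does not match grid");

  p.freeze_regulators = as<bool>(opts["freeze_regulators"]);
  if (opts.containsElementNamed("fixed_v_cell") &&
      !Rf_isNull(opts["fixed_v_cell"])) {
    p.freeze_velocity = true;
    p.fixed_v_cell = as<double>(opts["fixed_v_cell"]);
  }
  double dt_max = as<double>(opts["dt_max"]);
  double cfl = as<double>(opts["cfl"]);

  // time step: CFL-limited by the fast active-motor advection
  double vmax = std::max(p.v_a, p.v_c_max_s);
  double dt_t = dt_max;
  if (vmax > 0) dt_t = std::min(dt_t, cfl * p.dx / vmax);
  int sub = std::max(1, (int)std::ceil(output_dt / dt_t - 1e-12));
  double dt = output_dt / sub;
  if (vmax > 0 && vmax * dt / p.dx > 1.0) stop("CFL violation: |v|*dt/dx > 1");

  int n_out = (int)std::llround(t_end / output_dt);
  int snap_every = snapshot_dt > 0
      ? std::max(1, (int)std::llround(snapshot_dt / output_dt)) : -1;

  CNSolver cnA, cnB, cnR, cnI;
  cnA.init(n, p.D_A, dt / 2.0, p.dx);
  cnB.init(n, p.D_B, dt / 2.0, p.dx);
  cnR.init(n, p.D_R, dt / 2.0, p.dx);
  cnI.init(n, p.D_i, dt / 2.0, p.dx);
  std::vector<double> work(n);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(m), k2(m), ytmp(m);

  NumericVector times(n_out + 1), sigma(n_out + 1), vel(n_out + 1),
      Eng(n_out + 1), f_act(n_out + 1), f_eng(n_out + 1),
      nonpolar_A(n_out + 1);
  NumericMatrix pools(n_out + 1, 6), totals(n_out + 1, 4);
  std::vector<int> snap_idx;
  std::vector<std::vector<double>> snaps;

  auto record = [&](int k) {
    times[k] = k * output_dt;
    sigma[k] = y[1] - y[0];
    double E = 0, Aact = 0, Apolar_cyt = 0;
    for (int j = 0; j < n; ++j) {
      double map = y[6 + 4 * n + j], mam = y[6 + 5 * n + j],
             mep = y[6 + 6 * n + j], mem = y[6 + 7 * n + j];
      E += (mep + mem) * p.dx;
      Aact += (map + mam) * p.dx;
      double w = p.wl[j] + p.wr[j];
      Apolar_cyt += w * (y[6 + j] + map + mam + mep + mem) * p.dx;
    }
    double tt[4]; totals_of(p, y.data(), tt);
    for (int q = 0; q < 4; ++q) totals(k, q) = tt[q];
    for (int q = 0; q < 6; ++q) pools(k, q) = y[q];
    Eng[k] = E;
    f_act[k] = Aact / p.M_tot;
    f_eng[k] = E / p.M_tot;
    nonpolar_A[k] = tt[0] > 0 ? 1.0 - (y[0] + y[1] + Apolar_cyt) / tt[0] : 0.0;
    double dirn = sgn(y[1] - y[0]);
    vel[k] = p.freeze_velocity ? p.fixed_v_cell
                               : dirn * p.v_c_max_s * E / (E + p.K_v);
    if (snap_every > 0 && k % snap_every == 0) {
      snap_idx.push_back(k);
      snaps.push_back(y);
    }
  };

  record(0);
  for (int k = 1; k <= n_out; ++k) {
    for (int s = 0; s < sub; ++s) {
      double* yb = y.data() + 6;
      cnA.step(yb, work); cnB.step(yb + n, work);
      cnR.step(yb + 2 * n, work); cnI.step(yb + 3 * n, work);
      explicit_rhs(p, y.data(), k1.data());
      for (int i = 0; i < m; ++i) ytmp[i] = y[i] + dt * k1[i];
      explicit_rhs(p, ytmp.data(), k2.data());
      for (int i = 0; i < m; ++i) y[i] += 0.5 * dt * (k1[i] + k2[i]);
      yb = y.data() + 6;
      cnA.step(yb, work); cnB.step(yb + n, work);
      cnR.step(yb + 2 * n, work); cnI.step(yb + 3 * n, work);
    }
    record(k);
  }

  NumericMatrix snap_mat(snaps.size(), m);
  NumericVector snap_t(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) {
    snap_t[i] = snap_idx[i] * output_dt;
    for (int j = 0; j < m; ++j) snap_mat(i, j) = snaps[i][j];
  }

  return List::create(
      _["times"] = times, _["sigma"] = sigma, _["velocity"] = vel,
      _["engaged"] = Eng, _["f_active"] = f_act, _["f_engaged"] = f_eng,
      _["nonpolar_A"] = nonpolar_A, _["pools"] = pools, _["totals"] = totals,
      _["snapshot_times"] = snap_t, _["snapshots"] = snap_mat,
      _["state_final"] = NumericVector(y.begin(), y.end()),
      _["dt"] = dt);
}
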