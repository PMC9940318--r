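// 1D-0D pulse-wave solver core.
//
// Interior scheme: Richtmyer two-step (predictor at cell interfaces,
// corrector at nodes) for the 1D system
//   A_t + Q_x = 0
//   Q_t + (Q^2/A)_x + (A/rho) p_x = -fr Q/A
// with tube law p = p_ref + bh(x) (sqrt(A) - sqrt(A0(x))) + p_ext(t),
// bh = beta/A0, wave speed c^2 = bh sqrt(A) / (2 rho), and friction
// coefficient fr = 2 (zeta+2) pi mu / rho. The pressure-gradient term is
// discretised non-conservatively (central differences of nodal /
// half-step pressures): a spatially uniform pressure over an arbitrary
// taper is then an exact discrete equilibrium, which the conservative
// pressure-flux form does not satisfy (its O(dx^2) imbalance scales with
// the huge absolute flux and rectifies into a spurious mean gradient).
//
// Boundary nodes own conservative half-cells: each segment end evolves
//   (dx/2) dA_b/dt = (flux in at the boundary) - (predictor flux at the
//   first/last interior interface)
// so the boundary flux Q_b is the single unknown per end, and mass
// telescopes exactly from every inflow to every terminal. Couplings close
// the system:
//  - inflow: prescribed pressure -> A_b known, Q_b explicit;
//  - junction of N ends: static-pressure continuity + exact mass balance,
//    Newton on the N end fluxes (a 1-1 junction of identical segments
//    reduces exactly to the interior corrector: transparent);
//  - lumped stenosis interface: flux continuity with pressure jump
//    dP = Rv Q + Rt Q|Q| + Lu dQ/dt, scalar Newton;
//  - RCR terminal: backward-Euler Windkessel ODE with intramyocardial
//    back-pressure (C dPc/dt = Q - (Pc - Pim)/R2 + C dPim/dt), scalar
//    Newton.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

namespace {

struct Mesh {
  int nseg, ntot;
  std::vector<int> off, n;
  std::vector<double> dx;
  std::vector<double> A0, sqA0, bh;  // per node
  std::vector<double> gamma_ext;     // per segment
  double rho, fr, pref;
};

inline double wave_c(const Mesh& m, int node, double A) {
  return std::sqrt(m.bh[node] * std::sqrt(A) / (2.0 * m.rho));
}

// dense Gaussian elimination with partial pivoting (k x k), in place
bool gauss_solve(std::vector<double>& J, std::vector<double>& r, int k) {
  for (int c = 0; c < k; ++c) {
    int piv = c;
    double amax = std::fabs(J[c * k + c]);
    for (int i = c + 1; i < k; ++i) {
      double a = std::fabs(J[i * k + c]);
      if (a > amax) { amax = a; piv = i; }
    }
    if (amax < 1e-300) return false;
    if (piv != c) {
      for (int j = 0; j < k; ++j) std::swap(J[c * k + j], J[piv * k + j]);
      std::swap(r[c], r[piv]);
    }
    for (int i = c + 1; i < k; ++i) {
      double f = J[i * k + c] / J[c * k + c];
      if (f == 0.0) continue;
      for (int j = c; j < k; ++j) J[i * k + j] -= f * J[c * k + j];
      r[i] -= f * r[c];
    }
  }
  for (int i = k - 1; i >= 0; --i) {
    double s = r[i];
    for (int j = i + 1; j < k; ++j) s -= J[i * k + j] * r[j];
    r[i] = s / J[i * k + i];
  }
  return true;
}

// half-cell state of one segment end: A_b(Q_b) is affine in the unknown
// boundary flux with slope dAdQ
struct EndCell {
  int node;        // global node index of the boundary node
  double Aold;     // A at the boundary node, old time level
  double Qold;     // Q at the boundary node, old time level
  double slope;    // dA_b/dQ_b = +-2 dt/dx
  double Qh;       // predictor flux at the adjacent interface
  double sgn;      // +1 distal end (flow leaves segment), -1 proximal
  double bh, sqA0, pext;
  double A(double Qb) const { return Aold + slope * (sgn > 0 ? Qh - Qb
                                                             : Qb - Qh); }
  // n.b. for a proximal end slope carries the +2dt/dx, distal the same
};

} // namespace

// [[Rcpp::export(name = ".lw_solve")]]
List lw_solve(List mesh_r, List bc_r, List ctrl_r) {
  Mesh m;
  {
    IntegerVector off = mesh_r["off"], nn = mesh_r["n"];
    NumericVector dx = mesh_r["dx"], A0 = mesh_r["A0"], bh = mesh_r["bh"],
                  ge = mesh_r["gamma_ext"];
    m.nseg = off.size();
    m.off.assign(off.begin(), off.end());
    m.n.assign(nn.begin(), nn.end());
    m.dx.assign(dx.begin(), dx.end());
    m.A0.assign(A0.begin(), A0.end());
    m.bh.assign(bh.begin(), bh.end());
    m.ntot = m.A0.size();
    m.sqA0.resize(m.ntot);
    for (int i = 0; i < m.ntot; ++i) m.sqA0[i] = std::sqrt(m.A0[i]);
    m.gamma_ext.assign(ge.begin(), ge.end());
    m.rho = as<double>(mesh_r["rho"]);
    m.fr = as<double>(mesh_r["fr"]);
    m.pref = as<double>(mesh_r["pref"]);
  }
  CharacterVector seg_ids = mesh_r["seg_ids"];

  NumericVector pa = bc_r["pa"], plv = bc_r["plv"];
  IntegerMatrix inflows = bc_r["inflows"]; // columns: seg (0-based), end
  List junctions = bc_r["junctions"];      // each: IntegerMatrix ends x 2
  List stenoses = bc_r["stenoses"];        // each: list(segL, segR, Rv, Rt, Lu)
  List terminals = bc_r["terminals"];

  IntegerVector term_seg = terminals["seg"];
  NumericVector term_R1 = terminals["R1"], term_R2 = terminals["R2"],
                term_C = terminals["C"], term_gim = terminals["gamma_im"],
                term_Pc0 = terminals["Pc0"];
  int nterm = term_seg.size();

  int nst = stenoses.size();
  std::vector<int> st_sL(nst), st_sR(nst);
  std::vector<double> st_Rv(nst), st_Rt(nst), st_Lu(nst), st_Qold(nst, 0.0);
  for (int i = 0; i < nst; ++i) {
    List s = stenoses[i];
    st_sL[i] = as<int>(s["segL"]); st_sR[i] = as<int>(s["segR"]);
    st_Rv[i] = as<double>(s["Rv"]); st_Rt[i] = as<double>(s["Rt"]);
    st_Lu[i] = as<double>(s["Lu"]);
  }

  double dt = as<double>(ctrl_r["dt"]);
  int nsteps = as<int>(ctrl_r["nsteps"]);
  int max_cycles = as<int>(ctrl_r["max_cycles"]);
  double tol = as<double>(ctrl_r["tol"]);
  int stride = as<int>(ctrl_r["stride"]);
  int ndec = (nsteps + stride - 1) / stride;

  // state: uniform pressure equal to the inflow pressure at t = 0
  std::vector<double> A(m.ntot), Q(m.ntot, 0.0), An(m.ntot), Qn(m.ntot);
  {
    double p0 = pa[0];
    for (int s = 0; s < m.nseg; ++s) {
      int o = m.off[s], n = m.n[s];
      for (int i = o; i < o + n; ++i) {
        double sq = m.sqA0[i] + (p0 - m.pref - m.gamma_ext[s] * plv[0]) / m.bh[i];
        A[i] = (sq > 0.1 * m.sqA0[i]) ? sq * sq : 0.01 * m.A0[i];
      }
    }
  }
  std::vector<double> Pc(nterm);
  for (int i = 0; i < nterm; ++i) Pc[i] = term_Pc0[i];

  NumericMatrix Adec(ndec, m.ntot), Qdec(ndec, m.ntot);
  NumericVector tdec(ndec);
  std::vector<double> qt_prev((size_t)nterm * nsteps, 0.0),
                      qt_cur((size_t)nterm * nsteps, 0.0);
  std::vector<double> residuals;
  bool converged = false;
  int cycles_run = 0;

  int max_ends = 2;
  for (int j = 0; j < junctions.size(); ++j) {
    IntegerMatrix e = junctions[j];
    if (e.nrow() > max_ends) max_ends = e.nrow();
  }
  if (max_ends > 8) stop("junction with more than 8 ends not supported");

  std::vector<double> F1(m.ntot), F2(m.ntot);
  std::vector<double> QhL(m.nseg), QhR(m.nseg); // first/last interface flux

  // assemble the half-cell view of a segment end (end: 0 prox, 1 dist)
  auto end_cell = [&](int s, int end, double plv_new) {
    EndCell e;
    int o = m.off[s], n = m.n[s];
    e.node = end ? o + n - 1 : o;
    e.Aold = A[e.node];
    e.Qold = Q[e.node];
    e.slope = 2.0 * dt / m.dx[s];
    e.Qh = end ? QhR[s] : QhL[s];
    e.sgn = end ? 1.0 : -1.0;
    e.bh = m.bh[e.node];
    e.sqA0 = m.sqA0[e.node];
    e.pext = m.gamma_ext[s] * plv_new;
    return e;
  };
  auto cell_A = [&](const EndCell& e, double Qb) {
    // proximal: (dx/2) dA/dt = Qb - Qh ; distal: (dx/2) dA/dt = Qh - Qb
    return e.Aold + e.slope * ((e.sgn > 0) ? (e.Qh - Qb) : (Qb - e.Qh));
  };
  auto cell_dAdQ = [&](const EndCell& e) {
    return (e.sgn > 0) ? -e.slope : e.slope;
  };

  for (int cyc = 0; cyc < max_cycles && !converged; ++cyc) {
    for (int k = 0; k < nsteps; ++k) {
      double plv_new = plv[(k + 1) % nsteps];
      double pa_new = pa[(k + 1) % nsteps];
      double plv_old = plv[k % nsteps];

      // advective flux, nodal pressure (relative to p_ref), CFL
      double cfl_worst = 1e30; int cfl_seg = -1;
      for (int s = 0; s < m.nseg; ++s) {
        int o = m.off[s], n = m.n[s];
        double smax = 0.0;
        for (int i = o; i < o + n; ++i) {
          double a = A[i];
          if (!(a > 0.0) || !std::isfinite(Q[i]))
            stop("solver instability (non-positive area or NaN) in segment '%s' at cycle %d",
                 std::string(seg_ids[s]).c_str(), cyc + 1);
          double sq = std::sqrt(a);
          double u = Q[i] / a;
          double c = std::sqrt(m.bh[i] * sq / (2.0 * m.rho));
          double sp = std::fabs(u) + c;
          if (sp > smax) smax = sp;
          F1[i] = Q[i] * u;                      // advective momentum flux
          F2[i] = m.bh[i] * (sq - m.sqA0[i]);    // nodal pressure - p_ref
        }
        double lim = m.dx[s] / smax;
        if (lim < cfl_worst) { cfl_worst = lim; cfl_seg = s; }
      }
      if (dt > cfl_worst)
        stop("CFL violated in segment '%s': dt = %g exceeds dx/max(|u|+c) = %g (cycle %d, step %d)",
             std::string(seg_ids[cfl_seg]).c_str(), dt, cfl_worst, cyc + 1, k);

      // interior Richtmyer update; record first/last interface fluxes
      for (int s = 0; s < m.nseg; ++s) {
        int o = m.off[s], n = m.n[s];
        double dxs = m.dx[s], lam = dt / dxs;
        double Qh_prev = 0, Fh_prev = 0, ph_prev = 0, Ah_prev = 0;
        for (int i = o; i < o + n - 1; ++i) {
          double Aavg = 0.5 * (A[i] + A[i + 1]);
          double Qavg = 0.5 * (Q[i] + Q[i + 1]);
          double Ah = Aavg - 0.5 * lam * (Q[i + 1] - Q[i]);
          double src = -(Aavg / m.rho) * (F2[i + 1] - F2[i]) / dxs -
                       m.fr * Qavg / Aavg;
          double Qh = Qavg - 0.5 * lam * (F1[i + 1] - F1[i]) + 0.5 * dt * src;
          if (!(Ah > 0.0))
            stop("solver instability (half-step area <= 0) in segment '%s'",
                 std::string(seg_ids[s]).c_str());
          double bh_m = 0.5 * (m.bh[i] + m.bh[i + 1]);
          double sa0_m = 0.5 * (m.sqA0[i] + m.sqA0[i + 1]);
          double ph = bh_m * (std::sqrt(Ah) - sa0_m);
          double Fh = Qh * Qh / Ah;
          if (i == o) QhL[s] = Qh;
          if (i == o + n - 2) QhR[s] = Qh;
          if (i > o) {
            int j = i;
            double Atil = 0.5 * (Ah + Ah_prev);
            An[j] = A[j] - lam * (Qh - Qh_prev);
            Qn[j] = Q[j] - lam * (Fh - Fh_prev) -
                    (dt / m.rho) * Atil * (ph - ph_prev) / dxs -
                    dt * m.fr * Q[j] / A[j];
          }
          Qh_prev = Qh; Fh_prev = Fh; ph_prev = ph; Ah_prev = Ah;
        }
      }

      // --- inflows: prescribed pressure; flux from the half-cell ---
      for (int r = 0; r < inflows.nrow(); ++r) {
        int s = inflows(r, 0), end = inflows(r, 1);
        EndCell e = end_cell(s, end, plv_new);
        double sq = e.sqA0 + (pa_new - m.pref - e.pext) / e.bh;
        if (!(sq > 0))
          stop("inflow pressure collapses segment '%s'",
               std::string(seg_ids[s]).c_str());
        double Ab = sq * sq;
        // invert the half-cell mass balance for the boundary flux
        double Qb = (e.sgn > 0)
          ? e.Qh - (Ab - e.Aold) / e.slope
          : e.Qh + (Ab - e.Aold) / e.slope;
        An[e.node] = Ab;
        Qn[e.node] = Qb;
      }

      // --- junctions: pressure continuity + mass, Newton on end fluxes ---
      for (int jj = 0; jj < junctions.size(); ++jj) {
        IntegerMatrix ends = junctions[jj];
        int N = ends.nrow();
        EndCell ec[8];
        double Qb[8];
        for (int i = 0; i < N; ++i) {
          ec[i] = end_cell(ends(i, 0), ends(i, 1), plv_new);
          Qb[i] = ec[i].Qold;
        }
        bool ok = false;
        for (int it = 0; it < 60 && !ok; ++it) {
          std::vector<double> J(N * N, 0.0), r(N, 0.0);
          double p0 = 0, dp0 = 0, Ab0 = 0;
          for (int i = 0; i < N; ++i) {
            double Ab = cell_A(ec[i], Qb[i]);
            if (!(Ab > 0))
              stop("junction half-cell area collapsed (junction %d)", jj + 1);
            double p = ec[i].bh * (std::sqrt(Ab) - ec[i].sqA0) + ec[i].pext;
            double dpdQ = ec[i].bh / (2 * std::sqrt(Ab)) * cell_dAdQ(ec[i]);
            if (i == 0) { p0 = p; dp0 = dpdQ; Ab0 = Ab; (void)Ab0; }
            else {
              r[i - 1] = (p - p0) / m.rho;
              J[(i - 1) * N + i] = dpdQ / m.rho;
              J[(i - 1) * N + 0] = -dp0 / m.rho;
            }
          }
          double s = 0;
          for (int i = 0; i < N; ++i) {
            s += ec[i].sgn * Qb[i];
            J[(N - 1) * N + i] = ec[i].sgn;
          }
          r[N - 1] = s;
          if (!gauss_solve(J, r, N))
            stop("singular junction system (junction %d)", jj + 1);
          double step = 0;
          for (int i = 0; i < N; ++i) {
            Qb[i] -= r[i];
            step = std::max(step, std::fabs(r[i]) / (std::fabs(Qb[i]) + 1.0));
          }
          if (step < 1e-11) ok = true;
        }
        if (!ok)
          stop("junction Newton did not converge (junction %d)", jj + 1);
        for (int i = 0; i < N; ++i) {
          An[ec[i].node] = cell_A(ec[i], Qb[i]);
          Qn[ec[i].node] = Qb[i];
        }
      }

      // --- stenosis interfaces: scalar Newton on the common flux ---
      for (int i = 0; i < nst; ++i) {
        EndCell eL = end_cell(st_sL[i], 1, plv_new);
        EndCell eR = end_cell(st_sR[i], 0, plv_new);
        double Qs = 0.5 * (eL.Qold + eR.Qold);
        bool ok = false;
        for (int it = 0; it < 80 && !ok; ++it) {
          double AL = cell_A(eL, Qs), AR = cell_A(eR, Qs);
          if (!(AL > 0) || !(AR > 0))
            stop("stenosis half-cell area collapsed (stenosis %d)", i + 1);
          double pL = eL.bh * (std::sqrt(AL) - eL.sqA0) + eL.pext;
          double pR = eR.bh * (std::sqrt(AR) - eR.sqA0) + eR.pext;
          double dQdt = (Qs - st_Qold[i]) / dt;
          double g = pL - pR -
                     (st_Rv[i] * Qs + st_Rt[i] * Qs * std::fabs(Qs) +
                      st_Lu[i] * dQdt);
          double dg = eL.bh / (2 * std::sqrt(AL)) * cell_dAdQ(eL) -
                      eR.bh / (2 * std::sqrt(AR)) * cell_dAdQ(eR) -
                      (st_Rv[i] + 2 * st_Rt[i] * std::fabs(Qs) + st_Lu[i] / dt);
          double dq = g / dg;
          Qs -= dq;
          if (std::fabs(dq) / (std::fabs(Qs) + 1.0) < 1e-11) ok = true;
        }
        if (!ok) stop("stenosis Newton did not converge (stenosis %d)", i + 1);
        An[eL.node] = cell_A(eL, Qs); Qn[eL.node] = Qs;
        An[eR.node] = cell_A(eR, Qs); Qn[eR.node] = Qs;
        st_Qold[i] = Qs;
      }

      // --- terminals: scalar Newton on the outflow ---
      for (int i = 0; i < nterm; ++i) {
        EndCell e = end_cell(term_seg[i], 1, plv_new);
        double Pim = term_gim[i] * plv_new;
        double dPim = term_gim[i] * (plv_new - plv_old);
        double a1 = dt / term_C[i];
        double den = 1.0 + a1 / term_R2[i];
        double Qb = e.Qold;
        bool ok = false;
        for (int it = 0; it < 80 && !ok; ++it) {
          double Ab = cell_A(e, Qb);
          if (!(Ab > 0))
            stop("terminal half-cell area collapsed (terminal %d)", i + 1);
          double Pcn = (Pc[i] + dPim + a1 * (Qb + Pim / term_R2[i])) / den;
          double p = e.bh * (std::sqrt(Ab) - e.sqA0) + e.pext + m.pref;
          double g = p - term_R1[i] * Qb - Pcn;
          double dg = e.bh / (2 * std::sqrt(Ab)) * cell_dAdQ(e) -
                      term_R1[i] - a1 / den;
          double dq = g / dg;
          Qb -= dq;
          if (std::fabs(dq) / (std::fabs(Qb) + 1.0) < 1e-12) ok = true;
        }
        if (!ok) stop("terminal Newton did not converge (terminal %d)", i + 1);
        double Ab = cell_A(e, Qb);
        Pc[i] = (Pc[i] + dPim + a1 * (Qb + Pim / term_R2[i])) / den;
        An[e.node] = Ab; Qn[e.node] = Qb;
        qt_cur[(size_t)i * nsteps + k] = Qb;
      }

      A.swap(An); Q.swap(Qn);

      if (k % stride == 0) {
        int row = k / stride;
        tdec[row] = (k + 1) * dt;
        for (int i = 0; i < m.ntot; ++i) {
          Adec(row, i) = A[i];
          Qdec(row, i) = Q[i];
        }
      }
    }
    cycles_run = cyc + 1;

    double num = 0, den = 0;
    for (size_t i = 0; i < qt_cur.size(); ++i) {
      double d = qt_cur[i] - qt_prev[i];
      num += d * d;
      den += qt_prev[i] * qt_prev[i];
    }
    double res = (cyc == 0 || den == 0) ? 1.0 : std::sqrt(num / den);
    residuals.push_back(res);
    if (cyc > 0 && res < tol) converged = true;
    qt_prev.swap(qt_cur);
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix qterm(nterm, nsteps);
  for (int i = 0; i < nterm; ++i)
    for (int k = 0; k < nsteps; ++k)
      qterm(i, k) = qt_prev[(size_t)i * nsteps + k];

  return List::create(
    _["time"] = tdec, _["A"] = Adec, _["Q"] = Qdec,
    _["terminal_Q"] = qterm,
    _["Pc"] = NumericVector(Pc.begin(), Pc.end()),
    _["cycles"] = cycles_run, _["converged"] = converged,
    _["residuals"] = NumericVector(residuals.begin(), residuals.end()));
}
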