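// Monodomain reaction-diffusion core on a P1 triangular mesh.
//
// Time stepping is operator-split per step: an explicit reaction update of
// the two-variable ionic model (dimensionless V in [0,1], gate h with exact
// exponential relaxation), then an implicit mass-lumped diffusion solve
// (M + dt K) V = M V*, done with Jacobi-preconditioned conjugate gradients
// warm-started from the reaction state. The system matrix is assembled in R
// and passed in CSR form; it is constant over a run, and CG on the strongly
// diagonally dominant system converges in a handful of iterations.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// y = A x for CSR (ap: row pointers 0-based, ai: col indices 0-based)
static inline void csr_mv(const int n, const int *ap, const int *ai,
                          const double *ax, const double *x, double *y) {
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = ap[i]; k < ap[i + 1]; ++k) s += ax[k] * x[ai[k]];
    y[i] = s;
  }
}

// Jacobi-preconditioned CG; x holds the warm start and the solution.
static int cg_solve(const int n, const int *ap, const int *ai,
                    const double *ax, const double *dinv, const double *b,
                    double *x, std::vector<double> &r, std::vector<double> &z,
                    std::vector<double> &p, std::vector<double> &q,
                    const double tol, const int maxit) {
  csr_mv(n, ap, ai, ax, x, r.data());
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = b[i] - r[i];
    bnorm += b[i] * b[i];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;
  double rz = 0.0;
  for (int i = 0; i < n; ++i) { z[i] = r[i] * dinv[i]; p[i] = z[i]; rz += r[i] * z[i]; }
  int it = 0;
  for (; it < maxit; ++it) {
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) rnorm += r[i] * r[i];
    if (std::sqrt(rnorm) <= tol * bnorm) break;
    csr_mv(n, ap, ai, ax, p.data(), q.data());
    double pq = 0.0;
    for (int i = 0; i < n; ++i) pq += p[i] * q[i];
    double alpha = rz / pq;
    for (int i = 0; i < n; ++i) { x[i] += alpha * p[i]; r[i] -= alpha * q[i]; }
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) { z[i] = r[i] * dinv[i]; rz_new += r[i] * z[i]; }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }
  return it;
}

// [[Rcpp::export]]
List cpp_monodomain_run(IntegerVector ap, IntegerVector ai, NumericVector ax,
                        NumericVector mdiag, NumericVector tau_close_node,
                        double tau_in, double tau_out, double tau_open,
                        double v_gate, double dt, double t0, double duration,
                        NumericVector stim_start, NumericVector stim_dur,
                        NumericVector stim_amp, List stim_nodes,
                        NumericVector V0, NumericVector h0,
                        double act_thresh, int max_act,
                        bool stop_on_quiescent, double quiesce_tol,
                        IntegerVector watch_nodes, int watch_min,
                        double watch_after, int check_every) {
  const int n = V0.size();
  const int nsteps = (int)std::lround(duration / dt);
  const int nstim = stim_start.size();
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> Vr(n), rhs(n), r(n), z(n), p(n), q(n), dinv(n);
  const int *app = ap.begin(); const int *aip = ai.begin();
  const double *axp = ax.begin();
  for (int i = 0; i < n; ++i) {
    double d = 0.0;
    for (int k = app[i]; k < app[i + 1]; ++k)
      if (aip[k] == i) { d = axp[k]; break; }
    dinv[i] = 1.0 / d;
  }
  const double eo = std::exp(-dt / tau_open);
  std::vector<double> ec(n);
  for (int i = 0; i < n; ++i) ec[i] = std::exp(-dt / tau_close_node[i]);
  std::vector<std::vector<int>> snodes(nstim);
  for (int s = 0; s < nstim; ++s) {
    IntegerVector sv = stim_nodes[s];
    snodes[s].assign(sv.begin(), sv.end());   // 0-based
  }
  std::vector<int> act_node; std::vector<double> act_time;
  std::vector<int> nact(n, 0);
  std::vector<char> watched_hit(watch_nodes.size(), 0);
  int watch_count = 0;
  std::string stopped = "end";
  double t = t0;
  double last_stim_end = -1e30;
  for (int s = 0; s < nstim; ++s)
    last_stim_end = std::max(last_stim_end, stim_start[s] + stim_dur[s]);
  int step = 0;
  for (; step < nsteps; ++step) {
    // reaction + stimulus
    for (int i = 0; i < n; ++i) {
      double v = V[i];
      double dv = h[i] * v * v * (1.0 - v) / tau_in - v / tau_out;
      Vr[i] = v + dt * dv;
    }
    for (int s = 0; s < nstim; ++s) {
      if (t >= stim_start[s] && t < stim_start[s] + stim_dur[s]) {
        const double add = dt * stim_amp[s];
        // cap the driven potential at plateau level so strong pulses
        // cannot push the node into the instability guard
        for (size_t kk = 0; kk < snodes[s].size(); ++kk) {
          const int nd = snodes[s][kk];
          Vr[nd] = std::min(Vr[nd] + add, 1.1);
        }
      }
    }
    // gate relaxation (exact exponential toward 1 below gate, 0 above)
    for (int i = 0; i < n; ++i) {
      if (V[i] < v_gate) h[i] = 1.0 + (h[i] - 1.0) * eo;
      else h[i] *= ec[i];
    }
    // implicit diffusion
    for (int i = 0; i < n; ++i) rhs[i] = mdiag[i] * Vr[i];
    cg_solve(n, app, aip, axp, dinv.data(), rhs.data(), Vr.data(),
             r, z, p, q, 1e-9, 300);
    const double tnew = t0 + (step + 1) * dt;
    bool unstable = false;
    for (int i = 0; i < n; ++i) {
      const double vn = Vr[i];
      if (V[i] < act_thresh && vn >= act_thresh && nact[i] < max_act) {
        act_node.push_back(i + 1);
        act_time.push_back(tnew);
        ++nact[i];
      }
      V[i] = vn;
      if (vn > 2.0 || vn < -2.0 || !std::isfinite(vn)) unstable = true;
    }
    t = tnew;
    if (unstable) { stopped = "unstable"; ++step; break; }
    if ((step + 1) % check_every == 0) {
      if (watch_min > 0) {
        // count watched nodes whose latest activation is after watch_after
        watch_count = 0;
        std::fill(watched_hit.begin(), watched_hit.end(), 0);
        for (size_t a = 0; a < act_node.size(); ++a) {
          if (act_time[a] <= watch_after) continue;
          for (int w = 0; w < watch_nodes.size(); ++w)
            if (act_node[a] == watch_nodes[w] && !watched_hit[w]) {
              watched_hit[w] = 1; ++watch_count;
            }
        }
        if (watch_count >= watch_min) { stopped = "watch"; ++step; break; }
      }
      if (stop_on_quiescent && t > last_stim_end) {
        double vmax = 0.0;
        for (int i = 0; i < n; ++i) vmax = std::max(vmax, std::fabs(V[i]));
        if (vmax < quiesce_tol) { stopped = "quiescent"; ++step; break; }
      }
    }
  }
  return List::create(_["V"] = NumericVector(V.begin(), V.end()),
                      _["h"] = NumericVector(h.begin(), h.end()),
                      _["act_node"] = IntegerVector(act_node.begin(), act_node.end()),
                      _["act_time"] = NumericVector(act_time.begin(), act_time.end()),
                      _["t_end"] = t, _["stopped"] = stopped,
                      _["stable"] = (stopped != "unstable"));
}

// Single-cell (0D) integration of the same ionic model. Records every
// crossing of v_gate in both directions, for APD/restitution bookkeeping.
// [[Rcpp::export]]
List cpp_cell_run(double tau_in, double tau_out, double tau_open,
                  double tau_close, double v_gate, double dt, double duration,
                  NumericVector stim_start, double stim_dur, double stim_amp,
                  double V0, double h0) {
  const int nsteps = (int)std::lround(duration / dt);
  double V = V0, h = h0, t = 0.0;
  const double eo = std::exp(-dt / tau_open);
  const double ec = std::exp(-dt / tau_close);
  std::vector<double> up, down;
  int si = 0;
  const int nstim = stim_start.size();
  for (int step = 0; step < nsteps; ++step) {
    double I = 0.0;
    while (si < nstim && t >= stim_start[si] + stim_dur) ++si;
    for (int s = si; s < nstim && stim_start[s] <= t; ++s)
      if (t >= stim_start[s] && t < stim_start[s] + stim_dur) I = stim_amp;
    double dv = h * V * V * (1.0 - V) / tau_in - V / tau_out + I;
    double Vn = V + dt * dv;
    if (V < v_gate) h = 1.0 + (h - 1.0) * eo; else h *= ec;
    double tn = t + dt;
    if (V < v_gate && Vn >= v_gate) up.push_back(tn);
    if (V >= v_gate && Vn < v_gate) down.push_back(tn);
    V = Vn; t = tn;
  }
  return List::create(_["up"] = NumericVector(up.begin(), up.end()),
                      _["down"] = NumericVector(down.begin(), down.end()),
                      _["V"] = V, _["h"] = h);
}
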