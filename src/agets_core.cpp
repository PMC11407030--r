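// Computational core: brute-force kNN for point clouds, batched fixed-step
// RK4 integration of the 3-gene connectionist ODE with time-varying signal
// inputs, and the Gaussian log-likelihood used by the ensemble sampler.
// The integrator is written with scalar per-cell loops: the likelihood is
// evaluated ~1e5 times per MCMC run, so allocation-free inner loops matter.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// k nearest neighbours of each query point among the reference points,
// squared-Euclidean brute force. Ties at the k-th neighbour break by lowest
// reference index (stable ordering contract shared with the R oracle).
// [[Rcpp::export]]
List cpp_knn(const arma::mat& query, const arma::mat& ref, const int k) {
  const int nq = query.n_rows, nr = ref.n_rows;
  if (k < 1 || k > nr) stop("k must be between 1 and nrow(ref)");
  arma::imat idx(nq, k);
  arma::mat dist(nq, k);
  std::vector<std::pair<double, int>> d(nr);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j) {
      const double dx = query(i, 0) - ref(j, 0);
      const double dy = query(i, 1) - ref(j, 1);
      const double dz = query(i, 2) - ref(j, 2);
      d[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int m = 0; m < k; ++m) {
      idx(i, m) = d[m].second + 1;  // 1-based for R
      dist(i, m) = std::sqrt(d[m].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

static inline double phi_s(const double u) {
  return 0.5 * (u / std::sqrt(u * u + 1.0) + 1.0);
}

// dg_a/dt = R_a * phi(u_a) - lam_a * g_a with
// u_a = sum_b W(b,a) g_b + E(0,a) s0 + E(1,a) s1 + h_a
static inline void rhs3(const double* g, const double s0, const double s1,
                        const double* W, const double* E, const double* R,
                        const double* lam, const double* h, double* out) {
  for (int a = 0; a < 3; ++a) {
    const double u = W[a * 3 + 0] * g[0] + W[a * 3 + 1] * g[1] +
                     W[a * 3 + 2] * g[2] + E[a * 2 + 0] * s0 +
                     E[a * 2 + 1] * s1 + h[a];
    out[a] = R[a] * phi_s(u) - lam[a] * g[a];
  }
}

// One cell's RK4 integration over all frames; sig points at (nf x 2) for the
// cell (column-major within the cube slice), traj receives nf x 3 values
// (column-major: traj[a * nf + t]).
static bool integrate_cell(const double* g0, const double* sig, const int nf,
                           const double* W, const double* E, const double* R,
                           const double* lam, const double* h,
                           const double dt_frame, const int substeps,
                           double* traj) {
  double g[3] = {g0[0], g0[1], g0[2]};
  double k1[3], k2[3], k3[3], k4[3], gt[3];
  const double dt = dt_frame / substeps;
  for (int a = 0; a < 3; ++a) traj[a * nf] = g[a];
  for (int f = 0; f < nf - 1; ++f) {
    const double s0a = sig[f], s0b = sig[nf + f];
    const double d0 = (sig[f + 1] - s0a) / substeps;
    const double d1 = (sig[nf + f + 1] - s0b) / substeps;
    for (int m = 0; m < substeps; ++m) {
      const double sa0 = s0a + d0 * m, sa1 = s0b + d1 * m;
      const double sb0 = s0a + d0 * (m + 0.5), sb1 = s0b + d1 * (m + 0.5);
      const double sc0 = s0a + d0 * (m + 1.0), sc1 = s0b + d1 * (m + 1.0);
      rhs3(g, sa0, sa1, W, E, R, lam, h, k1);
      for (int a = 0; a < 3; ++a) gt[a] = g[a] + 0.5 * dt * k1[a];
      rhs3(gt, sb0, sb1, W, E, R, lam, h, k2);
      for (int a = 0; a < 3; ++a) gt[a] = g[a] + 0.5 * dt * k2[a];
      rhs3(gt, sb0, sb1, W, E, R, lam, h, k3);
      for (int a = 0; a < 3; ++a) gt[a] = g[a] + dt * k3[a];
      rhs3(gt, sc0, sc1, W, E, R, lam, h, k4);
      for (int a = 0; a < 3; ++a)
        g[a] += (dt / 6.0) * (k1[a] + 2.0 * k2[a] + 2.0 * k3[a] + k4[a]);
    }
    for (int a = 0; a < 3; ++a) {
      if (!std::isfinite(g[a])) return false;
      traj[a * nf + f + 1] = g[a];
    }
  }
  return true;
}

// Column-major parameter blocks as the scalar kernels expect them:
// W[a*3+b] = W(b,a), E[a*2+s] = E(s,a).
static void flatten_params(const arma::mat& W, const arma::mat& E,
                           double* w, double* e) {
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) w[a * 3 + b] = W(b, a);
    for (int s = 0; s < 2; ++s) e[a * 2 + s] = E(s, a);
  }
}

// Integrate the model in every cell. g0: 3 x C initial gene levels.
// signals: cube (n_frames x 2 x C), linearly interpolated inside each frame
// interval. Classical RK4 with `substeps` sub-steps per frame of length
// dt_frame. Returns cube (n_frames x 3 x C) sampled at the frame times.
// [[Rcpp::export]]
arma::cube cpp_simulate_cells(const arma::mat& g0, const arma::cube& signals,
                              const arma::mat& W, const arma::mat& E,
                              const arma::vec& R, const arma::vec& lam,
                              const arma::vec& h, const double dt_frame,
                              const int substeps) {
  const int nf = signals.n_rows, nc = signals.n_slices;
  if ((int)g0.n_cols != nc) stop("g0/signals cell-count mismatch");
  if (substeps < 1) stop("substeps must be >= 1");
  double w[9], e[6];
  flatten_params(W, E, w, e);
  arma::cube out(nf, 3, nc);
  for (int c = 0; c < nc; ++c) {
    const bool ok = integrate_cell(g0.colptr(c), signals.slice_colptr(c, 0),
                                   nf, w, e, R.memptr(), lam.memptr(),
                                   h.memptr(), dt_frame, substeps,
                                   out.slice_colptr(c, 0));
    if (!ok) stop("non-finite state during integration (cell %d)", c + 1);
  }
  return out;
}

// L = -0.5 * sum_a sum_c sum_t (T_atc - S_atc)^2 / sigma_a^2
// targets: cube (n_frames x 3 x C) of AGET gene values; the first frame of
// each target supplies the cell's initial condition.
// [[Rcpp::export]]
double cpp_log_likelihood(const arma::cube& targets, const arma::cube& signals,
                          const arma::mat& W, const arma::mat& E,
                          const arma::vec& R, const arma::vec& lam,
                          const arma::vec& h, const arma::vec& sigmas,
                          const double dt_frame, const int substeps) {
  for (int a = 0; a < 3; ++a)
    if (lam(a) <= 0.0) return -arma::datum::inf;
  const int nf = targets.n_rows, nc = targets.n_slices;
  double w[9], e[6];
  flatten_params(W, E, w, e);
  const double inv2s[3] = {0.5 / (sigmas(0) * sigmas(0)),
                           0.5 / (sigmas(1) * sigmas(1)),
                           0.5 / (sigmas(2) * sigmas(2))};
  std::vector<double> traj(nf * 3);
  double g0[3], ll = 0.0;
  for (int c = 0; c < nc; ++c) {
    const double* tgt = targets.slice_colptr(c, 0);
    for (int a = 0; a < 3; ++a) g0[a] = tgt[a * nf];
    const bool ok = integrate_cell(g0, signals.slice_colptr(c, 0), nf, w, e,
                                   R.memptr(), lam.memptr(), h.memptr(),
                                   dt_frame, substeps, traj.data());
    if (!ok) return -arma::datum::inf;
    for (int a = 0; a < 3; ++a) {
      double ss = 0.0;
      for (int t = 0; t < nf; ++t) {
        const double r = tgt[a * nf + t] - traj[a * nf + t];
        ss += r * r;
      }
      ll -= inv2s[a] * ss;
    }
  }
  return std::isfinite(ll) ? ll : -arma::datum::inf;
}
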