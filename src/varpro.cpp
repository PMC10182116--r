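// Voxelwise variable-projection (VARPRO) kernels for water-fat separation.
//
// The nonlinear parameters are the off-resonance frequency psi (Hz) and the
// common transverse decay rate r2* (1/ms).  For fixed (psi, r2*) the complex
// water and fat amplitudes enter linearly through the basis
//   a_n = exp(i 2 pi psi t_n - r2* t_n),   b_n = c_n a_n
// where c_n is the multi-peak fat phasor at echo n, so they are projected out
// analytically and the residual is minimised over (psi, r2*) only.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void make_basis(const vec& t_s, const vec& t_ms, const cx_vec& cn,
                              double psi, double r2, cx_vec& a, cx_vec& b) {
  vec ph = 2.0 * datum::pi * psi * t_s;
  vec dec = exp(-r2 * t_ms);
  a = cx_vec(dec % cos(ph), dec % sin(ph));
  b = cn % a;
}

// Projection residual for a single voxel; optionally returns the linear
// (complex) water/fat amplitudes at the optimum.
static inline double resid_one(const cx_vec& s, const cx_vec& a, const cx_vec& b,
                               cx_double* W = nullptr, cx_double* F = nullptr) {
  double g11 = std::real(cdot(a, a));
  cx_double g12 = cdot(a, b);
  double g22 = std::real(cdot(b, b));
  cx_double pa = cdot(a, s);
  cx_double pb = cdot(b, s);
  double det = g11 * g22 - std::norm(g12);
  double energy = std::real(cdot(s, s));
  if (det < 1e-300) {
    if (W) { *W = cx_double(0, 0); *F = cx_double(0, 0); }
    return energy;
  }
  cx_double x1 = (g22 * pa - g12 * pb) / det;
  cx_double x2 = (g11 * pb - std::conj(g12) * pa) / det;
  if (W) { *W = x1; *F = x2; }
  double expl = std::real(std::conj(x1) * pa + std::conj(x2) * pb);
  double r = energy - expl;
  return r > 0 ? r : 0.0;
}

// Brent's local 1-D minimiser on [ax, bx] (golden section with parabolic
// interpolation, cf. the classic localmin routine).
template <typename Fun>
static double brent_min(Fun f, double ax, double bx, double tol, double& fout) {
  const double gold = 0.3819660112501051;
  double a = ax, b = bx;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol + 1e-12 * std::fabs(x);
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool use_golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) && p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        use_golden = false;
      }
    }
    if (use_golden) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  fout = fx;
  return x;
}

// Grid evaluation of the VARPRO residual for all voxels at once.  The basis
// depends only on (psi, r2*), not on the voxel, so the projections reduce to
// two matrix-vector products per grid node.  Optionally returns the full
// psi-residual profile (minimised over the r2* grid), used for field-map
// candidate extraction.
// [[Rcpp::export]]
Rcpp::List varpro_grid_cpp(const arma::cx_mat& S, const arma::vec& t_s,
                           const arma::vec& t_ms, const arma::cx_vec& cn,
                           const arma::vec& psi_grid, const arma::vec& r2_grid,
                           bool profile) {
  const uword V = S.n_cols, P = psi_grid.n_elem, R = r2_grid.n_elem;
  rowvec energy = sum(square(abs(S)), 0);
  vec best_res(V); best_res.fill(datum::inf);
  uvec best_p(V, fill::zeros), best_r(V, fill::zeros);
  mat prof;
  if (profile) { prof.set_size(P, V); prof.fill(datum::inf); }
  cx_vec a, b;
  for (uword ip = 0; ip < P; ++ip) {
    for (uword ir = 0; ir < R; ++ir) {
      make_basis(t_s, t_ms, cn, psi_grid(ip), r2_grid(ir), a, b);
      double g11 = std::real(cdot(a, a));
      cx_double g12 = cdot(a, b);
      double g22 = std::real(cdot(b, b));
      double det = g11 * g22 - std::norm(g12);
      if (det < 1e-300) continue;
      cx_rowvec pa = trans(a) * S;
      cx_rowvec pb = trans(b) * S;
      for (uword v = 0; v < V; ++v) {
        cx_double A = pa(v), B = pb(v);
        cx_double x1 = (g22 * A - g12 * B) / det;
        cx_double x2 = (g11 * B - std::conj(g12) * A) / det;
        double expl = std::real(std::conj(x1) * A + std::conj(x2) * B);
        double r = energy(v) - expl;
        if (r < 0) r = 0;
        if (r < best_res(v)) { best_res(v) = r; best_p(v) = ip; best_r(v) = ir; }
        if (profile && r < prof(ip, v)) prof(ip, v) = r;
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("best_resid") = best_res,
      Rcpp::Named("best_psi_idx") = Rcpp::IntegerVector(best_p.begin(), best_p.end()),
      Rcpp::Named("best_r2_idx") = Rcpp::IntegerVector(best_r.begin(), best_r.end()),
      Rcpp::Named("energy") = vec(energy.t()));
  if (profile) out["profile"] = prof;
  return out;
}

// Per-voxel local refinement by alternating Brent line searches in psi
// (within psi0 +/- psi_hw) and r2* (within [0, r2_max]).  Convergence when
// the residual decrease falls below tol relative to the residual (with an
// absolute floor tied to the signal energy, so exact noiseless fits also
// terminate).
// [[Rcpp::export]]
Rcpp::List varpro_refine_cpp(const arma::cx_mat& S, const arma::vec& t_s,
                             const arma::vec& t_ms, const arma::cx_vec& cn,
                             const arma::vec& psi0, const arma::vec& r20,
                             double psi_hw, double r2_max, double tol, int maxit,
                             double psi_tol = 1e-7, double r2_tol = 1e-10) {
  const uword V = S.n_cols;
  vec psi_out(V), r2_out(V), res_out(V);
  cx_vec W_out(V), F_out(V);
  ivec conv(V, fill::zeros), iters(V, fill::zeros);
  cx_vec a, b;
  for (uword v = 0; v < V; ++v) {
    cx_vec s = S.col(v);
    double energy = std::real(cdot(s, s));
    if (energy <= 0.0) {
      psi_out(v) = psi0(v); r2_out(v) = 0.0; res_out(v) = 0.0;
      W_out(v) = cx_double(0, 0); F_out(v) = cx_double(0, 0);
      conv(v) = 0; iters(v) = 0;
      continue;
    }
    double psi = psi0(v), r2 = r20(v);
    if (r2 < 0) r2 = 0;
    if (r2 > r2_max) r2 = r2_max;
    auto f_joint = [&](double p, double r) {
      make_basis(t_s, t_ms, cn, p, r, a, b);
      return resid_one(s, a, b);
    };
    double res = f_joint(psi, r2);
    int it = 0;
    bool ok = false;
    double floor_abs = 1e-14 * energy;
    for (it = 1; it <= maxit; ++it) {
      double prev = res;
      double fp;
      // first pass searches the full windows; later passes contract around
      // the current iterate (the psi/r2 coupling is weak, so the optimum
      // stays inside the contracted windows)
      double p_lo = psi0(v) - psi_hw, p_hi = psi0(v) + psi_hw;
      double r_lo = 0.0, r_hi = r2_max;
      if (it > 1) {
        double p_w = std::max(2.0, psi_hw / 8.0);
        p_lo = std::max(p_lo, psi - p_w);
        p_hi = std::min(p_hi, psi + p_w);
        double r_w = std::max(0.03, 0.5 * r2);
        r_lo = std::max(0.0, r2 - r_w);
        r_hi = std::min(r2_max, r2 + r_w);
      }
      psi = brent_min([&](double p) { return f_joint(p, r2); },
                      p_lo, p_hi, psi_tol, fp);
      r2 = brent_min([&](double r) { return f_joint(psi, r); },
                     r_lo, r_hi, r2_tol, fp);
      res = fp;
      if (prev - res <= tol * prev + floor_abs || res <= floor_abs) { ok = true; break; }
    }
    cx_double Wv, Fv;
    make_basis(t_s, t_ms, cn, psi, r2, a, b);
    res = resid_one(s, a, b, &Wv, &Fv);
    psi_out(v) = psi; r2_out(v) = r2; res_out(v) = res;
    W_out(v) = Wv; F_out(v) = Fv;
    conv(v) = ok ? 1 : 0; iters(v) = it;
  }
  return Rcpp::List::create(
      Rcpp::Named("psi_Hz") = psi_out,
      Rcpp::Named("r2star_per_ms") = r2_out,
      Rcpp::Named("water") = W_out,
      Rcpp::Named("fat") = F_out,
      Rcpp::Named("resid") = res_out,
      Rcpp::Named("converged") = Rcpp::IntegerVector(conv.begin(), conv.end()),
      Rcpp::Named("iterations") = Rcpp::IntegerVector(iters.begin(), iters.end()));
}

// ---- 3-D mask utilities (26-connectivity) --------------------------------

static inline void neighbours26(int idx, int nx, int ny, int nz,
                                std::vector<int>& out) {
  out.clear();
  int k = idx / (nx * ny);
  int rem = idx - k * nx * ny;
  int j = rem / nx;
  int i = rem - j * nx;
  for (int dk = -1; dk <= 1; ++dk) {
    int kk = k + dk; if (kk < 0 || kk >= nz) continue;
    for (int dj = -1; dj <= 1; ++dj) {
      int jj = j + dj; if (jj < 0 || jj >= ny) continue;
      for (int di = -1; di <= 1; ++di) {
        int ii = i + di; if (ii < 0 || ii >= nx) continue;
        if (di == 0 && dj == 0 && dk == 0) continue;
        out.push_back(ii + nx * (jj + ny * kk));
      }
    }
  }
}

// Connected component of `mask` containing `seed` (1-based linear index).
// [[Rcpp::export]]
Rcpp::LogicalVector flood_component_cpp(Rcpp::LogicalVector mask,
                                        Rcpp::IntegerVector dims, int seed) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  Rcpp::LogicalVector out(n, false);
  int s = seed - 1;
  if (s < 0 || s >= n || !mask[s]) return out;
  std::vector<char> seen(n, 0);
  std::queue<int> q;
  q.push(s); seen[s] = 1;
  std::vector<int> nb; nb.reserve(26);
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    out[cur] = true;
    neighbours26(cur, nx, ny, nz, nb);
    for (int m : nb) {
      if (!seen[m] && mask[m]) { seen[m] = 1; q.push(m); }
    }
  }
  return out;
}

// Simultaneous breadth-first growth of all labelled voxels into the
// `allowed` region: each reachable allowed voxel receives the label of the
// nearest front (ties resolved by deterministic queue order).
// [[Rcpp::export]]
Rcpp::IntegerVector multilabel_grow_cpp(Rcpp::IntegerVector labels,
                                        Rcpp::LogicalVector allowed,
                                        Rcpp::IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  Rcpp::IntegerVector out = Rcpp::clone(labels);
  std::queue<int> q;
  for (int i = 0; i < n; ++i) if (out[i] > 0) q.push(i);
  std::vector<int> nb; nb.reserve(26);
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    neighbours26(cur, nx, ny, nz, nb);
    for (int m : nb) {
      if (out[m] == 0 && allowed[m]) { out[m] = out[cur]; q.push(m); }
    }
  }
  return out;
}
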