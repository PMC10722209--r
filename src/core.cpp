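// Low-level voxel kernels: connected components, Laplace and transport
// solvers, streamline integration, distance transforms, slice-wise convex
// hulls, local variance. All grids are column-major (i fastest), 0-based
// here, matching R arrays of dim c(nx, ny, nz).
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <queue>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ---------------------------------------------------------------------------
// Connected components (6- or 26-connectivity), BFS labelling.
// Labels are assigned in order of the first (lowest linear index) voxel of
// each component, so ties elsewhere are reproducible.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        offs.push_back({di, dj, dk});
      }
  int next = 0;
  std::queue<int> q;
  for (int v = 0; v < n; ++v) {
    if (!mask[v] || lab[v]) continue;
    ++next;
    lab[v] = next;
    q.push(v);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int ci = c % nx, cj = (c / nx) % ny, ck = c / (nx * ny);
      for (auto &o : offs) {
        int i = ci + o[0], j = cj + o[1], k = ck + o[2];
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
        int w = idx3(i, j, k, nx, ny);
        if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Laplace solver on a coded grid.
// codes: 0 = outside (zero-flux), 1 = solve, 2 = Dirichlet value 0 at the
// shared face (reflection ghost), 3 = Dirichlet value 1 at the face,
// 4 = voxel fixed at 0, 5 = voxel fixed at 1.
// Red-black Gauss-Seidel with optional over-relaxation, or Jacobi.
// Neighbour weights are 1/spacing^2 per axis; face-Dirichlet neighbours act
// as value v* with doubled weight (u_ghost = 2 v* - u_c).
// [[Rcpp::export]]
List cpp_laplace(IntegerVector codes, IntegerVector dim, NumericVector spacing,
                 double tol, int max_iter, double omega, bool jacobi,
                 Nullable<NumericVector> init = R_NilValue) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  NumericVector u(n, 0.5);
  if (init.isNotNull()) {
    NumericVector u0(init);
    for (int v = 0; v < n; ++v) u[v] = u0[v];
  }
  for (int v = 0; v < n; ++v) {
    if (codes[v] == 4) u[v] = 0.0;
    else if (codes[v] == 5) u[v] = 1.0;
    else if (codes[v] == 0) u[v] = NA_REAL;
  }
  double wx = 1.0 / (spacing[0] * spacing[0]);
  double wy = 1.0 / (spacing[1] * spacing[1]);
  double wz = 1.0 / (spacing[2] * spacing[2]);
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  const double wts[6] = {wx, wx, wy, wy, wz, wz};
  // Precompute the active stencil: per solve voxel, the tissue-neighbour
  // indices/weights and the constant Dirichlet-face contribution.
  struct Stencil { int v; double inv_den, cnum; int nnb; int nb[6]; double wnb[6]; };
  std::vector<Stencil> red, black, all;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = idx3(i, j, k, nx, ny);
        if (codes[v] != 1) continue;
        Stencil st; st.v = v; st.cnum = 0.0; st.nnb = 0;
        double den = 0.0;
        for (int t = 0; t < 6; ++t) {
          int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;  // grid edge: zero-flux
          int w = idx3(ii, jj, kk, nx, ny);
          int cw = codes[w];
          double wt = wts[t];
          if (cw == 0) continue;               // zero-flux (mirror)
          if (cw == 2) { den += 2.0 * wt; }    // face value 0
          else if (cw == 3) { st.cnum += 2.0 * wt; den += 2.0 * wt; }
          else { st.nb[st.nnb] = w; st.wnb[st.nnb] = wt; ++st.nnb; den += wt; }
        }
        st.inv_den = den > 0 ? 1.0 / den : 0.0;
        if (jacobi) all.push_back(st);
        else if (((i + j + k) & 1) == 0) red.push_back(st);
        else black.push_back(st);
      }
  std::vector<double> ubuf;
  if (jacobi) ubuf.resize(n);
  double *up = REAL(u);
  double maxupd = R_PosInf;
  int iter = 0;
  auto sweep = [&](const std::vector<Stencil> &set, const double *src) {
    for (const Stencil &st : set) {
      if (st.inv_den == 0.0) continue;         // isolated voxel: keep value
      double num = st.cnum;
      for (int t = 0; t < st.nnb; ++t) num += st.wnb[t] * src[st.nb[t]];
      double upd = omega * (num * st.inv_den - up[st.v]);
      up[st.v] += upd;
      double au = std::abs(upd);
      if (au > maxupd || std::isnan(au)) maxupd = au;
    }
  };
  while (iter < max_iter && maxupd > tol) {
    maxupd = 0.0;
    ++iter;
    if (jacobi) {
      std::copy(up, up + n, ubuf.begin());
      sweep(all, ubuf.data());
    } else {
      sweep(red, up);
      sweep(black, up);
    }
  }
  for (int v = 0; v < n; ++v)
    if (codes[v] == 2 || codes[v] == 3) u[v] = NA_REAL;
  u.attr("dim") = dim;
  return List::create(_["u"] = u, _["iterations"] = iter, _["residual"] = maxupd);
}

// ---------------------------------------------------------------------------
// Physical gradient of u on the tissue domain with the same ghost
// conventions as cpp_laplace, normalised to a unit tangent field.
// Returns Tx,Ty,Tz (zero off tissue), gradient norm, degenerate mask.
// [[Rcpp::export]]
List cpp_tangent(NumericVector u, IntegerVector codes, IntegerVector dim,
                 NumericVector spacing, double eps_grad) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  NumericVector Tx(n, 0.0), Ty(n, 0.0), Tz(n, 0.0), gn(n, 0.0);
  IntegerVector degen(n, 0);
  const int di[3] = {1, 0, 0};
  const int dj[3] = {0, 1, 0};
  const int dk[3] = {0, 0, 1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = idx3(i, j, k, nx, ny);
        if (codes[v] != 1) continue;
        double uc = u[v], g[3];
        for (int a = 0; a < 3; ++a) {
          double up = NA_REAL, um = NA_REAL;
          int ip = i + di[a], jp = j + dj[a], kp = k + dk[a];
          int im = i - di[a], jm = j - dj[a], km = k - dk[a];
          if (ip < nx && jp < ny && kp < nz) {
            int w = idx3(ip, jp, kp, nx, ny);
            int cw = codes[w];
            if (cw == 1 || cw == 4 || cw == 5) up = u[w];
            else if (cw == 2) up = -uc;
            else if (cw == 3) up = 2.0 - uc;
          }
          if (im >= 0 && jm >= 0 && km >= 0) {
            int w = idx3(im, jm, km, nx, ny);
            int cw = codes[w];
            if (cw == 1 || cw == 4 || cw == 5) um = u[w];
            else if (cw == 2) um = -uc;
            else if (cw == 3) um = 2.0 - uc;
          }
          double s = spacing[a];
          if (!ISNAN(up) && !ISNAN(um)) g[a] = (up - um) / (2.0 * s);
          else if (!ISNAN(up)) g[a] = (up - uc) / s;
          else if (!ISNAN(um)) g[a] = (uc - um) / s;
          else g[a] = 0.0;
        }
        double nm = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
        gn[v] = nm;
        if (nm < eps_grad) { degen[v] = 1; continue; }
        Tx[v] = g[0] / nm; Ty[v] = g[1] / nm; Tz[v] = g[2] / nm;
      }
  Tx.attr("dim") = dim; Ty.attr("dim") = dim; Tz.attr("dim") = dim;
  gn.attr("dim") = dim; degen.attr("dim") = dim;
  return List::create(_["Tx"] = Tx, _["Ty"] = Ty, _["Tz"] = Tz,
                      _["grad_norm"] = gn, _["degenerate"] = degen);
}

// ---------------------------------------------------------------------------
// First-order upwind transport solver for grad(L) . T = 1 (dir = -1, L0,
// boundary value at exit_code faces) or -grad(L) . T = 1 (dir = +1, L1).
// The upwind neighbour along axis a sits at index + dir*sign(T_a).
// Exit faces contribute the half-voxel-corrected value -spacing/2.
// Gauss-Seidel sweeps alternating over the 8 axis orderings.
// [[Rcpp::export]]
List cpp_transport(NumericVector Tx, NumericVector Ty, NumericVector Tz,
                   IntegerVector codes, IntegerVector dim, NumericVector spacing,
                   int dir, int exit_code, double tol, int max_iter,
                   IntegerVector degen) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  NumericVector L(n, NA_REAL);
  IntegerVector flag(n, 0);
  std::vector<int> solve_idx;
  for (int v = 0; v < n; ++v)
    if (codes[v] == 1) { L[v] = 0.0; solve_idx.push_back(v); if (degen[v]) flag[v] = 1; }
  double maxupd = R_PosInf;
  int iter = 0;
  while (iter < max_iter && maxupd > tol) {
    maxupd = 0.0;
    int ord = iter & 7;  // sweep ordering: bits flip i/j/k direction
    ++iter;
    int k0 = (ord & 4) ? nz - 1 : 0, kstep = (ord & 4) ? -1 : 1;
    int j0 = (ord & 2) ? ny - 1 : 0, jstep = (ord & 2) ? -1 : 1;
    int i0 = (ord & 1) ? nx - 1 : 0, istep = (ord & 1) ? -1 : 1;
    for (int k = k0; k >= 0 && k < nz; k += kstep)
      for (int j = j0; j >= 0 && j < ny; j += jstep)
        for (int i = i0; i >= 0 && i < nx; i += istep) {
          int v = idx3(i, j, k, nx, ny);
          if (codes[v] != 1 || flag[v]) continue;
          double Tv[3] = {Tx[v], Ty[v], Tz[v]};
          double num = 1.0, den = 0.0;
          for (int a = 0; a < 3; ++a) {
            double t = Tv[a];
            if (t == 0.0) continue;
            int step = dir * (t > 0 ? 1 : -1);
            int ii = i + (a == 0 ? step : 0);
            int jj = j + (a == 1 ? step : 0);
            int kk = k + (a == 2 ? step : 0);
            double w = std::abs(t) / spacing[a];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;  // leaves the grid with no boundary: drop axis
            int nb = idx3(ii, jj, kk, nx, ny);
            int cn = codes[nb];
            if (cn == 1) {
              if (flag[nb]) continue;
              num += w * L[nb]; den += w;
            } else if (cn == exit_code) {
              num += w * (-spacing[a] / 2.0); den += w;
            }
            // other ghost types / unlabeled outside: zero-flux, drop axis
          }
          if (den <= 0) { flag[v] = 1; continue; }
          double Lnew = num / den;
          double upd = std::abs(Lnew - L[v]);
          L[v] = Lnew;
          if (upd > maxupd) maxupd = upd;
        }
  }
  // fill flagged voxels by repeated 6-neighbour averaging of solved values
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  int n_flag = 0;
  for (int v : solve_idx) if (flag[v]) ++n_flag;
  int fill_pass = 0;
  std::vector<char> filled(n, 0);
  for (int v : solve_idx) filled[v] = flag[v] ? 0 : 1;
  int remaining = n_flag;
  while (remaining > 0 && fill_pass < 64) {
    ++fill_pass;
    std::vector<int> newly;
    for (int v : solve_idx) {
      if (filled[v]) continue;
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      double s = 0; int c = 0;
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        int w = idx3(ii, jj, kk, nx, ny);
        if (codes[w] == 1 && filled[w]) { s += L[w]; ++c; }
      }
      if (c > 0) { L[v] = s / c; newly.push_back(v); }
    }
    if (newly.empty()) break;
    for (int v : newly) filled[v] = 1;
    remaining -= (int)newly.size();
  }
  L.attr("dim") = dim; flag.attr("dim") = dim;
  return List::create(_["L"] = L, _["iterations"] = iter, _["residual"] = maxupd,
                      _["flagged"] = flag, _["n_flagged"] = n_flag);
}

// ---------------------------------------------------------------------------
// Extend a vector field defined on `defined` voxels outward by `passes`
// rounds of 6-neighbour averaging (then renormalised), so trilinear
// interpolation near the tissue boundary has support.
// [[Rcpp::export]]
List cpp_extend_field(NumericVector Tx, NumericVector Ty, NumericVector Tz,
                      IntegerVector defined, IntegerVector dim, int passes) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  NumericVector ex = clone(Tx), ey = clone(Ty), ez = clone(Tz);
  std::vector<char> def(n);
  for (int v = 0; v < n; ++v) def[v] = defined[v] ? 1 : 0;
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (int p = 0; p < passes; ++p) {
    std::vector<int> newly;
    std::vector<double> vx, vy, vz;
    for (int v = 0; v < n; ++v) {
      if (def[v]) continue;
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      double sx = 0, sy = 0, sz = 0; int c = 0;
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        int w = idx3(ii, jj, kk, nx, ny);
        if (def[w]) { sx += ex[w]; sy += ey[w]; sz += ez[w]; ++c; }
      }
      if (c > 0) {
        double nm = std::sqrt(sx * sx + sy * sy + sz * sz);
        if (nm > 1e-12) { sx /= nm; sy /= nm; sz /= nm; }
        newly.push_back(v); vx.push_back(sx); vy.push_back(sy); vz.push_back(sz);
      }
    }
    for (size_t q = 0; q < newly.size(); ++q) {
      ex[newly[q]] = vx[q]; ey[newly[q]] = vy[q]; ez[newly[q]] = vz[q];
      def[newly[q]] = 1;
    }
  }
  ex.attr("dim") = dim; ey.attr("dim") = dim; ez.attr("dim") = dim;
  return List::create(_["Tx"] = ex, _["Ty"] = ey, _["Tz"] = ez);
}

static inline double trilin(const double *f, int nx, int ny, int nz,
                            double qx, double qy, double qz) {
  // q in voxel-centre coordinates: grid node i holds value at centre i
  int i0 = (int)std::floor(qx), j0 = (int)std::floor(qy), k0 = (int)std::floor(qz);
  double fx = qx - i0, fy = qy - j0, fz = qz - k0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        int i = std::min(std::max(i0 + di, 0), nx - 1);
        int j = std::min(std::max(j0 + dj, 0), ny - 1);
        int k = std::min(std::max(k0 + dk, 0), nz - 1);
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        acc += w * f[idx3(i, j, k, nx, ny)];
      }
  return acc;
}

// ---------------------------------------------------------------------------
// Streamline thickness: from every tissue voxel centre, integrate the unit
// tangent field forward (+T, to the epicardium) and backward (-T, to the
// endocardium) with fixed-step midpoint (RK2) integration and trilinear
// interpolation; the tissue exit point is refined by bisection.
// Returns arc lengths L0 (backward), L1 (forward), W = L0+L1, unresolved flag.
// [[Rcpp::export]]
List cpp_streamline(NumericVector Tx, NumericVector Ty, NumericVector Tz,
                    IntegerVector tissue, IntegerVector dim, NumericVector spacing,
                    double step_mm, int max_steps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  const double *tx = REAL(Tx), *ty = REAL(Ty), *tz = REAL(Tz);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector L0(n, NA_REAL), L1(n, NA_REAL), W(n, NA_REAL);
  IntegerVector unres(n, 0);
  auto inside = [&](double px, double py, double pz) -> bool {
    int i = (int)std::floor(px / sx), j = (int)std::floor(py / sy), kk = (int)std::floor(pz / sz);
    if (i < 0 || j < 0 || kk < 0 || i >= nx || j >= ny || kk >= nz) return false;
    return tissue[idx3(i, j, kk, nx, ny)] != 0;
  };
  auto sampleT = [&](double px, double py, double pz, double out[3]) {
    double qx = px / sx - 0.5, qy = py / sy - 0.5, qz = pz / sz - 0.5;
    out[0] = trilin(tx, nx, ny, nz, qx, qy, qz);
    out[1] = trilin(ty, nx, ny, nz, qx, qy, qz);
    out[2] = trilin(tz, nx, ny, nz, qx, qy, qz);
    double nm = std::sqrt(out[0] * out[0] + out[1] * out[1] + out[2] * out[2]);
    if (nm > 1e-12) { out[0] /= nm; out[1] /= nm; out[2] /= nm; }
    return nm;
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = idx3(i, j, k, nx, ny);
        if (!tissue[v]) continue;
        double lens[2];
        bool ok = true;
        for (int d = 0; d < 2; ++d) {
          double sgn = (d == 0) ? -1.0 : 1.0;  // backward to endo, forward to epi
          double px = (i + 0.5) * sx, py = (j + 0.5) * sy, pz = (k + 0.5) * sz;
          double len = 0.0;
          int st;
          for (st = 0; st < max_steps; ++st) {
            double v1[3];
            double nm1 = sampleT(px, py, pz, v1);
            if (nm1 < 1e-12) { ok = false; break; }
            double mx = px + sgn * 0.5 * step_mm * v1[0];
            double my = py + sgn * 0.5 * step_mm * v1[1];
            double mz = pz + sgn * 0.5 * step_mm * v1[2];
            double v2[3];
            double nm2 = sampleT(mx, my, mz, v2);
            if (nm2 < 1e-12) { v2[0] = v1[0]; v2[1] = v1[1]; v2[2] = v1[2]; }
            double qx = px + sgn * step_mm * v2[0];
            double qy = py + sgn * step_mm * v2[1];
            double qz = pz + sgn * step_mm * v2[2];
            if (!inside(qx, qy, qz)) {
              // bisect the crossing on the final segment
              double a = 0.0, b = 1.0;
              for (int it = 0; it < 24; ++it) {
                double m = 0.5 * (a + b);
                if (inside(px + m * (qx - px), py + m * (qy - py), pz + m * (qz - pz))) a = m;
                else b = m;
              }
              len += 0.5 * (a + b) * step_mm;
              break;
            }
            px = qx; py = qy; pz = qz;
            len += step_mm;
          }
          if (st >= max_steps) ok = false;
          if (!ok) break;
          lens[d] = len;
        }
        if (ok) { L0[v] = lens[0]; L1[v] = lens[1]; W[v] = lens[0] + lens[1]; }
        else unres[v] = 1;
      }
  L0.attr("dim") = dim; L1.attr("dim") = dim; W.attr("dim") = dim; unres.attr("dim") = dim;
  return List::create(_["L0"] = L0, _["L1"] = L1, _["W"] = W, _["unresolved"] = unres);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope), anisotropic spacing, distance to the nearest target voxel
// centre in mm, over the whole grid.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 const std::vector<double> &x, int n) {
  std::vector<int> vv(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  vv[0] = 0;
  zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    if (f[q] == std::numeric_limits<double>::infinity()) continue;
    while (true) {
      if (f[vv[k]] == std::numeric_limits<double>::infinity()) {
        // previous parabola absent: replace
        if (k == 0) { vv[0] = q; break; }
        --k; continue;
      }
      double s = ((f[q] + x[q] * x[q]) - (f[vv[k]] + x[vv[k]] * x[vv[k]])) /
                 (2 * x[q] - 2 * x[vv[k]]);
      if (s <= zz[k]) { --k; continue; }
      ++k; vv[k] = q; zz[k] = s; zz[k + 1] = std::numeric_limits<double>::infinity();
      break;
    }
  }
  if (f[vv[0]] == std::numeric_limits<double>::infinity()) {
    for (int q = 0; q < n; ++q) d[q] = std::numeric_limits<double>::infinity();
    return;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[kk + 1] < x[q]) ++kk;
    d[q] = (x[q] - x[vv[kk]]) * (x[q] - x[vv[kk]]) + f[vv[kk]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector target, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D(n);
  for (int v = 0; v < n; ++v) D[v] = target[v] ? 0.0 : INF;
  // pass along x
  {
    std::vector<double> f(nx), d(nx), x(nx);
    for (int i = 0; i < nx; ++i) x[i] = i * spacing[0];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) f[i] = D[idx3(i, j, k, nx, ny)];
        dt1d(f, d, x, nx);
        for (int i = 0; i < nx; ++i) D[idx3(i, j, k, nx, ny)] = d[i];
      }
  }
  {
    std::vector<double> f(ny), d(ny), x(ny);
    for (int j = 0; j < ny; ++j) x[j] = j * spacing[1];
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) f[j] = D[idx3(i, j, k, nx, ny)];
        dt1d(f, d, x, ny);
        for (int j = 0; j < ny; ++j) D[idx3(i, j, k, nx, ny)] = d[j];
      }
  }
  {
    std::vector<double> f(nz), d(nz), x(nz);
    for (int k = 0; k < nz; ++k) x[k] = k * spacing[2];
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) f[k] = D[idx3(i, j, k, nx, ny)];
        dt1d(f, d, x, nz);
        for (int k = 0; k < nz; ++k) D[idx3(i, j, k, nx, ny)] = d[k];
      }
  }
  NumericVector out(n);
  for (int v = 0; v < n; ++v) out[v] = std::isfinite(D[v]) ? std::sqrt(D[v]) : NA_REAL;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Slice-wise 2D convex hull fill (exact integer tests) intersected over the
// three principal axes.
typedef std::pair<long long, long long> P2;
static long long cross2(const P2 &o, const P2 &a, const P2 &b) {
  return (a.first - o.first) * (b.second - o.second) -
         (a.second - o.second) * (b.first - o.first);
}
static std::vector<P2> hull2d(std::vector<P2> pts) {
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  int m = (int)pts.size();
  if (m <= 2) return pts;
  std::vector<P2> h(2 * m);
  int k = 0;
  for (int i = 0; i < m; ++i) {
    while (k >= 2 && cross2(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  int lower = k + 1;
  for (int i = m - 2; i >= 0; --i) {
    while (k >= lower && cross2(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  h.resize(k - 1);
  return h;  // counter-clockwise, no repeated first point
}
static void fill_slice(const std::vector<P2> &pts, std::vector<char> &out,
                       int na, int nb) {
  // out is na x nb slice buffer (a fastest)
  std::vector<P2> h = hull2d(pts);
  int m = (int)h.size();
  if (m == 0) return;
  if (m == 1) { out[h[0].first + na * h[0].second] = 1; return; }
  if (m == 2) {
    long long dx = h[1].first - h[0].first, dy = h[1].second - h[0].second;
    long long amin = std::min(h[0].first, h[1].first), amax = std::max(h[0].first, h[1].first);
    long long bmin = std::min(h[0].second, h[1].second), bmax = std::max(h[0].second, h[1].second);
    for (long long b = bmin; b <= bmax; ++b)
      for (long long a = amin; a <= amax; ++a) {
        long long cr = (a - h[0].first) * dy - (b - h[0].second) * dx;
        if (cr == 0) out[a + na * b] = 1;
      }
    return;
  }
  long long amin = h[0].first, amax = h[0].first, bmin = h[0].second, bmax = h[0].second;
  for (auto &p : h) {
    amin = std::min(amin, p.first); amax = std::max(amax, p.first);
    bmin = std::min(bmin, p.second); bmax = std::max(bmax, p.second);
  }
  for (long long b = bmin; b <= bmax; ++b)
    for (long long a = amin; a <= amax; ++a) {
      P2 q(a, b);
      bool in = true;
      for (int e = 0; e < m; ++e) {
        if (cross2(h[e], h[(e + 1) % m], q) < 0) { in = false; break; }
      }
      if (in) out[a + na * b] = 1;
    }
}
// [[Rcpp::export]]
IntegerVector cpp_multiplanar_hull(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  IntegerVector hull(n, 0);
  std::vector<char> acc(n, 1);
  // axis 0: slices i = const, points (j,k); axis 1: j const, (i,k); axis 2: k const, (i,j)
  for (int axis = 0; axis < 3; ++axis) {
    int ns = (axis == 0) ? nx : (axis == 1) ? ny : nz;
    int na = (axis == 0) ? ny : nx;
    int nb = (axis == 2) ? ny : nz;
    std::vector<char> filled(n, 0);
    for (int s = 0; s < ns; ++s) {
      std::vector<P2> pts;
      std::vector<char> sl(na * nb, 0);
      for (int b = 0; b < nb; ++b)
        for (int a = 0; a < na; ++a) {
          int i = (axis == 0) ? s : a;
          int j = (axis == 0) ? a : (axis == 2) ? b : s;
          int k = (axis == 2) ? s : b;
          if (mask[idx3(i, j, k, nx, ny)]) pts.push_back(P2(a, b));
        }
      if (!pts.empty()) fill_slice(pts, sl, na, nb);
      for (int b = 0; b < nb; ++b)
        for (int a = 0; a < na; ++a) {
          if (!sl[a + na * b]) continue;
          int i = (axis == 0) ? s : a;
          int j = (axis == 0) ? a : (axis == 2) ? b : s;
          int k = (axis == 2) ? s : b;
          filled[idx3(i, j, k, nx, ny)] = 1;
        }
    }
    for (int v = 0; v < n; ++v) acc[v] = acc[v] && filled[v];
  }
  for (int v = 0; v < n; ++v) hull[v] = acc[v] ? 1 : 0;
  hull.attr("dim") = dim;
  return hull;
}

// Per-slice hull vertices over one axis (candidates for 3D hull vertices).
// [[Rcpp::export]]
IntegerMatrix cpp_slice_hull_vertices(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<std::array<int,3>> verts;
  for (int k = 0; k < nz; ++k) {
    std::vector<P2> pts;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (mask[idx3(i, j, k, nx, ny)]) pts.push_back(P2(i, j));
    std::vector<P2> h = hull2d(pts);
    for (auto &p : h) verts.push_back({(int)p.first, (int)p.second, k});
  }
  IntegerMatrix out((int)verts.size(), 3);
  for (size_t r = 0; r < verts.size(); ++r)
    for (int c = 0; c < 3; ++c) out(r, c) = verts[r][c];
  return out;
}

// Exact 3D convex-hull membership for integer points: enumerate supporting
// planes over all candidate-vertex triples (exact int64 arithmetic), then
// test each query against every supporting half-space. Intended for small
// to moderate candidate sets (per-slice hull vertices).
// [[Rcpp::export]]
LogicalVector cpp_in_hull_exact(IntegerMatrix queries, IntegerMatrix pts) {
  int np = pts.nrow(), nq = queries.nrow();
  LogicalVector out(nq);
  if (np == 0) return out;
  typedef std::array<long long, 4> Plane;  // nx, ny, nz, d with n.p >= d inside
  std::vector<Plane> planes;
  auto addPlane = [&](long long nx, long long ny, long long nz, long long d) {
    long long g = std::abs(nx);
    auto gcd = [](long long a, long long b) {
      a = std::abs(a); b = std::abs(b);
      while (b) { long long t = a % b; a = b; b = t; }
      return a;
    };
    g = gcd(gcd(nx, ny), gcd(nz, d));
    if (g > 1) { nx /= g; ny /= g; nz /= g; d /= g; }
    Plane pl = {nx, ny, nz, d};
    for (auto &e : planes) if (e == pl) return;
    planes.push_back(pl);
  };
  for (int i = 0; i < np; ++i)
    for (int j = i + 1; j < np; ++j)
      for (int k = j + 1; k < np; ++k) {
        long long ax = pts(i,0), ay = pts(i,1), az = pts(i,2);
        long long ux = pts(j,0)-ax, uy = pts(j,1)-ay, uz = pts(j,2)-az;
        long long vx = pts(k,0)-ax, vy = pts(k,1)-ay, vz = pts(k,2)-az;
        long long nx = uy*vz - uz*vy, ny = uz*vx - ux*vz, nz = ux*vy - uy*vx;
        if (nx == 0 && ny == 0 && nz == 0) continue;
        bool anyPos = false, anyNeg = false;
        for (int p = 0; p < np; ++p) {
          long long s = nx*(pts(p,0)-ax) + ny*(pts(p,1)-ay) + nz*(pts(p,2)-az);
          if (s > 0) anyPos = true;
          else if (s < 0) anyNeg = true;
          if (anyPos && anyNeg) break;
        }
        if (anyPos && anyNeg) continue;
        long long d = nx*ax + ny*ay + nz*az;
        if (!anyNeg) addPlane(nx, ny, nz, d);      // all on >= side: inward normal
        if (!anyPos) addPlane(-nx, -ny, -nz, -d);  // all on <= side
      }
  for (int q = 0; q < nq; ++q) {
    long long x = queries(q,0), y = queries(q,1), z = queries(q,2);
    bool in = true;
    for (auto &pl : planes)
      if (pl[0]*x + pl[1]*y + pl[2]*z < pl[3]) { in = false; break; }
    out[q] = in;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local population variance of W over in-mask voxels within an index-space
// Euclidean radius (the voxel itself included).
// [[Rcpp::export]]
NumericVector cpp_local_variance(NumericVector W, IntegerVector mask,
                                 IntegerVector dim, double radius_px) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  int r = (int)std::floor(radius_px);
  double r2 = radius_px * radius_px;
  std::vector<std::array<int,3>> offs;
  for (int dk = -r; dk <= r; ++dk)
    for (int dj = -r; dj <= r; ++dj)
      for (int di = -r; di <= r; ++di)
        if (di * di + dj * dj + dk * dk <= r2) offs.push_back({di, dj, dk});
  NumericVector out(n, NA_REAL);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = idx3(i, j, k, nx, ny);
        if (!mask[v]) continue;
        // two-pass for numerical exactness (constant fields give exactly 0)
        double s = 0; int c = 0;
        double lo = R_PosInf, hi = R_NegInf;
        for (auto &o : offs) {
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          int w = idx3(ii, jj, kk, nx, ny);
          if (mask[w]) {
            s += W[w]; ++c;
            if (W[w] < lo) lo = W[w];
            if (W[w] > hi) hi = W[w];
          }
        }
        if (lo == hi) { out[v] = 0.0; continue; }
        double mean = s / c, ss = 0;
        for (auto &o : offs) {
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          int w = idx3(ii, jj, kk, nx, ny);
          if (mask[w]) { double d = W[w] - mean; ss += d * d; }
        }
        out[v] = ss / c;
      }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Minimum Euclidean distance from each query point to a point cloud (mm).
// Used by the ellipsoid ground-truth oracle (dense surface sampling).
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix queries, NumericMatrix pts) {
  int nq = queries.nrow(), np = pts.nrow();
  NumericVector out(nq);
  std::vector<double> px(np), py(np), pz(np);
  for (int p = 0; p < np; ++p) { px[p] = pts(p, 0); py[p] = pts(p, 1); pz[p] = pts(p, 2); }
  for (int q = 0; q < nq; ++q) {
    double qx = queries(q, 0), qy = queries(q, 1), qz = queries(q, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int p = 0; p < np; ++p) {
      double dx = qx - px[p], dy = qy - py[p], dz = qz - pz[p];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear resampling of a scalar grid onto a new spacing (voxel centres at
// (i+1/2)*spacing), edge-clamped.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector data, IntegerVector dim, NumericVector spacing,
                           IntegerVector newdim, NumericVector newspacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = newdim[0], my = newdim[1], mz = newdim[2];
  NumericVector out(mx * my * mz);
  const double *f = REAL(data);
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double qx = ((i + 0.5) * newspacing[0]) / spacing[0] - 0.5;
        double qy = ((j + 0.5) * newspacing[1]) / spacing[1] - 0.5;
        double qz = ((k + 0.5) * newspacing[2]) / spacing[2] - 0.5;
        out[i + mx * (j + my * k)] = trilin(f, nx, ny, nz, qx, qy, qz);
      }
  out.attr("dim") = newdim;
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur with zero padding outside the grid (outside is
// non-tissue for mask smoothing), per-axis sigma in voxels.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector data, IntegerVector dim, NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<double> buf(REAL(data), REAL(data) + n), tmp(n);
  int dims[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double sg = sigma_vox[axis];
    if (sg <= 0) continue;
    int r = std::max(1, (int)std::ceil(4.0 * sg));
    std::vector<double> kern(2 * r + 1);
    double s = 0;
    for (int t = -r; t <= r; ++t) { kern[t + r] = std::exp(-0.5 * t * t / (sg * sg)); s += kern[t + r]; }
    for (auto &kv : kern) kv /= s;
    int stride = (axis == 0) ? 1 : (axis == 1) ? nx : nx * ny;
    int len = dims[axis];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int pos[3] = {i, j, k};
          if (pos[axis] != 0) continue;  // start of a line
          int base = idx3(i, j, k, nx, ny);
          for (int t = 0; t < len; ++t) {
            double acc = 0;
            for (int o = -r; o <= r; ++o) {
              int tt = t + o;
              if (tt < 0 || tt >= len) continue;  // zero pad
              acc += kern[o + r] * buf[base + tt * stride];
            }
            tmp[base + t * stride] = acc;
          }
        }
    std::swap(buf, tmp);
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = dim;
  return out;
}
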