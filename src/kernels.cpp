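// Low-level voxel kernels: seeded flood fill, connected-component labelling,
// per-voxel symmetric 3x3 eigen-analysis, Euclidean distance transform, and
// the anisotropic monodomain diffusion stencil. All arrays are passed as flat
// vectors in R's column-major order with 0-based indices internally.
#include <RcppArmadillo.h>
#include <queue>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Neighbour offsets for 6/18/26 connectivity.
static void neighbour_offsets(int connectivity, std::vector<std::array<int,3>>& offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
}

// [[Rcpp::export]]
LogicalVector region_grow_cpp(LogicalVector inband, IntegerVector dim,
                              IntegerVector seed0, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<std::array<int,3>> offs;
  neighbour_offsets(connectivity, offs);
  LogicalVector out(inband.size(), false);
  std::queue<std::array<int,3>> q;
  int si = seed0[0], sj = seed0[1], sk = seed0[2];
  int sl = lin(si, sj, sk, nx, ny);
  if (!inband[sl]) stop("seed voxel is not inside the target band/mask");
  out[sl] = true;
  q.push({si, sj, sk});
  while (!q.empty()) {
    std::array<int,3> p = q.front(); q.pop();
    for (const auto& o : offs) {
      int i = p[0] + o[0], j = p[1] + o[1], k = p[2] + o[2];
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
      int l = lin(i, j, k, nx, ny);
      if (inband[l] && !out[l]) { out[l] = true; q.push({i, j, k}); }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<std::array<int,3>> offs;
  neighbour_offsets(connectivity, offs);
  IntegerVector lab(mask.size(), 0);
  int cur = 0;
  std::queue<std::array<int,3>> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int l = lin(i, j, k, nx, ny);
        if (!mask[l] || lab[l]) continue;
        ++cur;
        lab[l] = cur;
        q.push({i, j, k});
        while (!q.empty()) {
          std::array<int,3> p = q.front(); q.pop();
          for (const auto& o : offs) {
            int ii = p[0] + o[0], jj = p[1] + o[1], kk = p[2] + o[2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            int ll = lin(ii, jj, kk, nx, ny);
            if (mask[ll] && !lab[ll]) { lab[ll] = cur; q.push({ii, jj, kk}); }
          }
        }
      }
  return lab;
}

// Eigen-analysis of a field of symmetric 3x3 tensors. Returns the unit
// eigenvector of the smallest eigenvalue (sign-canonicalised: last nonzero
// component positive) and all three eigenvalues sorted descending.
// [[Rcpp::export]]
List smallest_eig_cpp(NumericVector xx, NumericVector yy, NumericVector zz,
                      NumericVector xy, NumericVector xz, NumericVector yz) {
  const R_xlen_t n = xx.size();
  NumericMatrix dir(n, 3), ev(n, 3);
  arma::mat33 J;
  arma::vec3 eval;
  arma::mat33 evec;
  for (R_xlen_t t = 0; t < n; ++t) {
    J(0,0) = xx[t]; J(1,1) = yy[t]; J(2,2) = zz[t];
    J(0,1) = J(1,0) = xy[t];
    J(0,2) = J(2,0) = xz[t];
    J(1,2) = J(2,1) = yz[t];
    arma::eig_sym(eval, evec, J); // ascending
    double vx = evec(0,0), vy = evec(1,0), vz = evec(2,0);
    if (vz < 0 || (vz == 0 && (vy < 0 || (vy == 0 && vx < 0)))) {
      vx = -vx; vy = -vy; vz = -vz;
    }
    dir(t,0) = vx; dir(t,1) = vy; dir(t,2) = vz;
    ev(t,0) = eval(2); ev(t,1) = eval(1); ev(t,2) = eval(0); // descending
  }
  return List::create(_["direction"] = dir, _["eigenvalues"] = ev);
}

// Felzenszwalb & Huttenlocher 1D squared distance transform.
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (in mm) from every voxel to the nearest feature voxel.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector feature, IntegerVector dim, double spacing_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = 1e30;
  NumericVector g(feature.size());
  for (R_xlen_t t = 0; t < feature.size(); ++t) g[t] = feature[t] ? 0.0 : INF;
  std::vector<double> f(std::max({nx, ny, nz})), d(std::max({nx, ny, nz}));
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = g[lin(i,j,k,nx,ny)];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) g[lin(i,j,k,nx,ny)] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[lin(i,j,k,nx,ny)];
      dt1d(f, d, ny);
      for (int j = 0; j < ny; ++j) g[lin(i,j,k,nx,ny)] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[lin(i,j,k,nx,ny)];
      dt1d(f, d, nz);
      for (int k = 0; k < nz; ++k) g[lin(i,j,k,nx,ny)] = d[k];
    }
  for (R_xlen_t t = 0; t < g.size(); ++t) g[t] = std::sqrt(g[t]) * spacing_mm;
  return g;
}

// Tangential derivative of V along axis b at cell l, using conducting
// neighbours only (centred where possible, one-sided otherwise, 0 if none).
static inline double tangential_grad(const double* V, const int* cond,
                                     int i, int j, int k, int b,
                                     int nx, int ny, int nz, double h) {
  int ip = i, jp = j, kp = k, im = i, jm = j, km = k;
  if (b == 0) { ip = i + 1; im = i - 1; }
  else if (b == 1) { jp = j + 1; jm = j - 1; }
  else { kp = k + 1; km = k - 1; }
  bool hasp = ip < nx && jp < ny && kp < nz && cond[lin(ip,jp,kp,nx,ny)];
  bool hasm = im >= 0 && jm >= 0 && km >= 0 && cond[lin(im,jm,km,nx,ny)];
  int l = lin(i,j,k,nx,ny);
  if (hasp && hasm) return (V[lin(ip,jp,kp,nx,ny)] - V[lin(im,jm,km,nx,ny)]) / (2.0 * h);
  if (hasp) return (V[lin(ip,jp,kp,nx,ny)] - V[l]) / h;
  if (hasm) return (V[l] - V[lin(im,jm,km,nx,ny)]) / h;
  return 0.0;
}

// Finite-volume divergence of the anisotropic flux D grad(V) with no-flux
// boundaries at non-conducting voxels. Flux form: exactly conservative.
// [[Rcpp::export]]
NumericVector diffusion_cpp(NumericVector V,
                            NumericVector Dxx, NumericVector Dyy, NumericVector Dzz,
                            NumericVector Dxy, NumericVector Dxz, NumericVector Dyz,
                            IntegerVector cond, IntegerVector dim, double h) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(V.size(), 0.0);
  const double* v = V.begin();
  const int* c = cond.begin();
  bool any_cross = false;
  for (R_xlen_t t = 0; t < Dxy.size(); ++t)
    if (Dxy[t] != 0.0 || Dxz[t] != 0.0 || Dyz[t] != 0.0) { any_cross = true; break; }
  const NumericVector* Dn[3] = { &Dxx, &Dyy, &Dzz };
  // cross[a][b] with a<b: Dxy (0,1), Dxz (0,2), Dyz (1,2)
  for (int a = 0; a < 3; ++a) {
    int ea[3] = {0, 0, 0}; ea[a] = 1;
    const NumericVector& Da = *Dn[a];
    for (int k = 0; k < nz - ea[2]; ++k)
      for (int j = 0; j < ny - ea[1]; ++j)
        for (int i = 0; i < nx - ea[0]; ++i) {
          int p = lin(i, j, k, nx, ny);
          int q = lin(i + ea[0], j + ea[1], k + ea[2], nx, ny);
          if (!c[p] || !c[q]) continue;
          double flux = 0.5 * (Da[p] + Da[q]) * (v[q] - v[p]) / h;
          if (any_cross) {
            for (int b = 0; b < 3; ++b) {
              if (b == a) continue;
              const NumericVector& Dab =
                ((a == 0 && b == 1) || (a == 1 && b == 0)) ? Dxy :
                ((a == 0 && b == 2) || (a == 2 && b == 0)) ? Dxz : Dyz;
              double df = 0.5 * (Dab[p] + Dab[q]);
              if (df == 0.0) continue;
              double gp = tangential_grad(v, c, i, j, k, b, nx, ny, nz, h);
              double gq = tangential_grad(v, c, i + ea[0], j + ea[1], k + ea[2], b, nx, ny, nz, h);
              flux += df * 0.5 * (gp + gq);
            }
          }
          out[p] += flux / h;
          out[q] -= flux / h;
        }
  }
  return out;
}
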