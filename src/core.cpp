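#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel centres sit at (i + 0.5) * pitch, origin at the grid corner.
// Arrays are stored in R's column-major order with dim = c(nx, ny, nz),
// so flat index = i + nx * (j + ny * k).

// [[Rcpp::export]]
NumericVector cpp_render_phantom(IntegerVector dims, NumericVector voxel,
                                 NumericVector center,
                                 double a, double b, double c, double nuc_ri,
                                 double mid_len, double mid_rad, double mid_ri,
                                 double mid_overlap,
                                 double tail_len, double tail_rad, double tail_ri,
                                 double medium_ri, double noise_sd) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = voxel[0], dy = voxel[1], dz = voxel[2];
  const double cx = center[0], cy = center[1], cz = center[2];
  NumericVector out((R_xlen_t)nx * ny * nz, medium_ri);
  const double x0 = cx + a;                 // nucleus tip, midpiece start
  const double x1 = x0 + mid_len;           // midpiece end, tail start
  const double x2 = x1 + tail_len;          // tail end
  const double mr2 = mid_rad * mid_rad;
  const double tr2 = tail_rad * tail_rad;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double z = (k + 0.5) * dz, zc = z - cz;
    for (int j = 0; j < ny; ++j) {
      const double y = (j + 0.5) * dy, yc = y - cy;
      const double r2 = yc * yc + zc * zc;
      for (int i = 0; i < nx; ++i, ++idx) {
        const double x = (i + 0.5) * dx, xc = x - cx;
        const double e = (xc * xc) / (a * a) + (yc * yc) / (b * b) +
                         (zc * zc) / (c * c);
        if (e <= 1.0) {
          out[idx] = nuc_ri;                       // nucleus has precedence
        } else if (x >= x0 && x <= x1 && r2 <= mr2) {
          out[idx] = mid_ri;
        } else if (x >= x0 - mid_overlap && x < x0 && r2 <= mr2) {
          // neck: bridges nucleus and midpiece in the whole-cell window
          // without entering either sub-window
          out[idx] = tail_ri;
        } else if (x > x1 && x <= x2 && r2 <= tr2) {
          out[idx] = tail_ri;
        }
      }
    }
  }
  if (noise_sd > 0) {
    const R_xlen_t n = out.size();
    for (R_xlen_t v = 0; v < n; ++v) out[v] += R::rnorm(0.0, noise_sd);
  }
  out.attr("dim") = dims;
  return out;
}

// Classify voxels into the three half-open RI windows in one pass.
// Returns masks plus the count of voxels at or above the whole-window
// upper bound (unclassified-high QC).
// [[Rcpp::export]]
List cpp_window_masks(NumericVector grid, IntegerVector dims,
                      NumericVector lo, NumericVector hi) {
  const R_xlen_t n = grid.size();
  LogicalVector whole(n), mid(n), nuc(n);
  R_xlen_t n_high = 0;
  for (R_xlen_t v = 0; v < n; ++v) {
    const double g = grid[v];
    whole[v] = (g >= lo[0] && g < hi[0]);
    mid[v] = (g >= lo[1] && g < hi[1]);
    nuc[v] = (g >= lo[2] && g < hi[2]);
    if (g >= hi[0]) ++n_high;
  }
  whole.attr("dim") = dims;
  mid.attr("dim") = dims;
  nuc.attr("dim") = dims;
  return List::create(_["whole"] = whole, _["midpiece"] = mid,
                      _["nucleus"] = nuc, _["n_high"] = (double)n_high);
}

// Largest connected component of a binary mask (6- or 26-connectivity).
// Ties are broken in favour of the component whose first voxel has the
// smaller flattened (column-major) index; BFS seeds are scanned in that
// order so the first-found component wins a size tie.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dims,
                                    int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  std::vector<int> offs_i, offs_j, offs_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh > 1) continue;
        offs_i.push_back(di); offs_j.push_back(dj); offs_k.push_back(dk);
      }
  int best_label = 0, cur = 0;
  R_xlen_t best_size = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++cur;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t t = 0; t < offs_i.size(); ++t) {
        int ii = i + offs_i[t], jj = j + offs_j[t], kk = k + offs_k[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && !label[w]) { label[w] = cur; stack.push_back(w); }
      }
    }
    if (size > best_size) { best_size = size; best_label = cur; }
  }
  LogicalVector out(n, false);
  if (best_label > 0)
    for (R_xlen_t v = 0; v < n; ++v) out[v] = (label[v] == best_label);
  out.attr("dim") = dims;
  return out;
}

// Separable 1-D convolution along each axis with zero padding; one
// kernel per axis so smoothing can be isotropic in physical units on
// anisotropic voxel grids.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dims,
                          List kernels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const NumericVector kx = kernels[0], ky = kernels[1], kz = kernels[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  // x axis
  {
    const int kl = kx.size(), h = kl / 2;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = 0; i < nx; ++i) {
          double s = 0;
          for (int t = 0; t < kl; ++t) {
            int ii = i + t - h;
            if (ii >= 0 && ii < nx) s += kx[t] * a[base + ii];
          }
          b[base + i] = s;
        }
      }
    std::swap(a, b);
  }
  // y axis
  {
    const int kl = ky.size(), h = kl / 2;
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
        for (int j = 0; j < ny; ++j) {
          double s = 0;
          for (int t = 0; t < kl; ++t) {
            int jj = j + t - h;
            if (jj >= 0 && jj < ny) s += ky[t] * a[base + (R_xlen_t)nx * jj];
          }
          b[base + (R_xlen_t)nx * j] = s;
        }
      }
    std::swap(a, b);
  }
  // z axis
  {
    const int kl = kz.size(), h = kl / 2;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t base = i + (R_xlen_t)nx * j;
        R_xlen_t step = (R_xlen_t)nx * ny;
        for (int k = 0; k < nz; ++k) {
          double s = 0;
          for (int t = 0; t < kl; ++t) {
            int kk = k + t - h;
            if (kk >= 0 && kk < nz) s += kz[t] * a[base + step * kk];
          }
          b[base + step * k] = s;
        }
      }
  }
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dims;
  return out;
}

// Iso-surface of a scalar field by marching tetrahedra (6 tets per cell,
// all sharing the main diagonal). Returns c(area, enclosed_volume) in
// physical units. Triangles are oriented outward (away from the region
// with value >= level); the enclosed volume comes from the divergence
// theorem and is valid when the surface is closed, i.e. when the region
// does not touch the grid boundary.
static inline void interp(const double *p0, const double *p1, double v0,
                          double v1, double level, double *out) {
  double t = (level - v0) / (v1 - v0);
  for (int d = 0; d < 3; ++d) out[d] = p0[d] + t * (p1[d] - p0[d]);
}

// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(NumericVector vol, IntegerVector dims,
                                   NumericVector voxel, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = voxel[0], dy = voxel[1], dz = voxel[2];
  // cube corner offsets, bit order (x, y, z)
  static const int co[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},
                               {0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  // six tetrahedra around the 0-7 diagonal
  static const int tets[6][4] = {{0,1,3,7},{0,3,2,7},{0,2,6,7},
                                 {0,6,4,7},{0,4,5,7},{0,5,1,7}};
  double area = 0.0, vol6 = 0.0;
  double P[8][3], V[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          V[c] = vol[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          P[c][0] = (ii + 0.5) * dx;
          P[c][1] = (jj + 0.5) * dy;
          P[c][2] = (kk + 0.5) * dz;
          if (V[c] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int v = 0; v < 4; ++v) {
            int c = tets[t][v];
            if (V[c] >= level) in_idx[nin++] = c; else out_idx[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          double tri[2][3][3];
          int ntri = 0;
          double inside_pt[3];
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in_idx[0] : out_idx[0];
            const int *others = (nin == 1) ? out_idx : in_idx;
            for (int e = 0; e < 3; ++e)
              interp(P[apex], P[others[e]], V[apex], V[others[e]], level,
                     tri[0][e]);
            ntri = 1;
            int ref = (nin == 1) ? in_idx[0] : in_idx[0];
            for (int d = 0; d < 3; ++d) inside_pt[d] = P[ref][d];
          } else { // 2-2: quad from the four crossing edges
            double q[4][3];
            interp(P[in_idx[0]], P[out_idx[0]], V[in_idx[0]], V[out_idx[0]], level, q[0]);
            interp(P[in_idx[0]], P[out_idx[1]], V[in_idx[0]], V[out_idx[1]], level, q[1]);
            interp(P[in_idx[1]], P[out_idx[1]], V[in_idx[1]], V[out_idx[1]], level, q[2]);
            interp(P[in_idx[1]], P[out_idx[0]], V[in_idx[1]], V[out_idx[0]], level, q[3]);
            for (int d = 0; d < 3; ++d) {
              tri[0][0][d] = q[0][d]; tri[0][1][d] = q[1][d]; tri[0][2][d] = q[2][d];
              tri[1][0][d] = q[0][d]; tri[1][1][d] = q[2][d]; tri[1][2][d] = q[3][d];
            }
            ntri = 2;
            for (int d = 0; d < 3; ++d)
              inside_pt[d] = 0.5 * (P[in_idx[0]][d] + P[in_idx[1]][d]);
          }
          for (int m = 0; m < ntri; ++m) {
            double u[3], w[3], nvec[3], cen[3];
            for (int d = 0; d < 3; ++d) {
              u[d] = tri[m][1][d] - tri[m][0][d];
              w[d] = tri[m][2][d] - tri[m][0][d];
              cen[d] = (tri[m][0][d] + tri[m][1][d] + tri[m][2][d]) / 3.0;
            }
            nvec[0] = u[1] * w[2] - u[2] * w[1];
            nvec[1] = u[2] * w[0] - u[0] * w[2];
            nvec[2] = u[0] * w[1] - u[1] * w[0];
            double dot = 0;
            for (int d = 0; d < 3; ++d) dot += nvec[d] * (cen[d] - inside_pt[d]);
            if (dot < 0) { // flip to outward orientation
              for (int d = 0; d < 3; ++d) {
                double tmp = tri[m][1][d];
                tri[m][1][d] = tri[m][2][d];
                tri[m][2][d] = tmp;
                nvec[d] = -nvec[d];
              }
            }
            area += 0.5 * std::sqrt(nvec[0] * nvec[0] + nvec[1] * nvec[1] +
                                    nvec[2] * nvec[2]);
            // signed volume of tetra (origin, p0, p1, p2)
            const double *p0 = tri[m][0], *p1 = tri[m][1], *p2 = tri[m][2];
            vol6 += p0[0] * (p1[1] * p2[2] - p1[2] * p2[1]) -
                    p0[1] * (p1[0] * p2[2] - p1[2] * p2[0]) +
                    p0[2] * (p1[0] * p2[1] - p1[1] * p2[0]);
          }
        }
      }
  return NumericVector::create(_["area"] = area, _["volume"] = vol6 / 6.0);
}
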