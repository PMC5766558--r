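// Low-level 3D grid kernels. Arrays are R column-major: linear index
// i = x + nx*(y + ny*z), 0-based here, 1-based at the R boundary.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable correlation along one axis with replicate (edge-clamp) borders.
// kernel has odd length; centre at (len-1)/2.
// [[Rcpp::export(name = ".sep_convolve")]]
NumericVector sep_convolve(NumericVector arr, IntegerVector dim,
                           NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size(), r = (klen - 1) / 2;
  const int n[3] = {nx, ny, nz};
  const int na = n[axis];
  NumericVector out(arr.size());
  const double *in = arr.begin();
  const double *k = kernel.begin();
  double *o = out.begin();

  const long sx = 1, sy = nx, sz = (long)nx * ny;
  const long stride = axis == 0 ? sx : (axis == 1 ? sy : sz);

  // iterate over all lines along `axis`
  std::vector<double> line(na), res(na);
  int d1, d2;
  long s1, s2;
  if (axis == 0)      { d1 = ny; d2 = nz; s1 = sy; s2 = sz; }
  else if (axis == 1) { d1 = nx; d2 = nz; s1 = sx; s2 = sz; }
  else                { d1 = nx; d2 = ny; s1 = sx; s2 = sy; }

  for (int j2 = 0; j2 < d2; ++j2) {
    for (int j1 = 0; j1 < d1; ++j1) {
      const long base = j1 * s1 + j2 * s2;
      for (int i = 0; i < na; ++i) line[i] = in[base + i * stride];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t)
          acc += k[t + r] * line[clampi(i + t, 0, na - 1)];
        res[i] = acc;
      }
      for (int i = 0; i < na; ++i) o[base + i * stride] = res[i];
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Eigenvalues of the symmetric 3x3 matrix field given by the six unique
// Hessian entries, sorted by decreasing |lambda|. Trigonometric closed form.
// [[Rcpp::export(name = ".eig3_sorted")]]
List eig3_sorted(NumericVector hxx, NumericVector hyy, NumericVector hzz,
                 NumericVector hxy, NumericVector hxz, NumericVector hyz) {
  const R_xlen_t n = hxx.size();
  NumericVector l1(n), l2(n), l3(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double a11 = hxx[i], a22 = hyy[i], a33 = hzz[i];
    const double a12 = hxy[i], a13 = hxz[i], a23 = hyz[i];
    double e[3];
    const double p1 = a12 * a12 + a13 * a13 + a23 * a23;
    if (p1 == 0.0) {
      e[0] = a11; e[1] = a22; e[2] = a33;
    } else {
      const double q = (a11 + a22 + a33) / 3.0;
      const double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                        (a33 - q) * (a33 - q) + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      const double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
      const double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
      double detB = b11 * (b22 * b33 - b23 * b23)
                  - b12 * (b12 * b33 - b23 * b13)
                  + b13 * (b12 * b23 - b22 * b13);
      double rr = detB / 2.0;
      rr = rr < -1.0 ? -1.0 : (rr > 1.0 ? 1.0 : rr);
      const double phi = std::acos(rr) / 3.0;
      e[0] = q + 2.0 * p * std::cos(phi);
      e[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e[1] = 3.0 * q - e[0] - e[2];
    }
    // sort by decreasing absolute value
    if (std::fabs(e[0]) < std::fabs(e[1])) std::swap(e[0], e[1]);
    if (std::fabs(e[1]) < std::fabs(e[2])) std::swap(e[1], e[2]);
    if (std::fabs(e[0]) < std::fabs(e[1])) std::swap(e[0], e[1]);
    l1[i] = e[0]; l2[i] = e[1]; l3[i] = e[2];
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}

// Standard deviation (population) over the 3x3x3 neighbourhood including the
// centre; edge voxels use the available neighbours.
// [[Rcpp::export(name = ".neighborhood_sd")]]
NumericVector neighborhood_sd_cpp(NumericVector arr, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(arr.size());
  const double *in = arr.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0.0, s2 = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          const int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              const int xx = x + dx; if (xx < 0 || xx >= nx) continue;
              const double v = in[xx + (long)nx * (yy + (long)ny * zz)];
              s += v; s2 += v * v; ++cnt;
            }
          }
        }
        const double m = s / cnt;
        double var = s2 / cnt - m * m;
        if (var < 0) var = 0;
        out[x + (long)nx * (y + (long)ny * z)] = std::sqrt(var);
      }
  out.attr("dim") = dim;
  return out;
}

// Connected-component labelling of a binary mask (6 or 26 connectivity).
// Component ids are assigned in order of the smallest linear voxel index,
// starting at 1.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> offs_dx, offs_dy, offs_dz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man > 1) continue;
        offs_dx.push_back(dx); offs_dy.push_back(dy); offs_dz.push_back(dz);
      }
  int next_id = 0;
  std::vector<long> stack;
  for (long seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next_id;
    lab[seed] = next_id;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      const long cur = stack.back(); stack.pop_back();
      const int x = cur % nx, y = (cur / nx) % ny, z = cur / ((long)nx * ny);
      for (size_t t = 0; t < offs_dx.size(); ++t) {
        const int xx = x + offs_dx[t], yy = y + offs_dy[t], zz = z + offs_dz[t];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const long nb = xx + (long)nx * (yy + (long)ny * zz);
        if (mask[nb] && lab[nb] == 0) { lab[nb] = next_id; stack.push_back(nb); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// kNN class posteriors: fraction of each class among the k nearest training
// rows in Euclidean distance. Matrices are samples x features.
// [[Rcpp::export(name = ".knn_posteriors")]]
NumericMatrix knn_posteriors_cpp(NumericMatrix train, IntegerVector labels,
                                 NumericMatrix query, int k, int nclass) {
  const int ntr = train.nrow(), nq = query.nrow(), p = train.ncol();
  if (k < 1 || k > ntr) stop("k must be in [1, nrow(train)]");
  NumericMatrix post(nq, nclass);
  // train transposed into contiguous row-major buffer for cache locality
  std::vector<double> tr((size_t)ntr * p);
  for (int i = 0; i < ntr; ++i)
    for (int j = 0; j < p; ++j) tr[(size_t)i * p + j] = train(i, j);
  std::vector<double> d2(ntr);
  std::vector<int> idx(ntr);
  std::vector<double> q(p);
  for (int iq = 0; iq < nq; ++iq) {
    for (int j = 0; j < p; ++j) q[j] = query(iq, j);
    for (int i = 0; i < ntr; ++i) {
      const double *t = &tr[(size_t)i * p];
      double acc = 0.0;
      for (int j = 0; j < p; ++j) { const double d = q[j] - t[j]; acc += d * d; }
      d2[i] = acc;
      idx[i] = i;
    }
    std::nth_element(idx.begin(), idx.begin() + (k - 1), idx.end(),
                     [&](int a, int b) {
                       return d2[a] < d2[b] || (d2[a] == d2[b] && a < b);
                     });
    for (int t = 0; t < k; ++t) post(iq, labels[idx[t]] - 1) += 1.0;
    for (int c = 0; c < nclass; ++c) post(iq, c) /= k;
  }
  return post;
}

// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic spacing supported. Distance from every voxel to the nearest
// background (mask == FALSE) voxel; +Inf if mask covers the whole grid.
static void edt1d(std::vector<double> &f, std::vector<double> &d, int n,
                  double h) {
  // lower envelope of parabolas D_v(x) = (x - v*h)^2 + f[v]; infinite f[v]
  // parabolas are skipped (they never contribute).
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int first = -1;
  for (int q = 0; q < n; ++q)
    if (std::isfinite(f[q])) { first = q; break; }
  if (first < 0) {
    for (int q = 0; q < n; ++q) d[q] = INFINITY;
    return;
  }
  int kk = 0;
  v[0] = first;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = first + 1; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    const double xq = q * h;
    double s;
    while (true) {
      const int vk = v[kk];
      const double xv = vk * h;
      s = ((f[q] + xq * xq) - (f[vk] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= zb[kk] && kk > 0) --kk; else break;
    }
    ++kk;
    v[kk] = q;
    zb[kk] = s;
    zb[kk + 1] = INFINITY;
  }
  int kq = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * h;
    while (zb[kq + 1] < xq) ++kq;
    const double dd = xq - v[kq] * h;
    d[q] = dd * dd + f[v[kq]];
  }
}

// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(LogicalVector mask, IntegerVector dim,
                          NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = mask[i] ? INFINITY : 0.0;
  const int nn[3] = {nx, ny, nz};
  const long sx = 1, sy = nx, sz = (long)nx * ny;
  const long strides[3] = {sx, sy, sz};
  for (int axis = 0; axis < 3; ++axis) {
    const int na = nn[axis];
    if (na == 1) continue;
    const double h = spacing[axis];
    int d1, d2; long s1, s2;
    if (axis == 0)      { d1 = ny; d2 = nz; s1 = sy; s2 = sz; }
    else if (axis == 1) { d1 = nx; d2 = nz; s1 = sx; s2 = sz; }
    else                { d1 = nx; d2 = ny; s1 = sx; s2 = sy; }
    std::vector<double> f(na), d(na);
    for (int j2 = 0; j2 < d2; ++j2)
      for (int j1 = 0; j1 < d1; ++j1) {
        const long base = j1 * s1 + j2 * s2;
        bool allinf = true, anyinf = false;
        for (int i = 0; i < na; ++i) {
          f[i] = out[base + i * strides[axis]];
          if (std::isfinite(f[i])) allinf = false; else anyinf = true;
        }
        if (allinf) continue;           // stays infinite along this line
        if (!anyinf) {
          bool allzero = true;
          for (int i = 0; i < na; ++i) if (f[i] != 0.0) { allzero = false; break; }
          if (allzero) continue;
        }
        edt1d(f, d, na, h);
        for (int i = 0; i < na; ++i) out[base + i * strides[axis]] = d[i];
      }
  }
  out.attr("dim") = dim;
  return out;
}

// Local thickness: diameter of the largest inscribed sphere (within the mask)
// covering each mask voxel, from the EDT radius field. Brute-force sphere
// painting; adequate for vessel-sized structures.
// [[Rcpp::export(name = ".local_thickness")]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dim,
                                  NumericVector spacing,
                                  NumericVector edt2) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  NumericVector out((long)nx * ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const long i = x + (long)nx * (y + (long)ny * z);
        if (!mask[i]) continue;
        const double r = std::sqrt(edt2[i]);
        const double d = 2.0 * r;
        const int rx = (int)std::ceil(r / hx), ry = (int)std::ceil(r / hy),
                  rz = (int)std::ceil(r / hz);
        for (int dz = -rz; dz <= rz; ++dz) {
          const int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          for (int dy = -ry; dy <= ry; ++dy) {
            const int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dx = -rx; dx <= rx; ++dx) {
              const int xx = x + dx; if (xx < 0 || xx >= nx) continue;
              const double dist2 = dx * hx * dx * hx + dy * hy * dy * hy +
                                   dz * hz * dz * hz;
              if (dist2 > r * r) continue;
              const long j = xx + (long)nx * (yy + (long)ny * zz);
              if (mask[j] && out[j] < d) out[j] = d;
            }
          }
        }
      }
  out.attr("dim") = dim;
  return out;
}

// Resample onto an output grid. For each output voxel j along an axis the
// source continuous index is offset + j * step (both in source voxel units).
// mode 0 = trilinear with edge clamping, 1 = nearest neighbour.
// [[Rcpp::export(name = ".resample_grid")]]
NumericVector resample_grid(NumericVector arr, IntegerVector dim,
                            IntegerVector out_dim, NumericVector offset,
                            NumericVector step, int mode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((long)ox * oy * oz);
  const double *in = arr.begin();
  for (int z = 0; z < oz; ++z) {
    double cz = offset[2] + z * step[2];
    for (int y = 0; y < oy; ++y) {
      double cy = offset[1] + y * step[1];
      for (int x = 0; x < ox; ++x) {
        double cx = offset[0] + x * step[0];
        double val;
        if (mode == 1) {
          const int ix = clampi((int)std::lround(cx), 0, nx - 1);
          const int iy = clampi((int)std::lround(cy), 0, ny - 1);
          const int iz = clampi((int)std::lround(cz), 0, nz - 1);
          val = in[ix + (long)nx * (iy + (long)ny * iz)];
        } else {
          double fx = cx < 0 ? 0 : (cx > nx - 1 ? nx - 1 : cx);
          double fy = cy < 0 ? 0 : (cy > ny - 1 ? ny - 1 : cy);
          double fz = cz < 0 ? 0 : (cz > nz - 1 ? nz - 1 : cz);
          const int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
                    z0 = (int)std::floor(fz);
          const int x1 = std::min(x0 + 1, nx - 1),
                    y1 = std::min(y0 + 1, ny - 1),
                    z1 = std::min(z0 + 1, nz - 1);
          const double tx = fx - x0, ty = fy - y0, tz = fz - z0;
          double c00 = in[x0 + (long)nx * (y0 + (long)ny * z0)] * (1 - tx) +
                       in[x1 + (long)nx * (y0 + (long)ny * z0)] * tx;
          double c10 = in[x0 + (long)nx * (y1 + (long)ny * z0)] * (1 - tx) +
                       in[x1 + (long)nx * (y1 + (long)ny * z0)] * tx;
          double c01 = in[x0 + (long)nx * (y0 + (long)ny * z1)] * (1 - tx) +
                       in[x1 + (long)nx * (y0 + (long)ny * z1)] * tx;
          double c11 = in[x0 + (long)nx * (y1 + (long)ny * z1)] * (1 - tx) +
                       in[x1 + (long)nx * (y1 + (long)ny * z1)] * tx;
          double c0 = c00 * (1 - ty) + c10 * ty;
          double c1 = c01 * (1 - ty) + c11 * ty;
          val = c0 * (1 - tz) + c1 * tz;
        }
        out[x + (long)ox * (y + (long)oy * z)] = val;
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}

// For every labelled voxel (label > 0) count, per class, the labelled voxels
// in its 26-neighbourhood, and flag voxels with no same-label neighbour.
// Returns matrix: linear index (1-based), own label, n1, n2, n3, solitary.
// [[Rcpp::export(name = ".solitary_info")]]
IntegerMatrix solitary_info(IntegerVector labels, IntegerVector dim,
                            int nclass) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<long> sol_idx;
  std::vector<std::vector<int>> sol_counts;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const long i = x + (long)nx * (y + (long)ny * z);
        const int lab = labels[i];
        if (lab <= 0) continue;
        std::vector<int> cnt(nclass, 0);
        bool same = false;
        for (int dz = -1; dz <= 1; ++dz) {
          const int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int xx = x + dx; if (xx < 0 || xx >= nx) continue;
              const int nl = labels[xx + (long)nx * (yy + (long)ny * zz)];
              if (nl > 0) {
                ++cnt[nl - 1];
                if (nl == lab) same = true;
              }
            }
          }
        }
        if (!same) {
          sol_idx.push_back(i + 1);
          std::vector<int> row(nclass + 1);
          row[0] = lab;
          for (int c = 0; c < nclass; ++c) row[c + 1] = cnt[c];
          sol_counts.push_back(row);
        }
      }
  IntegerMatrix outm(sol_idx.size(), nclass + 2);
  for (size_t r = 0; r < sol_idx.size(); ++r) {
    outm(r, 0) = (int)sol_idx[r];
    for (int c = 0; c <= nclass; ++c) outm(r, c + 1) = sol_counts[r][c];
  }
  return outm;
}
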