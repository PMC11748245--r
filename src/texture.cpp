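// Counting kernels for gray-level texture matrices and mask geometry.
//
// All functions take a column-major integer volume `lev` (dims d = c(d1,d2,d3))
// holding discretized gray levels 1..nlev inside the mask and 0 outside.
// Feature formulas live in R; only the O(n)–O(n^2) enumeration is done here.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

inline int at(const int *lev, int i, int j, int k, int d1, int d2) {
  return lev[i + d1 * (j + (R_xlen_t)d2 * k)];
}

inline bool inside(int i, int j, int k, int d1, int d2, int d3) {
  return i >= 0 && j >= 0 && k >= 0 && i < d1 && j < d2 && k < d3;
}

}  // namespace

// Symmetric gray-level co-occurrence counts, one nlev x nlev slab per offset.
// [[Rcpp::export(name = ".glcm_counts")]]
NumericVector glcm_counts(IntegerVector lev, IntegerVector dim, int nlev,
                          IntegerMatrix offsets) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2], noff = offsets.nrow();
  NumericVector out((R_xlen_t)nlev * nlev * noff);
  const int *L = INTEGER(lev);
  for (int o = 0; o < noff; ++o) {
    int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
    double *M = REAL(out) + (R_xlen_t)o * nlev * nlev;
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          int a = at(L, i, j, k, d1, d2);
          if (a == 0) continue;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          if (!inside(i2, j2, k2, d1, d2, d3)) continue;
          int b = at(L, i2, j2, k2, d1, d2);
          if (b == 0) continue;
          M[(a - 1) + (R_xlen_t)nlev * (b - 1)] += 1.0;
          M[(b - 1) + (R_xlen_t)nlev * (a - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(nlev, nlev, noff);
  return out;
}

// Run-length counts, one nlev x maxlen slab per direction.
// [[Rcpp::export(name = ".glrlm_counts")]]
NumericVector glrlm_counts(IntegerVector lev, IntegerVector dim, int nlev,
                           IntegerMatrix dirs) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2], ndir = dirs.nrow();
  int maxlen = std::max(d1, std::max(d2, d3));
  NumericVector out((R_xlen_t)nlev * maxlen * ndir);
  const int *L = INTEGER(lev);
  for (int o = 0; o < ndir; ++o) {
    int dx = dirs(o, 0), dy = dirs(o, 1), dz = dirs(o, 2);
    double *M = REAL(out) + (R_xlen_t)o * nlev * maxlen;
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          int a = at(L, i, j, k, d1, d2);
          if (a == 0) continue;
          // run starts where the previous voxel along the direction differs
          int ip = i - dx, jp = j - dy, kp = k - dz;
          if (inside(ip, jp, kp, d1, d2, d3) && at(L, ip, jp, kp, d1, d2) == a)
            continue;
          int len = 1, in = i + dx, jn = j + dy, kn = k + dz;
          while (inside(in, jn, kn, d1, d2, d3) &&
                 at(L, in, jn, kn, d1, d2) == a) {
            ++len;
            in += dx; jn += dy; kn += dz;
          }
          M[(a - 1) + (R_xlen_t)nlev * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(nlev, maxlen, ndir);
  return out;
}

// Connected zones of equal gray level (26-connectivity; in-plane inputs with
// a singleton third dimension reduce to 8-connectivity). Returns a matrix
// with one row per zone: (level, size).
// [[Rcpp::export(name = ".glszm_zones")]]
IntegerMatrix glszm_zones(IntegerVector lev, IntegerVector dim) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const int *L = INTEGER(lev);
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (seen[s] || L[s] == 0) continue;
    int a = L[s];
    int size = 0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      int i = (int)(v % d1), j = (int)((v / d1) % d2), k = (int)(v / ((R_xlen_t)d1 * d2));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int i2 = i + di, j2 = j + dj, k2 = k + dk;
            if (!inside(i2, j2, k2, d1, d2, d3)) continue;
            R_xlen_t w = i2 + d1 * (j2 + (R_xlen_t)d2 * k2);
            if (!seen[w] && L[w] == a) {
              seen[w] = 1;
              stack.push_back(w);
            }
          }
    }
    zl.push_back(a);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t r = 0; r < zl.size(); ++r) {
    out(r, 0) = zl[r];
    out(r, 1) = zs[r];
  }
  return out;
}

// Neighborhood gray-tone difference accumulators: per level i returns
// n_i (valid voxels) and s_i = sum |i - mean(26-neighborhood levels)|.
// [[Rcpp::export(name = ".ngtdm_counts")]]
NumericMatrix ngtdm_counts(IntegerVector lev, IntegerVector dim, int nlev) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  NumericMatrix out(nlev, 2);
  const int *L = INTEGER(lev);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int a = at(L, i, j, k, d1, d2);
        if (a == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (!inside(i2, j2, k2, d1, d2, d3)) continue;
              int b = at(L, i2, j2, k2, d1, d2);
              if (b == 0) continue;
              sum += b;
              ++cnt;
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::fabs((double)a - sum / cnt);
      }
  return out;
}

// Gray-level dependence counts: rows = level, cols = dependence size k+1
// where k = number of 26-neighbors with |level difference| <= alpha.
// [[Rcpp::export(name = ".gldm_counts")]]
NumericMatrix gldm_counts(IntegerVector lev, IntegerVector dim, int nlev,
                          int alpha) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  NumericMatrix out(nlev, 27);
  const int *L = INTEGER(lev);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int a = at(L, i, j, k, d1, d2);
        if (a == 0) continue;
        int dep = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (!inside(i2, j2, k2, d1, d2, d3)) continue;
              int b = at(L, i2, j2, k2, d1, d2);
              if (b == 0) continue;
              if (std::abs(a - b) <= alpha) ++dep;
            }
        out(a - 1, dep) += 1.0;
      }
  return out;
}

// Peritumoral ring: background voxels whose center lies within `margin` mm
// (physical Euclidean distance, anisotropic spacing) of any tumor voxel
// center. Seeded from tumor border voxels (6-neighborhood), which carry the
// minimum distance to any background voxel.
// [[Rcpp::export(name = ".ring_mask")]]
LogicalVector ring_mask(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing, double margin) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const int *M = LOGICAL(mask);
  LogicalVector out(n);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // precompute the ellipsoidal offset ball
  int rx = (int)std::floor(margin / sx), ry = (int)std::floor(margin / sy),
      rz = (int)std::floor(margin / sz);
  std::vector<int> odx, ody, odz;
  double m2 = margin * margin;
  for (int dk = -rz; dk <= rz; ++dk)
    for (int dj = -ry; dj <= ry; ++dj)
      for (int di = -rx; di <= rx; ++di) {
        double dd = di * sx * di * sx + dj * sy * dj * sy + dk * sz * dk * sz;
        if (dd <= m2) {
          odx.push_back(di);
          ody.push_back(dj);
          odz.push_back(dk);
        }
      }
  const int stepi[6] = {1, -1, 0, 0, 0, 0};
  const int stepj[6] = {0, 0, 1, -1, 0, 0};
  const int stepk[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t v = i + d1 * (j + (R_xlen_t)d2 * k);
        if (!M[v]) continue;
        bool border = false;
        for (int s = 0; s < 6 && !border; ++s) {
          int i2 = i + stepi[s], j2 = j + stepj[s], k2 = k + stepk[s];
          if (!inside(i2, j2, k2, d1, d2, d3) ||
              !M[i2 + d1 * (j2 + (R_xlen_t)d2 * k2)])
            border = true;
        }
        if (!border) continue;
        for (size_t t = 0; t < odx.size(); ++t) {
          int i2 = i + odx[t], j2 = j + ody[t], k2 = k + odz[t];
          if (!inside(i2, j2, k2, d1, d2, d3)) continue;
          R_xlen_t w = i2 + d1 * (j2 + (R_xlen_t)d2 * k2);
          if (!M[w]) out[w] = TRUE;
        }
      }
  return out;
}

// Largest pairwise distances between border-voxel centers: overall 3D and
// within shared axial slice / coronal row / sagittal column planes.
// Returns c(max3d, maxSlice, maxColumn, maxRow); zero-size masks give zeros.
// [[Rcpp::export(name = ".max_diameters")]]
NumericVector max_diameters(LogicalVector mask, IntegerVector dim,
                            NumericVector spacing) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int *M = LOGICAL(mask);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  std::vector<int> xi, yi, zi;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t v = i + d1 * (j + (R_xlen_t)d2 * k);
        if (!M[v]) continue;
        bool border = false;
        for (int s = 0; s < 6 && !border; ++s) {
          static const int si[6] = {1, -1, 0, 0, 0, 0};
          static const int sj[6] = {0, 0, 1, -1, 0, 0};
          static const int sk[6] = {0, 0, 0, 0, 1, -1};
          int i2 = i + si[s], j2 = j + sj[s], k2 = k + sk[s];
          if (!inside(i2, j2, k2, d1, d2, d3) ||
              !M[i2 + d1 * (j2 + (R_xlen_t)d2 * k2)])
            border = true;
        }
        if (border) {
          xi.push_back(i);
          yi.push_back(j);
          zi.push_back(k);
        }
      }
  double m3 = 0, msl = 0, mcol = 0, mrow = 0;
  size_t nb = xi.size();
  for (size_t a = 0; a + 1 < nb; ++a)
    for (size_t b = a + 1; b < nb; ++b) {
      double ddx = (xi[a] - xi[b]) * sx, ddy = (yi[a] - yi[b]) * sy,
             ddz = (zi[a] - zi[b]) * sz;
      double dd = ddx * ddx + ddy * ddy + ddz * ddz;
      if (dd > m3) m3 = dd;
      if (zi[a] == zi[b] && dd > msl) msl = dd;   // axial plane (fixed z)
      if (yi[a] == yi[b] && dd > mcol) mcol = dd; // coronal plane (fixed y)
      if (xi[a] == xi[b] && dd > mrow) mrow = dd; // sagittal plane (fixed x)
    }
  return NumericVector::create(std::sqrt(m3), std::sqrt(msl),
                               std::sqrt(mcol), std::sqrt(mrow));
}

namespace {

struct V3 {
  double x, y, z;
};

inline V3 mid(const V3 &a, const V3 &b) {
  V3 m = {(a.x + b.x) / 2, (a.y + b.y) / 2, (a.z + b.z) / 2};
  return m;
}

inline V3 sub(const V3 &a, const V3 &b) {
  V3 m = {a.x - b.x, a.y - b.y, a.z - b.z};
  return m;
}

inline V3 cross(const V3 &a, const V3 &b) {
  V3 m = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
  return m;
}

inline double dot(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// accumulate one triangle oriented so its normal points from `in` to `outward`
void add_tri(V3 a, V3 b, V3 c, const V3 &insidePt, double &area, double &vol) {
  V3 n = cross(sub(b, a), sub(c, a));
  V3 cen = {(a.x + b.x + c.x) / 3 - insidePt.x, (a.y + b.y + c.y) / 3 - insidePt.y,
            (a.z + b.z + c.z) / 3 - insidePt.z};
  if (dot(n, cen) < 0) {
    V3 t = b;
    b = c;
    c = t;
    n = cross(sub(b, a), sub(c, a));
  }
  area += 0.5 * std::sqrt(dot(n, n));
  vol += (a.x * (b.y * c.z - b.z * c.y) - a.y * (b.x * c.z - b.z * c.x) +
          a.z * (b.x * c.y - b.y * c.x)) / 6.0;
}

}  // namespace

namespace {

// linear interpolation of the iso-0.5 crossing on a tetrahedron edge
inline V3 crossing(const V3 &a, double va, const V3 &b, double vb) {
  double t = (0.5 - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  V3 m = {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
  return m;
}

}  // namespace

// Marching-tetrahedra surface mesh of an indicator field (iso-level 0.5,
// linearly interpolated crossings, vertices at voxel centers, Freudenthal
// 6-tetrahedra cell decomposition; watertight). The field is 0 outside the
// volume. Returns c(surface_area_mm2, mesh_volume_mm3).
// [[Rcpp::export(name = ".mesh_area_volume")]]
NumericVector mesh_area_volume(NumericVector field, IntegerVector dim,
                               NumericVector spacing) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double *M = REAL(field);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // Freudenthal tetrahedra around the main diagonal c0-c7 (corner bit order
  // x + 2y + 4z)
  static const int tets[6][4] = {{0, 1, 5, 7}, {0, 5, 4, 7}, {0, 4, 6, 7},
                                 {0, 6, 2, 7}, {0, 2, 3, 7}, {0, 3, 1, 7}};
  double area = 0, vol = 0;
  for (int k = -1; k < d3; ++k)
    for (int j = -1; j < d2; ++j)
      for (int i = -1; i < d1; ++i) {
        double val[8];
        V3 pos[8];
        int sum = 0;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          double v = inside(ci, cj, ck, d1, d2, d3)
                         ? M[ci + d1 * (cj + (R_xlen_t)d2 * ck)]
                         : 0.0;
          val[c] = v;
          sum += (v > 0.5) ? 1 : 0;
          pos[c].x = ci * sx;
          pos[c].y = cj * sy;
          pos[c].z = ck * sz;
        }
        if (sum == 0 || sum == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int b[4], nin = 0;
          double v[4];
          V3 p[4];
          for (int c = 0; c < 4; ++c) {
            v[c] = val[T[c]];
            b[c] = (v[c] > 0.5) ? 1 : 0;
            nin += b[c];
            p[c] = pos[T[c]];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int lone = -1;
            for (int c = 0; c < 4; ++c)
              if ((nin == 1 && b[c] == 1) || (nin == 3 && b[c] == 0)) lone = c;
            int oth[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != lone) oth[m++] = c;
            V3 insidePt;
            if (nin == 1)
              insidePt = p[lone];
            else {  // centroid of the three inside vertices
              insidePt.x = (p[oth[0]].x + p[oth[1]].x + p[oth[2]].x) / 3;
              insidePt.y = (p[oth[0]].y + p[oth[1]].y + p[oth[2]].y) / 3;
              insidePt.z = (p[oth[0]].z + p[oth[1]].z + p[oth[2]].z) / 3;
            }
            add_tri(crossing(p[lone], v[lone], p[oth[0]], v[oth[0]]),
                    crossing(p[lone], v[lone], p[oth[1]], v[oth[1]]),
                    crossing(p[lone], v[lone], p[oth[2]], v[oth[2]]),
                    insidePt, area, vol);
          } else {  // 2 in / 2 out: quad split into two triangles
            int in1 = -1, in2 = -1, out1 = -1, out2 = -1;
            for (int c = 0; c < 4; ++c) {
              if (b[c] == 1) {
                if (in1 < 0) in1 = c; else in2 = c;
              } else {
                if (out1 < 0) out1 = c; else out2 = c;
              }
            }
            V3 q1 = crossing(p[in1], v[in1], p[out1], v[out1]);
            V3 q2 = crossing(p[in1], v[in1], p[out2], v[out2]);
            V3 q3 = crossing(p[in2], v[in2], p[out2], v[out2]);
            V3 q4 = crossing(p[in2], v[in2], p[out1], v[out1]);
            V3 insidePt = mid(p[in1], p[in2]);
            add_tri(q1, q2, q3, insidePt, area, vol);
            add_tri(q1, q3, q4, insidePt, area, vol);
          }
        }
      }
  return NumericVector::create(area, std::fabs(vol));
}
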