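#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline long idx3(int i, int j, int k, int nx, int ny) {
  return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
}

static void euler_matrix(const NumericVector &rotDeg, double R[3][3]) {
  // R = Rz * Ry * Rx, angles in degrees
  const double d2r = M_PI / 180.0;
  double a = rotDeg[0] * d2r, b = rotDeg[1] * d2r, g = rotDeg[2] * d2r;
  double ca = cos(a), sa = sin(a), cb = cos(b), sb = sin(b), cg = cos(g), sg = sin(g);
  R[0][0] = cg * cb;            R[0][1] = cg * sb * sa - sg * ca; R[0][2] = cg * sb * ca + sg * sa;
  R[1][0] = sg * cb;            R[1][1] = sg * sb * sa + cg * ca; R[1][2] = sg * sb * ca - cg * sa;
  R[2][0] = -sb;                R[2][1] = cb * sa;                R[2][2] = cb * ca;
}

static inline double trilinear(const NumericVector &vals, int nx, int ny, int nz,
                               double x, double y, double z, double background) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return background;
  int i0 = (int)floor(x), j0 = (int)floor(y), k0 = (int)floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double c000 = vals[idx3(i0, j0, k0, nx, ny)],     c100 = vals[idx3(i0 + 1, j0, k0, nx, ny)];
  double c010 = vals[idx3(i0, j0 + 1, k0, nx, ny)], c110 = vals[idx3(i0 + 1, j0 + 1, k0, nx, ny)];
  double c001 = vals[idx3(i0, j0, k0 + 1, nx, ny)], c101 = vals[idx3(i0 + 1, j0, k0 + 1, nx, ny)];
  double c011 = vals[idx3(i0, j0 + 1, k0 + 1, nx, ny)], c111 = vals[idx3(i0 + 1, j0 + 1, k0 + 1, nx, ny)];
  double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample a moving volume onto a target grid through a rigid map
// x_mov = R (x_tgt - c) + c + t   (physical um coordinates)
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(NumericVector movVals, IntegerVector movDim,
                                 double movPitch, NumericVector movOrigin,
                                 IntegerVector tgtDim, double tgtPitch,
                                 NumericVector tgtOrigin,
                                 NumericVector rotDeg, NumericVector transUm,
                                 NumericVector centerUm, double background) {
  int mnx = movDim[0], mny = movDim[1], mnz = movDim[2];
  int nx = tgtDim[0], ny = tgtDim[1], nz = tgtDim[2];
  double R[3][3];
  euler_matrix(rotDeg, R);
  NumericVector out((long)nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    double zf = tgtOrigin[2] + k * tgtPitch - centerUm[2];
    for (int j = 0; j < ny; ++j) {
      double yf = tgtOrigin[1] + j * tgtPitch - centerUm[1];
      for (int i = 0; i < nx; ++i) {
        double xf = tgtOrigin[0] + i * tgtPitch - centerUm[0];
        double xm = R[0][0] * xf + R[0][1] * yf + R[0][2] * zf + centerUm[0] + transUm[0];
        double ym = R[1][0] * xf + R[1][1] * yf + R[1][2] * zf + centerUm[1] + transUm[1];
        double zm = R[2][0] * xf + R[2][1] * yf + R[2][2] * zf + centerUm[2] + transUm[2];
        out[idx3(i, j, k, nx, ny)] = trilinear(
          movVals, mnx, mny, mnz,
          (xm - movOrigin[0]) / movPitch,
          (ym - movOrigin[1]) / movPitch,
          (zm - movOrigin[2]) / movPitch, background);
      }
    }
  }
  return out;
}

// Normalized cross-correlation between fixed volume and rigidly mapped moving
// volume, evaluated over a strided subsample of the fixed grid. `keep`, when
// non-empty, is a 0/1 mask on the fixed grid restricting the sum (used to
// trim regions where the two scans genuinely differ).
// [[Rcpp::export]]
double cpp_ncc_rigid(NumericVector movVals, IntegerVector movDim, double movPitch,
                     NumericVector movOrigin, NumericVector fixVals,
                     IntegerVector fixDim, double fixPitch, NumericVector fixOrigin,
                     NumericVector rotDeg, NumericVector transUm,
                     NumericVector centerUm, int stride, double background,
                     IntegerVector keep) {
  bool useKeep = keep.size() > 0;
  int mnx = movDim[0], mny = movDim[1], mnz = movDim[2];
  int nx = fixDim[0], ny = fixDim[1], nz = fixDim[2];
  double R[3][3];
  euler_matrix(rotDeg, R);
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  long n = 0;
  for (int k = 0; k < nz; k += stride) {
    double zf = fixOrigin[2] + k * fixPitch - centerUm[2];
    for (int j = 0; j < ny; j += stride) {
      double yf = fixOrigin[1] + j * fixPitch - centerUm[1];
      for (int i = 0; i < nx; i += stride) {
        long fi = idx3(i, j, k, nx, ny);
        if (useKeep && !keep[fi]) continue;
        double xf = fixOrigin[0] + i * fixPitch - centerUm[0];
        double xm = R[0][0] * xf + R[0][1] * yf + R[0][2] * zf + centerUm[0] + transUm[0];
        double ym = R[1][0] * xf + R[1][1] * yf + R[1][2] * zf + centerUm[1] + transUm[1];
        double zm = R[2][0] * xf + R[2][1] * yf + R[2][2] * zf + centerUm[2] + transUm[2];
        double a = fixVals[fi];
        double b = trilinear(movVals, mnx, mny, mnz,
                             (xm - movOrigin[0]) / movPitch,
                             (ym - movOrigin[1]) / movPitch,
                             (zm - movOrigin[2]) / movPitch, background);
        sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
        ++n;
      }
    }
  }
  if (n < 2) return -1.0;
  double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  if (va <= 0 || vb <= 0) return -1.0;
  return (sab - sa * sb / n) / sqrt(va * vb);
}

static void blur_axis(std::vector<double> &vals, int nx, int ny, int nz,
                      int axis, const std::vector<double> &kern) {
  int r = (int)kern.size() / 2;
  int n[3] = {nx, ny, nz};
  std::vector<double> out(vals.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        int pos[3] = {i, j, k};
        for (int t = -r; t <= r; ++t) {
          int p[3] = {i, j, k};
          int q = pos[axis] + t;
          if (q < 0) q = 0;
          if (q >= n[axis]) q = n[axis] - 1;
          p[axis] = q;
          acc += kern[t + r] * vals[idx3(p[0], p[1], p[2], nx, ny)];
        }
        out[idx3(i, j, k, nx, ny)] = acc;
      }
  vals.swap(out);
}

// Separable Gaussian blur, sigma in voxels, replicate boundary.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector inVals, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> vals(inVals.begin(), inVals.end());
  if (sigma > 0) {
    int r = (int)ceil(3.0 * sigma);
    std::vector<double> kern(2 * r + 1);
    double s = 0;
    for (int t = -r; t <= r; ++t) { kern[t + r] = exp(-0.5 * t * t / (sigma * sigma)); s += kern[t + r]; }
    for (size_t t = 0; t < kern.size(); ++t) kern[t] /= s;
    blur_axis(vals, nx, ny, nz, 0, kern);
    blur_axis(vals, nx, ny, nz, 1, kern);
    blur_axis(vals, nx, ny, nz, 2, kern);
  }
  return NumericVector(vals.begin(), vals.end());
}

static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e20; z[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e20;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) k++;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) to the nearest foreground voxel.
// [[Rcpp::export]]
NumericVector cpp_sqedt(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long total = (long)nx * ny * nz;
  std::vector<double> D(total);
  for (long t = 0; t < total; ++t) D[t] = mask[t] ? 0.0 : 1e20;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = D[idx3(i, j, k, nx, ny)];
      edt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) D[idx3(i, j, k, nx, ny)] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[idx3(i, j, k, nx, ny)];
      edt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j) D[idx3(i, j, k, nx, ny)] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = D[idx3(i, j, k, nx, ny)];
      edt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k) D[idx3(i, j, k, nx, ny)] = d[k];
    }
  return NumericVector(D.begin(), D.end());
}

// Background voxels 6-connected to the grid boundary (1 = outside air/water).
// [[Rcpp::export]]
IntegerVector cpp_flood_outside(IntegerVector bg, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long total = (long)nx * ny * nz;
  IntegerVector out(total);
  std::queue<long> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if ((i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1)) {
          long t = idx3(i, j, k, nx, ny);
          if (bg[t] && !out[t]) { out[t] = 1; q.push(t); }
        }
  const long dxs[6] = {1, -1, (long)nx, -(long)nx, (long)nx * ny, -(long)nx * ny};
  while (!q.empty()) {
    long t = q.front(); q.pop();
    long k = t / ((long)nx * ny), rem = t % ((long)nx * ny);
    long j = rem / nx, i = rem % nx;
    for (int m = 0; m < 6; ++m) {
      long ii = i, jj = j, kk = k;
      if (m == 0) ii++; else if (m == 1) ii--;
      else if (m == 2) jj++; else if (m == 3) jj--;
      else if (m == 4) kk++; else kk--;
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      long u = t + dxs[m];
      if (bg[u] && !out[u]) { out[u] = 1; q.push(u); }
    }
  }
  return out;
}

struct P3 { double x, y, z; };

static inline P3 interp_edge(const P3 &a, const P3 &b, double fa, double fb, double iso) {
  double t = (iso - fa) / (fb - fa);
  P3 p;
  p.x = a.x + t * (b.x - a.x);
  p.y = a.y + t * (b.y - a.y);
  p.z = a.z + t * (b.z - a.z);
  return p;
}

static inline double tri_area(const P3 &a, const P3 &b, const P3 &c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  return 0.5 * sqrt(cx * cx + cy * cy + cz * cz);
}

// Isosurface area by marching tetrahedra (6-tet cube decomposition).
// Returns area in voxel^2 units; triangles with centroid z <= zExclude
// (voxel coordinates) are dropped when zExclude is finite.
// [[Rcpp::export]]
double cpp_mt_area(NumericVector field, IntegerVector dim, double iso, double zExclude) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  // cube corner offsets
  static const int off[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  static const int tets[6][4] = {
    {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
    {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  bool excl = R_finite(zExclude);
  double area = 0;
  double fv[8];
  P3 pv[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        for (int c = 0; c < 8; ++c) {
          int ii = i + off[c][0], jj = j + off[c][1], kk = k + off[c][2];
          fv[c] = field[idx3(ii, jj, kk, nx, ny)];
          pv[c].x = ii; pv[c].y = jj; pv[c].z = kk;
        }
        for (int t = 0; t < 6; ++t) {
          int above[4], below[4];
          int na = 0, nb = 0;
          for (int c = 0; c < 4; ++c) {
            int vtx = tets[t][c];
            if (fv[vtx] > iso) above[na++] = vtx; else below[nb++] = vtx;
          }
          if (na == 0 || na == 4) continue;
          P3 tri[4];
          int ntri = 0;
          if (na == 1) {
            tri[0] = interp_edge(pv[above[0]], pv[below[0]], fv[above[0]], fv[below[0]], iso);
            tri[1] = interp_edge(pv[above[0]], pv[below[1]], fv[above[0]], fv[below[1]], iso);
            tri[2] = interp_edge(pv[above[0]], pv[below[2]], fv[above[0]], fv[below[2]], iso);
            ntri = 3;
          } else if (na == 3) {
            tri[0] = interp_edge(pv[below[0]], pv[above[0]], fv[below[0]], fv[above[0]], iso);
            tri[1] = interp_edge(pv[below[0]], pv[above[1]], fv[below[0]], fv[above[1]], iso);
            tri[2] = interp_edge(pv[below[0]], pv[above[2]], fv[below[0]], fv[above[2]], iso);
            ntri = 3;
          } else { // na == 2 -> quad
            tri[0] = interp_edge(pv[above[0]], pv[below[0]], fv[above[0]], fv[below[0]], iso);
            tri[1] = interp_edge(pv[above[0]], pv[below[1]], fv[above[0]], fv[below[1]], iso);
            tri[2] = interp_edge(pv[above[1]], pv[below[1]], fv[above[1]], fv[below[1]], iso);
            tri[3] = interp_edge(pv[above[1]], pv[below[0]], fv[above[1]], fv[below[0]], iso);
            ntri = 4;
          }
          if (ntri == 3) {
            if (!excl || (tri[0].z + tri[1].z + tri[2].z) / 3.0 > zExclude)
              area += tri_area(tri[0], tri[1], tri[2]);
          } else {
            if (!excl || (tri[0].z + tri[1].z + tri[2].z) / 3.0 > zExclude)
              area += tri_area(tri[0], tri[1], tri[2]);
            if (!excl || (tri[0].z + tri[2].z + tri[3].z) / 3.0 > zExclude)
              area += tri_area(tri[0], tri[2], tri[3]);
          }
        }
      }
  return area;
}
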