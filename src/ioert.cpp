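#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// All arrays are column-major with 0-based (i, j, k) and linear index
// i + nx * (j + ny * k). World coordinates assume an axis-aligned grid:
// world = origin + index * spacing (handled in R where orientation matters).

static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, double outside) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
    return outside;
  // clamp to the valid interpolation cube (edge voxels extend half a voxel)
  if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1;
  if (y > ny - 1) y = ny - 1;
  if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  if (nx == 1) x0 = 0; if (ny == 1) y0 = 0; if (nz == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (nx == 1) fx = 0; if (ny == 1) fy = 0; if (nz == 1) fz = 0;
  int x1 = nx == 1 ? x0 : x0 + 1, y1 = ny == 1 ? y0 : y0 + 1,
      z1 = nz == 1 ? z0 : z0 + 1;
  size_t sxy = (size_t)nx * ny;
  const double *p000 = v + x0 + (size_t)nx * y0 + sxy * z0;
  double c000 = p000[0];
  double c100 = v[x1 + (size_t)nx * y0 + sxy * z0];
  double c010 = v[x0 + (size_t)nx * y1 + sxy * z0];
  double c110 = v[x1 + (size_t)nx * y1 + sxy * z0];
  double c001 = v[x0 + (size_t)nx * y0 + sxy * z1];
  double c101 = v[x1 + (size_t)nx * y0 + sxy * z1];
  double c011 = v[x0 + (size_t)nx * y1 + sxy * z1];
  double c111 = v[x1 + (size_t)nx * y1 + sxy * z1];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts, double outside) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t q = 0; q < n; ++q)
    out[q] = trilinear(v, nx, ny, nz, pts(q, 0), pts(q, 1), pts(q, 2), outside);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector vol, IntegerVector dim,
                                 NumericMatrix pts, double outside) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t q = 0; q < n; ++q) {
    long i = lround(pts(q, 0)), j = lround(pts(q, 1)), k = lround(pts(q, 2));
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      out[q] = outside;
    else
      out[q] = v[i + (size_t)nx * j + (size_t)nx * ny * k];
  }
  return out;
}

static void neighbour_offsets(int connectivity, int nx, int ny,
                              std::vector<long> &offs,
                              std::vector<int> &di, std::vector<int> &dj,
                              std::vector<int> &dk) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nz_comp = std::abs(a) + std::abs(b) + std::abs(c);
        if (nz_comp == 0) continue;
        if (connectivity == 6 && nz_comp != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
        offs.push_back((long)a + (long)nx * b + (long)nx * ny * c);
      }
}

// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim,
                              double hu_min, double hu_max,
                              IntegerMatrix seeds, Nullable<LogicalVector> constraint,
                              int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const double *v = REAL(vol);
  const int *cons = nullptr;
  LogicalVector consv;
  if (constraint.isNotNull()) { consv = constraint.get(); cons = LOGICAL(consv); }
  LogicalVector out(n, false);
  int *o = LOGICAL(out);
  std::vector<long> offs; std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, nx, ny, offs, di, dj, dk);
  std::queue<std::array<int,3>> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int i = seeds(s, 0), j = seeds(s, 1), k = seeds(s, 2);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      stop("seed outside volume");
    size_t idx = i + (size_t)nx * j + (size_t)nx * ny * k;
    double hv = v[idx];
    if (hv < hu_min || hv > hu_max)
      stop("seed HU value %f outside the [%f, %f] window", hv, hu_min, hu_max);
    if (cons && !cons[idx]) continue;
    if (!o[idx]) { o[idx] = true; q.push({i, j, k}); }
  }
  while (!q.empty()) {
    auto c = q.front(); q.pop();
    size_t idx = c[0] + (size_t)nx * c[1] + (size_t)nx * ny * c[2];
    for (size_t m = 0; m < offs.size(); ++m) {
      int i = c[0] + di[m], j = c[1] + dj[m], k = c[2] + dk[m];
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
      size_t nb = idx + offs[m];
      if (o[nb]) continue;
      double hv = v[nb];
      if (hv < hu_min || hv > hu_max) continue;
      if (cons && !cons[nb]) continue;
      o[nb] = true;
      q.push({i, j, k});
    }
  }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const int *m = LOGICAL(mask);
  IntegerVector lab(n, 0);
  int *L = INTEGER(lab);
  std::vector<long> offs; std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, nx, ny, offs, di, dj, dk);
  int cur = 0;
  std::queue<std::array<int,3>> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i + (size_t)nx * j + (size_t)nx * ny * k;
        if (!m[idx] || L[idx]) continue;
        ++cur;
        L[idx] = cur;
        q.push({i, j, k});
        while (!q.empty()) {
          auto c = q.front(); q.pop();
          size_t cidx = c[0] + (size_t)nx * c[1] + (size_t)nx * ny * c[2];
          for (size_t t = 0; t < offs.size(); ++t) {
            int ii = c[0] + di[t], jj = c[1] + dj[t], kk = c[2] + dk[t];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t nb = cidx + offs[t];
            if (!m[nb] || L[nb]) continue;
            L[nb] = cur;
            q.push({ii, jj, kk});
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// one pass of 26- (box) or 6- (cross) neighbourhood dilation/erosion
static LogicalVector morph_pass(LogicalVector mask, IntegerVector dim,
                                int connectivity, bool dilate) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const int *m = LOGICAL(mask);
  LogicalVector out(n);
  int *o = LOGICAL(out);
  std::vector<long> offs; std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, nx, ny, offs, di, dj, dk);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i + (size_t)nx * j + (size_t)nx * ny * k;
        bool val = m[idx];
        if (dilate ? val : !val) { o[idx] = val; continue; }
        bool hit = false;
        for (size_t t = 0; t < offs.size() && !hit; ++t) {
          int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
            if (!dilate) hit = true;  // outside counts as background
            continue;
          }
          bool nb = m[idx + offs[t]];
          if (dilate ? nb : !nb) hit = true;
        }
        o[idx] = dilate ? hit : !hit;
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim, int radius,
                        int connectivity, bool dilate) {
  LogicalVector cur = mask;
  for (int r = 0; r < radius; ++r) cur = morph_pass(cur, dim, connectivity, dilate);
  if (radius == 0) { cur = clone(mask); cur.attr("dim") = dim; }
  return cur;
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out = clone(vol);
  std::vector<double> buf(std::max({nx, ny, nz}));
  int dims[3] = {nx, ny, nz};
  size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3 * s);
    std::vector<double> w(2 * r + 1);
    double sum = 0;
    for (int t = -r; t <= r; ++t) { w[t + r] = std::exp(-0.5 * t * t / (s * s)); sum += w[t + r]; }
    for (auto &x : w) x /= sum;
    int nA = dims[ax];
    size_t sA = strides[ax];
    int b1 = (ax == 0) ? 1 : 0, b2 = (ax == 2) ? 1 : 2;
    int n1 = dims[b1], n2 = dims[b2];
    size_t s1 = strides[b1], s2 = strides[b2];
    double *v = REAL(out);
    for (int j2 = 0; j2 < n2; ++j2)
      for (int j1 = 0; j1 < n1; ++j1) {
        size_t base = s1 * j1 + s2 * j2;
        for (int a = 0; a < nA; ++a) {
          double acc = 0, wn = 0;
          int lo = std::max(0, a - r), hi = std::min(nA - 1, a + r);
          for (int t = lo; t <= hi; ++t) { acc += w[t - a + r] * v[base + sA * t]; wn += w[t - a + r]; }
          buf[a] = acc / wn;
        }
        for (int a = 0; a < nA; ++a) v[base + sA * a] = buf[a];
      }
  }
  out.attr("dim") = dim;
  return out;
}

// Water-equivalent path length from each point back to the ray's crossing of
// the bevel plane, integrating a density volume along the ray from a virtual
// point source. Midpoint rule with step <= `step` mm.
// [[Rcpp::export]]
NumericVector cpp_ray_wepl(NumericVector dens, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           NumericVector source, NumericVector bevel_c,
                           NumericVector bevel_n, NumericMatrix pts,
                           double step, double outside_density) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = REAL(dens);
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  double ncs = bevel_n[0] * (bevel_c[0] - source[0]) +
               bevel_n[1] * (bevel_c[1] - source[1]) +
               bevel_n[2] * (bevel_c[2] - source[2]);
  for (R_xlen_t q = 0; q < n; ++q) {
    double ux = pts(q, 0) - source[0], uy = pts(q, 1) - source[1],
           uz = pts(q, 2) - source[2];
    double nu = bevel_n[0] * ux + bevel_n[1] * uy + bevel_n[2] * uz;
    if (nu <= 0) { out[q] = NA_REAL; continue; }  // ray parallel/backwards
    double tb = ncs / nu;                          // plane crossing parameter
    if (tb >= 1) { out[q] = 0.0; continue; }       // point proximal to plane
    double qx = source[0] + tb * ux, qy = source[1] + tb * uy,
           qz = source[2] + tb * uz;
    double dx = pts(q, 0) - qx, dy = pts(q, 1) - qy, dz = pts(q, 2) - qz;
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    int ns = (int)std::ceil(L / step);
    if (ns < 1) ns = 1;
    double h = L / ns, acc = 0;
    for (int s = 0; s < ns; ++s) {
      double f = (s + 0.5) / ns;
      double wx = qx + f * dx, wy = qy + f * dy, wz = qz + f * dz;
      acc += trilinear(v, nx, ny, nz,
                       (wx - origin[0]) / spacing[0],
                       (wy - origin[1]) / spacing[1],
                       (wz - origin[2]) / spacing[2], outside_density);
    }
    out[q] = acc * h;
  }
  return out;
}

struct GOffset { double ox, oy, oz, d2; };

static std::vector<GOffset> gamma_offsets(const NumericVector &step_mm,
                                          double radius, bool sorted) {
  std::vector<GOffset> offs;
  int mx = (int)std::floor(radius / step_mm[0]);
  int my = (int)std::floor(radius / step_mm[1]);
  int mz = (int)std::floor(radius / step_mm[2]);
  double r2 = radius * radius;
  for (int a = -mx; a <= mx; ++a)
    for (int b = -my; b <= my; ++b)
      for (int c = -mz; c <= mz; ++c) {
        double ox = a * step_mm[0], oy = b * step_mm[1], oz = c * step_mm[2];
        double d2 = ox * ox + oy * oy + oz * oz;
        if (d2 <= r2) offs.push_back({ox, oy, oz, d2});
      }
  if (sorted)
    std::sort(offs.begin(), offs.end(),
              [](const GOffset &u, const GOffset &w) { return u.d2 < w.d2; });
  return offs;
}

static NumericVector gamma_core(NumericVector ref, NumericVector eval,
                                IntegerVector dim, NumericVector spacing,
                                LogicalVector mask, NumericVector dd_abs,
                                double dta, NumericVector step_mm,
                                double radius, bool pruned) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const double *rv = REAL(ref);
  const double *ev = REAL(eval);
  const int *m = LOGICAL(mask);
  bool dd_scalar = dd_abs.size() == 1;
  NumericVector out(n, NA_REAL);
  double *o = REAL(out);
  std::vector<GOffset> offs = gamma_offsets(step_mm, radius, pruned);
  double dta2 = dta * dta;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i + (size_t)nx * j + (size_t)nx * ny * k;
        if (!m[idx]) continue;
        double ddv = dd_scalar ? dd_abs[0] : dd_abs[idx];
        double dd2 = ddv * ddv;
        double rd = rv[idx];
        double wx = i * spacing[0], wy = j * spacing[1], wz = k * spacing[2];
        double best = R_PosInf;
        bool any = false;
        for (size_t t = 0; t < offs.size(); ++t) {
          double dist2 = offs[t].d2 / dta2;
          if (pruned && dist2 >= best) break;  // sorted: no later offset can win
          double x = (wx + offs[t].ox) / spacing[0];
          double y = (wy + offs[t].oy) / spacing[1];
          double z = (wz + offs[t].oz) / spacing[2];
          if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
            continue;  // evaluated dose undefined outside the grid
          any = true;
          double de = trilinear(ev, nx, ny, nz, x, y, z, 0.0) - rd;
          double g2 = dist2 + de * de / dd2;
          if (g2 < best) best = g2;
        }
        o[idx] = any ? std::sqrt(best) : R_PosInf;
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gamma_search(NumericVector ref, NumericVector eval,
                               IntegerVector dim, NumericVector spacing,
                               LogicalVector mask, NumericVector dd_abs,
                               double dta, NumericVector step_mm,
                               double radius) {
  return gamma_core(ref, eval, dim, spacing, mask, dd_abs, dta, step_mm,
                    radius, true);
}

// Exhaustive variant: every lattice offset inside the search sphere is
// visited, in raw construction order, with no pruning. Kept as an
// independent code path for verification.
// [[Rcpp::export]]
NumericVector cpp_gamma_brute(NumericVector ref, NumericVector eval,
                              IntegerVector dim, NumericVector spacing,
                              LogicalVector mask, NumericVector dd_abs,
                              double dta, NumericVector step_mm,
                              double radius) {
  return gamma_core(ref, eval, dim, spacing, mask, dd_abs, dta, step_mm,
                    radius, false);
}
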