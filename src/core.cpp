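#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Linear index of (i,j,k) in a column-major nx*ny*nz array (0-based).
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Seeded volume growing: maximal connected in-window component containing the
// seeds, restricted to the inclusive bounding box [lo, hi].  All indices 0-based.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(NumericVector vol, IntegerVector dims,
                             IntegerMatrix seeds, double lower, double upper,
                             IntegerVector lo, IntegerVector hi,
                             int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector mask(vol.size(), false);
  std::vector<char> seen((size_t)vol.size(), 0);

  // neighbourhood offsets
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back({dx, dy, dz});
      }

  std::queue<std::array<int,3>> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int i = seeds(s,0), j = seeds(s,1), k = seeds(s,2);
    R_xlen_t id = lin(i, j, k, nx, ny);
    if (!seen[id]) { seen[id] = 1; q.push({i, j, k}); mask[id] = true; }
  }
  while (!q.empty()) {
    std::array<int,3> c = q.front(); q.pop();
    for (const auto &o : off) {
      int i = c[0] + o[0], j = c[1] + o[1], k = c[2] + o[2];
      if (i < lo[0] || i > hi[0] || j < lo[1] || j > hi[1] ||
          k < lo[2] || k > hi[2]) continue;
      R_xlen_t id = lin(i, j, k, nx, ny);
      if (seen[id]) continue;
      seen[id] = 1;
      double v = vol[id];
      if (v >= lower && v <= upper) { mask[id] = true; q.push({i, j, k}); }
    }
  }
  return mask;
}

static inline double trilin_at(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, double oob,
                               bool *inside) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    *inside = false; return oob;
  }
  *inside = true;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--; if (j0 == ny - 1) j0--; if (k0 == nz - 1) k0--;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const double *p = v;
  double c000 = p[lin(i0,   j0,   k0,   nx, ny)];
  double c100 = p[lin(i0+1, j0,   k0,   nx, ny)];
  double c010 = p[lin(i0,   j0+1, k0,   nx, ny)];
  double c110 = p[lin(i0+1, j0+1, k0,   nx, ny)];
  double c001 = p[lin(i0,   j0,   k0+1, nx, ny)];
  double c101 = p[lin(i0+1, j0,   k0+1, nx, ny)];
  double c011 = p[lin(i0,   j0+1, k0+1, nx, ny)];
  double c111 = p[lin(i0+1, j0+1, k0+1, nx, ny)];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Trilinear interpolation of a volume at continuous 0-based voxel coordinates.
// Points outside the grid get `oob` (pass NA_real_ to mark them).
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts, double oob) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  bool inside;
  for (R_xlen_t r = 0; r < n; ++r)
    out[r] = trilin_at(REAL(vol), nx, ny, nz,
                       pts(r,0), pts(r,1), pts(r,2), oob, &inside);
  return out;
}

// Nearest-neighbour lookup of an integer label volume at continuous coords.
// [[Rcpp::export]]
IntegerVector cpp_nearest(IntegerVector labs, IntegerVector dims,
                          NumericMatrix pts, int oob) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = pts.nrow();
  IntegerVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    int i = (int)std::lround(pts(r,0));
    int j = (int)std::lround(pts(r,1));
    int k = (int)std::lround(pts(r,2));
    out[r] = (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      ? oob : labs[lin(i, j, k, nx, ny)];
  }
  return out;
}

// Orthographic front-to-back ray casting with per-label dense opacity tables.
// origins: one ray start per pixel, in continuous 0-based voxel coordinates;
// step: the per-sample increment in voxel coordinates.  alpha_tab has one row
// per label id (0..L-1) with K opacity samples spanning [imin, imax] (already
// corrected for the step length); colors is L x 3 in [0,1].
// [[Rcpp::export]]
List cpp_raycast(NumericVector vol, IntegerVector labs, IntegerVector dims,
                 NumericMatrix origins, NumericVector step, int nsteps,
                 NumericMatrix alpha_tab, NumericMatrix colors,
                 double imin, double imax, double stop_alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int L = alpha_tab.nrow(), K = alpha_tab.ncol();
  const double rng = (imax > imin) ? (imax - imin) : 1.0;
  R_xlen_t n = origins.nrow();
  NumericMatrix rgb(n, 3);
  NumericVector acc(n);
  bool inside;
  for (R_xlen_t r = 0; r < n; ++r) {
    double x = origins(r,0), y = origins(r,1), z = origins(r,2);
    double A = 0.0, R0 = 0.0, G0 = 0.0, B0 = 0.0;
    for (int s = 0; s < nsteps; ++s, x += step[0], y += step[1], z += step[2]) {
      if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
        continue;
      int li = (int)std::lround(x), lj = (int)std::lround(y),
          lk = (int)std::lround(z);
      int lab = labs[lin(li, lj, lk, nx, ny)];
      if (lab < 0 || lab >= L) continue;
      double it = trilin_at(REAL(vol), nx, ny, nz, x, y, z, 0.0, &inside);
      // linear interpolation into the dense opacity table
      double u = (it - imin) / rng * (K - 1);
      double a;
      if (u <= 0) a = alpha_tab(lab, 0);
      else if (u >= K - 1) a = alpha_tab(lab, K - 1);
      else {
        int b = (int)std::floor(u);
        double f = u - b;
        a = alpha_tab(lab, b) * (1 - f) + alpha_tab(lab, b + 1) * f;
      }
      if (a <= 0) continue;
      double w = (1 - A) * a;
      R0 += w * colors(lab, 0);
      G0 += w * colors(lab, 1);
      B0 += w * colors(lab, 2);
      A += w;
      if (A >= stop_alpha) break;
    }
    rgb(r,0) = R0; rgb(r,1) = G0; rgb(r,2) = B0; acc[r] = A;
  }
  return List::create(_["rgb"] = rgb, _["alpha"] = acc);
}

// CRC-32 (ISO 3309, as used by PNG chunks).
// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFu);
}

// Trilinear sampling at affine-mapped integer grid points: for each row of
// `idx` (0-based voxel indices of the fixed grid), sample the moving volume
// at A[,1:3] %*% idx + A[,4] (continuous 0-based moving-voxel coords).
// Out-of-field samples get NaN.
// [[Rcpp::export]]
NumericVector cpp_affine_trilinear(NumericVector vol, IntegerVector dims,
                                   NumericMatrix idx, NumericMatrix A) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double a11 = A(0,0), a12 = A(0,1), a13 = A(0,2), a14 = A(0,3);
  const double a21 = A(1,0), a22 = A(1,1), a23 = A(1,2), a24 = A(1,3);
  const double a31 = A(2,0), a32 = A(2,1), a33 = A(2,2), a34 = A(2,3);
  bool inside;
  for (R_xlen_t r = 0; r < n; ++r) {
    double i = idx(r,0), j = idx(r,1), k = idx(r,2);
    double x = a11*i + a12*j + a13*k + a14;
    double y = a21*i + a22*j + a23*k + a24;
    double z = a31*i + a32*j + a33*k + a34;
    out[r] = trilin_at(REAL(vol), nx, ny, nz, x, y, z, R_NaReal, &inside);
  }
  return out;
}

// Weighted 2-D joint histogram for partial-volume MI: mass (1-w) goes to
// (fb, b0) and w to (fb, b0+1); fb, b0 are 1-based, b0 in [1, bins-1].
// [[Rcpp::export]]
NumericMatrix cpp_whist2(IntegerVector fb, IntegerVector b0,
                         NumericVector w, int bins) {
  NumericMatrix jm(bins, bins);
  R_xlen_t n = fb.size();
  for (R_xlen_t r = 0; r < n; ++r) {
    jm(fb[r] - 1, b0[r] - 1) += 1.0 - w[r];
    jm(fb[r] - 1, b0[r]) += w[r];
  }
  return jm;
}
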