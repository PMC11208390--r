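// Condensed-history beta transport on a voxel density grid, plus a sparse
// direct 3-D convolution. The RNG is self-contained (xoshiro256+) so results
// are reproducible bit-for-bit from an integer seed regardless of R's RNG
// state or platform stdlib.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  bool have_g = false;
  double g2 = 0.0;
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  Rng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL ^ (stream + 0xD1B54A32D192ED03ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  double norm() {  // Marsaglia polar, cached second deviate
    if (have_g) { have_g = false; return g2; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0; v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    g2 = v * f; have_g = true;
    return u * f;
  }
};

// uniform-log-grid lookup (clamped linear interpolation)
struct LogTable {
  const double *loge, *y;
  int n;
  double lo, step;
  LogTable(const NumericVector &le, const NumericVector &yy)
      : loge(le.begin()), y(yy.begin()), n(le.size()) {
    lo = loge[0];
    step = (loge[n - 1] - loge[0]) / (n - 1);
  }
  double at(double e_mev) const {
    double t = (std::log(e_mev) - lo) / step;
    if (t <= 0) return y[0];
    if (t >= n - 1) return y[n - 1];
    int i = (int)t;
    double f = t - i;
    return y[i] * (1 - f) + y[i + 1] * f;
  }
};

inline void ortho_basis(const double d[3], double u[3], double v[3]) {
  // pick the axis least aligned with d
  double ax = std::fabs(d[0]), ay = std::fabs(d[1]), az = std::fabs(d[2]);
  double a[3] = {0, 0, 0};
  if (ax <= ay && ax <= az) a[0] = 1; else if (ay <= az) a[1] = 1; else a[2] = 1;
  // u = normalize(a x d)
  u[0] = a[1] * d[2] - a[2] * d[1];
  u[1] = a[2] * d[0] - a[0] * d[2];
  u[2] = a[0] * d[1] - a[1] * d[0];
  double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  for (int i = 0; i < 3; ++i) u[i] /= nu;
  v[0] = d[1] * u[2] - d[2] * u[1];
  v[1] = d[2] * u[0] - d[0] * u[2];
  v[2] = d[0] * u[1] - d[1] * u[0];
}

struct Engine {
  const double *dens;
  int nx, ny, nz;
  double sx, sy, sz, min_sp;
  LogTable stab, rtab;
  double cutoff, f_vox, f_rng;
  bool ms_on;
  double *edep;
  double escaped = 0.0, path_mm = 0.0;

  Engine(const NumericVector &density, const IntegerVector &dims,
         const NumericVector &spacing, const NumericVector &loge,
         const NumericVector &s_grid, const NumericVector &r_grid,
         double cutoff_mev, double frac_voxel, double frac_range,
         bool ms, double *edep_out)
      : dens(density.begin()), nx(dims[0]), ny(dims[1]), nz(dims[2]),
        sx(spacing[0]), sy(spacing[1]), sz(spacing[2]),
        stab(loge, s_grid), rtab(loge, r_grid),
        cutoff(cutoff_mev), f_vox(frac_voxel), f_rng(frac_range),
        ms_on(ms), edep(edep_out) {
    min_sp = std::min(sx, std::min(sy, sz));
  }

  inline long idx_of(const double p[3]) const {
    int i = (int)std::floor(p[0] / sx);
    int j = (int)std::floor(p[1] / sy);
    int k = (int)std::floor(p[2] / sz);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return -1;
    return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
  }

  // transports one electron; all deposited + escaped energy == e0 exactly
  void history(double p[3], double d[3], double e0, Rng &rng) {
    double e = e0;
    for (;;) {
      long ci = idx_of(p);
      if (ci < 0) { escaped += e; return; }
      if (e < cutoff) { edep[ci] += e; return; }
      double rho = dens[ci];
      double ds;  // mm
      if (rho > 1e-9) {
        double r_res_cm = rtab.at(e) / rho;  // g/cm2 -> cm
        ds = std::min(f_vox * min_sp, f_rng * r_res_cm * 10.0);
        if (ds < 1e-4) ds = 1e-4;
      } else {
        ds = f_vox * min_sp;  // vacuum: drift without loss
      }
      double mid[3] = {p[0] + 0.5 * ds * d[0], p[1] + 0.5 * ds * d[1],
                       p[2] + 0.5 * ds * d[2]};
      long mi = idx_of(mid);
      if (mi < 0) { escaped += e; return; }
      double de = (rho > 1e-9) ? stab.at(e) * rho * ds * 0.1 : 0.0;
      if (rho > 1e-9 && e - de <= cutoff) {  // terminal step
        edep[mi] += e;
        path_mm += ds;
        return;
      }
      edep[mi] += de;
      e -= de;
      p[0] += ds * d[0]; p[1] += ds * d[1]; p[2] += ds * d[2];
      path_mm += ds;
      if (ms_on && rho > 1e-9) {
        double x_rad = rho * ds * 0.1 / 36.08;  // fraction of X0 of water
        double pbc = e * (e + 2.0 * 0.51099895) / (e + 0.51099895);
        double th0 = 13.6 / pbc * std::sqrt(x_rad) *
                     (1.0 + 0.038 * std::log(x_rad));
        if (th0 > 0) {
          double u[3], v[3];
          ortho_basis(d, u, v);
          double tx = th0 * rng.norm(), ty = th0 * rng.norm();
          for (int i = 0; i < 3; ++i) d[i] += tx * u[i] + ty * v[i];
          double nd = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
          for (int i = 0; i < 3; ++i) d[i] /= nd;
        }
      }
    }
  }
};

inline int sample_cdf(const double *cdf, int n, double u) {
  // first index with cdf[i] >= u  (cdf has length n, non-decreasing, ends 1)
  int lo = 0, hi = n - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

inline double sample_energy(const NumericVector &ce, const NumericVector &cc,
                            Rng &rng) {
  double u = rng.unif();
  int n = cc.size();
  int i = sample_cdf(cc.begin(), n, u);
  if (i == 0) return ce[0];
  double c0 = cc[i - 1], c1 = cc[i];
  double f = (c1 > c0) ? (u - c0) / (c1 - c0) : 0.0;
  return ce[i - 1] + f * (ce[i] - ce[i - 1]);
}

}  // namespace

// [[Rcpp::export]]
List mc_transport_cpp(NumericVector tia_cdf, NumericVector density,
                      IntegerVector dims, NumericVector spacing,
                      NumericVector spec_cdf_e, NumericVector spec_cdf,
                      NumericVector loge, NumericVector s_grid,
                      NumericVector r_grid, int n_primaries,
                      double seed, double stream, double cutoff_mev,
                      double frac_voxel, double frac_range, bool ms_on) {
  long nvox = (long)dims[0] * dims[1] * dims[2];
  NumericVector edep(nvox);
  Engine eng(density, dims, spacing, loge, s_grid, r_grid, cutoff_mev,
             frac_voxel, frac_range, ms_on, edep.begin());
  Rng rng((uint64_t)seed, (uint64_t)stream);
  double e_init = 0.0;
  const int nx = dims[0], ny = dims[1];
  for (int h = 0; h < n_primaries; ++h) {
    long vi = sample_cdf(tia_cdf.begin(), tia_cdf.size(), rng.unif());
    int k = (int)(vi / ((long)nx * ny));
    int j = (int)((vi / nx) % ny);
    int i = (int)(vi % nx);
    double p[3] = {(i + rng.unif()) * spacing[0],
                   (j + rng.unif()) * spacing[1],
                   (k + rng.unif()) * spacing[2]};
    double mu = 2.0 * rng.unif() - 1.0;
    double phi = 2.0 * M_PI * rng.unif();
    double st = std::sqrt(1.0 - mu * mu);
    double d[3] = {st * std::cos(phi), st * std::sin(phi), mu};
    double e0 = sample_energy(spec_cdf_e, spec_cdf, rng);
    e_init += e0;
    eng.history(p, d, e0, rng);
  }
  return List::create(_["edep"] = edep, _["escaped"] = eng.escaped,
                      _["e_init"] = e_init);
}

// [[Rcpp::export]]
List mc_history_cpp(NumericVector start_mm, NumericVector direction,
                    double energy_mev, NumericVector density,
                    IntegerVector dims, NumericVector spacing,
                    NumericVector loge, NumericVector s_grid,
                    NumericVector r_grid, double seed, double cutoff_mev,
                    double frac_voxel, double frac_range, bool ms_on) {
  long nvox = (long)dims[0] * dims[1] * dims[2];
  NumericVector edep(nvox);
  Engine eng(density, dims, spacing, loge, s_grid, r_grid, cutoff_mev,
             frac_voxel, frac_range, ms_on, edep.begin());
  Rng rng((uint64_t)seed, 0ULL);
  double p[3] = {start_mm[0], start_mm[1], start_mm[2]};
  double nd = std::sqrt(direction[0] * direction[0] +
                        direction[1] * direction[1] +
                        direction[2] * direction[2]);
  double d[3] = {direction[0] / nd, direction[1] / nd, direction[2] / nd};
  eng.history(p, d, energy_mev, rng);
  return List::create(_["edep"] = edep, _["escaped"] = eng.escaped,
                      _["path_mm"] = eng.path_mm);
}

// Direct (spatial-domain) linear convolution with zero boundary. Skips zero
// kernel entries, so compact kernels cost O(nonzeros * volume).
// [[Rcpp::export]]
NumericVector conv3_cpp(NumericVector vol, IntegerVector vd,
                        NumericVector ker, IntegerVector kd) {
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const int kx = kd[0], ky = kd[1], kz = kd[2];
  const int cx = (kx - 1) / 2, cy = (ky - 1) / 2, cz = (kz - 1) / 2;
  NumericVector out((long)nx * ny * nz);
  const double *v = vol.begin();
  double *o = out.begin();
  for (int c = 0; c < kz; ++c) {
    for (int b = 0; b < ky; ++b) {
      for (int a = 0; a < kx; ++a) {
        double kv = ker[(long)a + kx * ((long)b + ky * (long)c)];
        if (kv == 0.0) continue;
        int ox = a - cx, oy = b - cy, oz = c - cz;  // out = src + offset
        int x0 = std::max(0, ox), x1 = std::min(nx, nx + ox);
        int y0 = std::max(0, oy), y1 = std::min(ny, ny + oy);
        int z0 = std::max(0, oz), z1 = std::min(nz, nz + oz);
        for (int z = z0; z < z1; ++z) {
          for (int y = y0; y < y1; ++y) {
            long ob = (long)nx * ((long)y + ny * (long)z);
            long vb = (long)nx * ((long)(y - oy) + ny * (long)(z - oz)) - ox;
            for (int x = x0; x < x1; ++x) o[ob + x] += kv * v[vb + x];
          }
        }
      }
    }
  }
  return out;
}
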