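#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Analog Monte Carlo optical photon transport on a voxel grid.
// Distances in mm, attenuation coefficients in 1/mm. Each photon carries
// the full beam energy and is absorbed whole (tissue or nano channel) or
// redirected by Henyey-Greenstein scattering; the world boundary is a
// perfect absorber (photons escape). A dedicated xoshiro256++ generator
// (seeded via splitmix64 from the run seed) keeps runs bit-reproducible
// independent of R's RNG state.

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {           // uniform in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline double unif_open() {      // uniform in (0, 1)
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  inline void unit_circle(double& c, double& s_) {
    double vx, vy, r2;
    do {
      vx = 2.0 * unif() - 1.0; vy = 2.0 * unif() - 1.0;
      r2 = vx * vx + vy * vy;
    } while (r2 > 1.0 || r2 < 1e-24);
    double inv = 1.0 / std::sqrt(r2);
    c = vx * inv; s_ = vy * inv;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_transport(IntegerVector dims, double pitch, NumericVector origin,
                   IntegerVector labels,
                   NumericVector mu_a_mm, NumericVector mu_an_mm,
                   NumericVector mu_s_mm, NumericVector g_hg,
                   NumericVector tip, NumericVector dir0, double disc_radius,
                   double n_hist_d, int max_steps, double seed,
                   bool homogeneous) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double hx = ox + nx * pitch, hy = oy + ny * pitch, hz = oz + nz * pitch;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const long long n_hist = (long long)n_hist_d;
  IntegerVector cnt_tissue(nvox), cnt_nano(nvox);
  int* ct = INTEGER(cnt_tissue);
  int* cn = INTEGER(cnt_nano);
  const int* lab = INTEGER(labels);
  long long n_escaped = 0, n_terminated = 0, n_absorbed = 0;

  Xoshiro rng((uint64_t)seed);

  // orthonormal basis for the source disc
  double d0 = dir0[0], d1 = dir0[1], d2 = dir0[2];
  double ax = 0, ay = 0, az = 1;
  if (std::fabs(d2) >= 0.9) { ax = 1; az = 0; }
  double u1x = d1 * az - d2 * ay, u1y = d2 * ax - d0 * az, u1z = d0 * ay - d1 * ax;
  double n1 = std::sqrt(u1x * u1x + u1y * u1y + u1z * u1z);
  u1x /= n1; u1y /= n1; u1z /= n1;
  double u2x = d1 * u1z - d2 * u1y, u2y = d2 * u1x - d0 * u1z, u2z = d0 * u1y - d1 * u1x;

  const double eps_mm = 1e-9;
  const double m0a = mu_a_mm[0], m0an = mu_an_mm[0], m0s = mu_s_mm[0];
  const double m0t = m0a + m0an + m0s;

  double ux, uy, uz, tau;

  auto hg_scatter = [&](double g) {
    double ctheta;
    if (std::fabs(g) < 1e-8) {
      ctheta = 2.0 * rng.unif() - 1.0;
    } else {
      double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
      ctheta = (1.0 + g * g - f * f) / (2.0 * g);
      if (ctheta > 1.0) ctheta = 1.0; else if (ctheta < -1.0) ctheta = -1.0;
    }
    double stheta = std::sqrt(1.0 - ctheta * ctheta);
    double cph, sph;
    rng.unit_circle(cph, sph);
    if (std::fabs(uz) > 0.99999) {
      double sgn = uz >= 0 ? 1.0 : -1.0;
      ux = stheta * cph; uy = stheta * sph; uz = sgn * ctheta;
    } else {
      double den = std::sqrt(1.0 - uz * uz);
      double nux = stheta * (ux * uz * cph - uy * sph) / den + ux * ctheta;
      double nuy = stheta * (uy * uz * cph + ux * sph) / den + uy * ctheta;
      double nuz = -stheta * cph * den + uz * ctheta;
      double nn = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
      ux = nux / nn; uy = nuy / nn; uz = nuz / nn;
    }
    tau = -std::log(rng.unif_open());
  };

  for (long long h = 0; h < n_hist; ++h) {
    if ((h & 0x3FFFF) == 0) Rcpp::checkUserInterrupt();
    double r = disc_radius * std::sqrt(rng.unif());
    double cp, sp;
    rng.unit_circle(cp, sp);
    double px = tip[0] + r * (cp * u1x + sp * u2x);
    double py = tip[1] + r * (cp * u1y + sp * u2y);
    double pz = tip[2] + r * (cp * u1z + sp * u2z);
    ux = d0; uy = d1; uz = d2;
    tau = -std::log(rng.unif_open());
    int steps = 0;

    if (homogeneous) {
      if (m0t <= 0.0) { ++n_escaped; continue; }  // transparent world
      for (;;) {
        if (++steps > max_steps) { ++n_terminated; break; }
        double s = tau / m0t;
        px += s * ux; py += s * uy; pz += s * uz;
        if (px < ox || px >= hx || py < oy || py >= hy || pz < oz || pz >= hz) {
          ++n_escaped; break;
        }
        double e = rng.unif() * m0t;
        if (e < m0a + m0an) {
          int ix = (int)((px - ox) / pitch);
          int iy = (int)((py - oy) / pitch);
          int iz = (int)((pz - oz) / pitch);
          R_xlen_t idx = (R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
          if (e < m0a) ct[idx]++; else cn[idx]++;
          ++n_absorbed;
          break;
        }
        hg_scatter(g_hg[0]);
      }
      continue;
    }

    for (;;) {
      if (++steps > max_steps) { ++n_terminated; break; }
      int ix = (int)std::floor((px - ox) / pitch);
      int iy = (int)std::floor((py - oy) / pitch);
      int iz = (int)std::floor((pz - oz) / pitch);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        ++n_escaped; break;
      }
      R_xlen_t idx = (R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
      int m = lab[idx] - 1;
      double ma = mu_a_mm[m], man = mu_an_mm[m], ms = mu_s_mm[m];
      double mt = ma + man + ms;

      // distance to the nearest voxel boundary along the direction
      double db = R_PosInf;
      if (ux > 1e-12)       db = ((ix + 1) * pitch + ox - px) / ux;
      else if (ux < -1e-12) db = (ix * pitch + ox - px) / ux;
      if (uy > 1e-12)       { double t = ((iy + 1) * pitch + oy - py) / uy; if (t < db) db = t; }
      else if (uy < -1e-12) { double t = (iy * pitch + oy - py) / uy; if (t < db) db = t; }
      if (uz > 1e-12)       { double t = ((iz + 1) * pitch + oz - pz) / uz; if (t < db) db = t; }
      else if (uz < -1e-12) { double t = (iz * pitch + oz - pz) / uz; if (t < db) db = t; }
      if (db < 0) db = 0;

      if (mt <= 0.0) {
        // transparent voxel: ballistic to the next boundary
        px += (db + eps_mm) * ux; py += (db + eps_mm) * uy; pz += (db + eps_mm) * uz;
        continue;
      }
      double s = tau / mt;
      if (s >= db) {
        // consume optical depth up to the boundary, re-evaluate material
        tau -= mt * db;
        px += (db + eps_mm) * ux; py += (db + eps_mm) * uy; pz += (db + eps_mm) * uz;
        continue;
      }
      // interaction inside this voxel
      px += s * ux; py += s * uy; pz += s * uz;
      double e = rng.unif() * mt;
      if (e < ma) { ct[idx]++; ++n_absorbed; break; }
      if (e < ma + man) { cn[idx]++; ++n_absorbed; break; }
      hg_scatter(g_hg[m]);
    }
  }

  return List::create(_["counts_tissue"] = cnt_tissue,
                      _["counts_nano"] = cnt_nano,
                      _["n_escaped"] = (double)n_escaped,
                      _["n_absorbed"] = (double)n_absorbed,
                      _["n_terminated"] = (double)n_terminated);
}
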