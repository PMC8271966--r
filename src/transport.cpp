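// Voxelized Monte Carlo photon transport for interstitial fiber illumination.
//
// Conventions follow the standard MCML/voxel-MC scheme: exponential optical-depth
// sampling, partial weight absorption w*mua/mut at each interaction site,
// Henyey-Greenstein scattering, Russian roulette below a weight threshold.
// Photons are tracked voxel-by-voxel (DDA traversal) so heterogeneous media are
// handled exactly; escape at the grid boundary terminates the photon.
//
// Units: positions in mm (grid-local: x,y,z in [0, extent)); optical
// coefficients are passed in cm^-1 and converted to mm^-1 internally.
// The returned fluence is the normalized fluence rate (1/cm^2 per unit
// incident power): deposited-energy estimator in absorbing voxels, track-length
// estimator where mua = 0.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256++; one independent stream per fiber so per-fiber results do not
// depend on simulation order.
struct Rng {
  uint64_t s[4];
  bool have_norm;
  double norm_cache;
  explicit Rng(uint64_t seed) : have_norm(false), norm_cache(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform on (0, 1]: safe inside log()
  inline double unif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  inline double norm() {
    if (have_norm) { have_norm = false; return norm_cache; }
    const double u1 = unif(), u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 6.283185307179586 * u2;
    norm_cache = r * std::sin(a);
    have_norm = true;
    return r * std::cos(a);
  }
};

inline void ortho_basis(const double *a, double *u, double *v) {
  // u, v orthonormal and perpendicular to unit vector a
  double ex[3] = {1.0, 0.0, 0.0};
  if (std::fabs(a[0]) > 0.9) { ex[0] = 0.0; ex[1] = 1.0; }
  u[0] = a[1] * ex[2] - a[2] * ex[1];
  u[1] = a[2] * ex[0] - a[0] * ex[2];
  u[2] = a[0] * ex[1] - a[1] * ex[0];
  const double n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= n; u[1] /= n; u[2] /= n;
  v[0] = a[1] * u[2] - a[2] * u[1];
  v[1] = a[2] * u[0] - a[0] * u[2];
  v[2] = a[0] * u[1] - a[1] * u[0];
}

// Launch one photon from a fiber face: radially Gaussian position
// (sigma = core_radius/2, truncated at the core edge) and Gaussian polar angle
// about the fiber axis (sigma = theta_max/2, truncated at theta_max), with
// theta_max = asin(NA / n_medium) precomputed by the caller.
inline void sample_launch_one(const double *fpos, const double *axis,
                              const double *u, const double *v,
                              double core_r, double theta_max,
                              Rng &rng, double *pos, double *dir) {
  double ox = 0.0, oy = 0.0;
  if (core_r > 0.0) {
    const double sr = 0.5 * core_r;
    do {
      ox = rng.norm() * sr;
      oy = rng.norm() * sr;
    } while (ox * ox + oy * oy > core_r * core_r);
  }
  for (int k = 0; k < 3; ++k) pos[k] = fpos[k] + ox * u[k] + oy * v[k];
  if (theta_max <= 0.0) {
    for (int k = 0; k < 3; ++k) dir[k] = axis[k];
    return;
  }
  const double st_sd = 0.5 * theta_max;
  double th;
  do { th = std::fabs(rng.norm()) * st_sd; } while (th > theta_max);
  const double phi = 6.283185307179586 * rng.unif();
  const double sth = std::sin(th), cth = std::cos(th);
  const double cp = std::cos(phi), sp = std::sin(phi);
  for (int k = 0; k < 3; ++k)
    dir[k] = cth * axis[k] + sth * (cp * u[k] + sp * v[k]);
}

// Henyey-Greenstein deflection about the current direction.
inline void hg_scatter(double *d, double g, Rng &rng) {
  double ct;
  if (std::fabs(g) < 1e-6) {
    ct = 2.0 * rng.unif() - 1.0;
  } else {
    const double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
    ct = (1.0 + g * g - t * t) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
  }
  const double st = std::sqrt(1.0 - ct * ct);
  const double phi = 6.283185307179586 * rng.unif();
  const double cp = std::cos(phi), sp = std::sin(phi);
  const double ux = d[0], uy = d[1], uz = d[2];
  if (std::fabs(uz) > 0.99999) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = (uz > 0.0) ? ct : -ct;
  } else {
    const double den = std::sqrt(1.0 - uz * uz);
    d[0] = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    d[1] = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    d[2] = -st * cp * den + uz * ct;
  }
  const double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= n; d[1] /= n; d[2] /= n;
}

} // namespace

// [[Rcpp::export]]
List cpp_sample_launch(NumericVector fpos, NumericVector faxis,
                       double core_diameter, double na, double n_medium,
                       int n, double seed) {
  double axis[3] = {faxis[0], faxis[1], faxis[2]};
  const double an = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                              axis[2] * axis[2]);
  for (int k = 0; k < 3; ++k) axis[k] /= an;
  double u[3], v[3];
  ortho_basis(axis, u, v);
  double theta_max = 0.0;
  if (na > 0.0) {
    double s = na / n_medium;
    if (s > 1.0) s = 1.0;
    theta_max = std::asin(s);
  }
  const double fp[3] = {fpos[0], fpos[1], fpos[2]};
  Rng rng(static_cast<uint64_t>(seed) * 0x9E3779B97f4A7C15ULL + 1ULL);
  NumericMatrix pos(n, 3), dir(n, 3);
  double p[3], d[3];
  for (int i = 0; i < n; ++i) {
    sample_launch_one(fp, axis, u, v, 0.5 * core_diameter, theta_max, rng, p, d);
    for (int k = 0; k < 3; ++k) { pos(i, k) = p[k]; dir(i, k) = d[k]; }
  }
  return List::create(_["position"] = pos, _["direction"] = dir);
}

// [[Rcpp::export]]
List cpp_simulate(IntegerVector dims, double voxel_mm, IntegerVector region,
                  NumericVector mua_cm, NumericVector mus_cm,
                  NumericVector g_reg, NumericVector n_reg,
                  NumericMatrix fib_pos, NumericMatrix fib_axis,
                  NumericVector core_diam, NumericVector na_fib,
                  int photons_per_fiber, double seed,
                  double w_min, double roulette_p, double max_steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const std::size_t nvox = static_cast<std::size_t>(nx) * ny * nz;
  const double h = voxel_mm;
  const double Lx = nx * h, Ly = ny * h, Lz = nz * h;
  const int nreg = mua_cm.size();
  const int nfib = fib_pos.nrow();

  std::vector<double> mua_mm(nreg), mut_mm(nreg), afrac(nreg);
  for (int r = 0; r < nreg; ++r) {
    mua_mm[r] = mua_cm[r] / 10.0;
    mut_mm[r] = (mua_cm[r] + mus_cm[r]) / 10.0;
    afrac[r] = (mut_mm[r] > 0.0) ? mua_mm[r] / mut_mm[r] : 0.0;
  }

  std::vector<double> absorbed(nvox, 0.0); // deposited weight
  std::vector<double> tracklen(nvox, 0.0); // weight * pathlength (mm), mua=0 voxels
  double launched = 0.0, deposited = 0.0, escaped = 0.0, roulette_net = 0.0;
  long long truncated = 0; // photons stopped by the step cap
  const int *reg = INTEGER(region);

  for (int f = 0; f < nfib; ++f) {
    uint64_t sx = static_cast<uint64_t>(seed) * 0x9E3779B97f4A7C15ULL +
                  0xD1B54A32D192ED03ULL * (static_cast<uint64_t>(f) + 1ULL);
    Rng rng(splitmix64(sx));
    double axis[3] = {fib_axis(f, 0), fib_axis(f, 1), fib_axis(f, 2)};
    const double an = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                                axis[2] * axis[2]);
    for (int k = 0; k < 3; ++k) axis[k] /= an;
    double u[3], v[3];
    ortho_basis(axis, u, v);
    const double fp[3] = {fib_pos(f, 0), fib_pos(f, 1), fib_pos(f, 2)};

    // NA cone narrowed by the refractive index of the entry medium
    int fix = std::min(std::max(int(fp[0] / h), 0), nx - 1);
    int fiy = std::min(std::max(int(fp[1] / h), 0), ny - 1);
    int fiz = std::min(std::max(int(fp[2] / h), 0), nz - 1);
    const std::size_t fidx = fix + static_cast<std::size_t>(nx) *
                             (fiy + static_cast<std::size_t>(ny) * fiz);
    const double n_med = n_reg[reg[fidx]];
    double theta_max = 0.0;
    if (na_fib[f] > 0.0) {
      double s = na_fib[f] / n_med;
      if (s > 1.0) s = 1.0;
      theta_max = std::asin(s);
    }

    for (int ph = 0; ph < photons_per_fiber; ++ph) {
      double pos[3], dir[3];
      sample_launch_one(fp, axis, u, v, 0.5 * core_diam[f], theta_max,
                        rng, pos, dir);
      double w = 1.0;
      launched += 1.0;
      // clamp launch position onto the grid (fiber faces sit on the z=0 plane)
      if (pos[0] < 0.0 || pos[0] >= Lx || pos[1] < 0.0 || pos[1] >= Ly ||
          pos[2] < 0.0 || pos[2] >= Lz) {
        if (pos[2] < 0.0 && pos[2] > -1e-9) pos[2] = 0.0;
        if (pos[0] < 0.0 || pos[0] >= Lx || pos[1] < 0.0 || pos[1] >= Ly ||
            pos[2] < 0.0 || pos[2] >= Lz) { escaped += w; continue; }
      }
      int ix = std::min(int(pos[0] / h), nx - 1);
      int iy = std::min(int(pos[1] / h), ny - 1);
      int iz = std::min(int(pos[2] / h), nz - 1);
      double tau = -std::log(rng.unif());
      long long steps = 0;
      bool alive = true;

      while (alive) {
        if (++steps > (long long)max_steps) {
          escaped += w; ++truncated; break;
        }
        const std::size_t idx = ix + static_cast<std::size_t>(nx) *
                                (iy + static_cast<std::size_t>(ny) * iz);
        const int r = reg[idx];
        const double mut = mut_mm[r];

        // distance to the nearest voxel face along dir
        double db = 1e300;
        int bax = -1, bdir = 0;
        const int ijk[3] = {ix, iy, iz};
        for (int k = 0; k < 3; ++k) {
          double t;
          if (dir[k] > 1e-12) {
            t = ((ijk[k] + 1) * h - pos[k]) / dir[k];
            if (t < db) { db = t; bax = k; bdir = 1; }
          } else if (dir[k] < -1e-12) {
            t = (ijk[k] * h - pos[k]) / dir[k];
            if (t < db) { db = t; bax = k; bdir = -1; }
          }
        }
        if (bax < 0) { escaped += w; break; } // degenerate direction
        if (db < 0.0) db = 0.0;

        const double dfree = (mut > 0.0) ? tau / mut : 1e300;
        if (dfree < db) {
          // interaction inside the current voxel
          for (int k = 0; k < 3; ++k) pos[k] += dir[k] * dfree;
          if (mua_mm[r] <= 0.0) {
            tracklen[idx] += w * dfree;
          } else {
            const double dw = w * afrac[r];
            absorbed[idx] += dw;
            deposited += dw;
            w -= dw;
          }
          if (w <= 0.0) break;
          hg_scatter(dir, g_reg[r], rng);
          tau = -std::log(rng.unif());
          if (w < w_min) {
            if (rng.unif() <= roulette_p) {
              roulette_net -= w * (1.0 / roulette_p - 1.0);
              w /= roulette_p;
            } else {
              roulette_net += w;
              break;
            }
          }
        } else {
          // traverse to the voxel face
          if (mut > 0.0) tau -= db * mut;
          if (mua_mm[r] <= 0.0) tracklen[idx] += w * db;
          for (int k = 0; k < 3; ++k) pos[k] += dir[k] * db;
          const int step = bdir;
          if (bax == 0) {
            ix += step;
            pos[0] = (step > 0 ? ix : ix + 1) * h;
            if (ix < 0 || ix >= nx) { escaped += w; alive = false; }
          } else if (bax == 1) {
            iy += step;
            pos[1] = (step > 0 ? iy : iy + 1) * h;
            if (iy < 0 || iy >= ny) { escaped += w; alive = false; }
          } else {
            iz += step;
            pos[2] = (step > 0 ? iz : iz + 1) * h;
            if (iz < 0 || iz >= nz) { escaped += w; alive = false; }
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  // normalized fluence rate, 1/cm^2 per unit incident power
  const double vcm3 = std::pow(h / 10.0, 3.0);
  const double ntot = launched > 0.0 ? launched : 1.0;
  NumericVector nfr(nvox);
  for (std::size_t i = 0; i < nvox; ++i) {
    const int r = reg[i];
    if (mua_cm[r] > 0.0)
      nfr[i] = absorbed[i] / (mua_cm[r] * vcm3 * ntot);
    else
      nfr[i] = (tracklen[i] / 10.0) / (vcm3 * ntot);
  }

  return List::create(
    _["nfr"] = nfr,
    _["launched_weight"] = launched,
    _["deposited_weight"] = deposited,
    _["escaped_weight"] = escaped + roulette_net,
    _["roulette_net"] = roulette_net,
    _["truncated_photons"] = (double)truncated);
}
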