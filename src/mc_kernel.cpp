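// Time-resolved Monte Carlo photon transport through a laterally infinite
// turbid slab, transmittance geometry.  Photons are launched at the origin
// normally into the slab; Fresnel reflection/refraction is applied at both
// faces; photons leaving through the far face within the detector radius are
// binned by total time of flight t = L * n / c.
//
// Two absorption modes:
//   mu_a == 0  -> "white" run (null absorption); absorption is applied later
//                 analytically via exp(-mu_a * v * t).
//   mu_a  > 0  -> analog absorption sampling (photon dies at an interaction
//                 with probability mu_a / mu_t); used as an independent check
//                 of the white-MC identity.
//
// RNG: counter-based splitmix64 stream seeded per photon, so results are
// bit-reproducible and independent of any batching of the photon loop.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double C0_CM_PS = 0.0299792458; // speed of light in vacuum, cm/ps

static inline std::uint64_t mix64(std::uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline std::uint64_t splitmix64_next(std::uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  return mix64(state);
}

// uniform in [0, 1)
static inline double rng_u01(std::uint64_t &state) {
  return (splitmix64_next(state) >> 11) * (1.0 / 9007199254740992.0);
}

// unpolarized Fresnel reflectance for internal incidence (n_in -> n_out),
// cos_i = |cosine of incidence angle|; returns 1 beyond the critical angle
static inline double fresnel_R(double cos_i, double n_in, double n_out) {
  if (n_in == n_out) return 0.0;
  double sin_i2 = 1.0 - cos_i * cos_i;
  if (sin_i2 < 0.0) sin_i2 = 0.0;
  double ratio = n_in / n_out;
  double sin_t2 = ratio * ratio * sin_i2;
  if (sin_t2 >= 1.0) return 1.0; // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n_in * cos_i - n_out * cos_t) / (n_in * cos_i + n_out * cos_t);
  double rp = (n_in * cos_t - n_out * cos_i) / (n_in * cos_t + n_out * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export(name = ".mc_slab_cpp")]]
List mc_slab_cpp(double mu_s_prime, double mu_a, double g, bool henyey_greenstein,
                 double thickness, double n_medium, double n_external,
                 double detector_radius,
                 double t0, double dt, int n_channels,
                 double n_photons, double seed, double time_cutoff_ps) {
  // scattering coefficient actually simulated
  double mu_s = henyey_greenstein ? mu_s_prime / (1.0 - g) : mu_s_prime;
  double mu_t = mu_s + mu_a;
  double inv_mu_t = 1.0 / mu_t;
  double p_absorb = (mu_t > 0.0) ? mu_a / mu_t : 0.0;
  double v = C0_CM_PS / n_medium;            // cm/ps inside the medium
  double max_path = time_cutoff_ps * v;      // path-length cutoff, cm
  double det_r2 = detector_radius * detector_radius;

  std::vector<double> hist(n_channels, 0.0);
  double n_detected = 0.0, n_transmitted = 0.0, n_reflected = 0.0;
  double n_absorbed = 0.0, n_lost = 0.0, n_overflow = 0.0;

  const std::uint64_t seed_u = static_cast<std::uint64_t>(seed);
  const long long n_ph = static_cast<long long>(n_photons);

  for (long long i = 0; i < n_ph; ++i) {
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    // counter-based per-photon stream: hash (seed, photon index) to a
    // pseudo-random orbit position so photon streams never overlap the
    // regularly spaced splitmix64 increments of their neighbours
    std::uint64_t st = mix64(mix64(seed_u + 0x9E3779B97F4A7C15ULL) ^
                             (static_cast<std::uint64_t>(i) + 0xBF58476D1CE4E5B9ULL));

    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double path = 0.0;
    bool alive = true;

    while (alive) {
      double step = -std::log(1.0 - rng_u01(st)) * inv_mu_t;

      // propagate, handling (possibly repeated) boundary hits within the step
      while (step > 0.0) {
        double dist_b = 1e300;
        int face = 0; // +1 far face (z = s), -1 near face (z = 0)
        if (uz > 0.0) {
          dist_b = (thickness - z) / uz;
          face = 1;
        } else if (uz < 0.0) {
          dist_b = -z / uz;
          face = -1;
        }
        if (dist_b > step) { // no boundary within this step
          x += ux * step; y += uy * step; z += uz * step;
          path += step;
          step = 0.0;
          break;
        }
        // move to the boundary
        x += ux * dist_b; y += uy * dist_b;
        z = (face == 1) ? thickness : 0.0;
        path += dist_b;
        step -= dist_b;
        if (path > max_path) break; // cutoff handled below

        double R = fresnel_R(std::fabs(uz), n_medium, n_external);
        if (rng_u01(st) < R) {
          uz = -uz; // internal reflection, continue remaining sub-step
        } else {
          // photon escapes
          if (face == 1) {
            n_transmitted += 1.0;
            double t = path / v; // ps since injection
            if (x * x + y * y <= det_r2) {
              n_detected += 1.0;
              int idx = static_cast<int>(std::floor((t - t0) / dt));
              if (idx >= 0 && idx < n_channels) hist[idx] += 1.0;
              else n_overflow += 1.0;
            }
          } else {
            n_reflected += 1.0;
          }
          alive = false;
          break;
        }
      }
      if (!alive) break;
      if (path > max_path) { n_lost += 1.0; break; }

      // interaction: absorption (analog mode) or scattering
      if (p_absorb > 0.0 && rng_u01(st) < p_absorb) {
        n_absorbed += 1.0;
        break;
      }
      if (henyey_greenstein && g != 0.0) {
        // Henyey-Greenstein polar angle, uniform azimuth, rotate direction
        double u = rng_u01(st);
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
        double cos_t = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (cos_t > 1.0) cos_t = 1.0;
        if (cos_t < -1.0) cos_t = -1.0;
        double sin_t = std::sqrt(1.0 - cos_t * cos_t);
        double phi = 2.0 * M_PI * rng_u01(st);
        double cos_p = std::cos(phi), sin_p = std::sin(phi);
        if (std::fabs(uz) > 0.99999) {
          ux = sin_t * cos_p;
          uy = sin_t * sin_p;
          uz = (uz >= 0.0) ? cos_t : -cos_t;
        } else {
          double denom = std::sqrt(1.0 - uz * uz);
          double nx = sin_t * (ux * uz * cos_p - uy * sin_p) / denom + ux * cos_t;
          double ny = sin_t * (uy * uz * cos_p + ux * sin_p) / denom + uy * cos_t;
          double nz = -sin_t * cos_p * denom + uz * cos_t;
          ux = nx; uy = ny; uz = nz;
        }
      } else {
        // isotropic scattering (reduced / similarity description);
        // trigonometry-free uniform sampling on the sphere (Marsaglia 1972)
        double a, b, s2;
        do {
          a = 2.0 * rng_u01(st) - 1.0;
          b = 2.0 * rng_u01(st) - 1.0;
          s2 = a * a + b * b;
        } while (s2 >= 1.0);
        double f = 2.0 * std::sqrt(1.0 - s2);
        ux = a * f;
        uy = b * f;
        uz = 1.0 - 2.0 * s2;
      }
    }
  }

  return List::create(
    _["counts"] = NumericVector(hist.begin(), hist.end()),
    _["n_detected"] = n_detected,
    _["n_transmitted"] = n_transmitted,
    _["n_reflected"] = n_reflected,
    _["n_absorbed"] = n_absorbed,
    _["n_lost_cutoff"] = n_lost,
    _["n_detected_overflow"] = n_overflow);
}
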