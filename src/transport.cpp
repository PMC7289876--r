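// Simplified helical-CT photon transport over a voxel grid.
//
// Physics: photoelectric absorption + incoherent (Klein-Nishina) scatter,
// kerma approximation (energy transferred to electrons is deposited at the
// interaction site). Woodcock (delta) tracking through the voxelized
// attenuation map. Point source on a helix with a rectangular field aimed at
// the rotation axis. Per-history counter-based RNG so results are bitwise
// reproducible for a given seed and independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double u() {  // uniform in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// log-log interpolation on a fixed energy grid (clamped at the ends)
double grid_interp(const std::vector<double>& loge,
                   const std::vector<double>& logy, double e) {
  double le = std::log(e);
  size_t n = loge.size();
  if (le <= loge[0]) return std::exp(logy[0]);
  if (le >= loge[n - 1]) return std::exp(logy[n - 1]);
  size_t i = 1;
  while (loge[i] < le) ++i;
  double t = (le - loge[i - 1]) / (loge[i] - loge[i - 1]);
  return std::exp(logy[i - 1] + t * (logy[i] - logy[i - 1]));
}

const double ELECTRON_REST_KEV = 510.99895;
const double RE2_2PI = 2.0 * M_PI * 2.8179403262e-13 * 2.8179403262e-13;
const double NE_WATER_PER_CM3 = 3.3428e23;  // electrons/cm^3 at density 1

double kn_sigma(double e_kev) {  // cm^2 per electron
  double a = e_kev / ELECTRON_REST_KEV;
  return RE2_2PI *
         ((1 + a) / (a * a) * (2 * (1 + a) / (1 + 2 * a) - std::log(1 + 2 * a) / a) +
          std::log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / ((1 + 2 * a) * (1 + 2 * a)));
}

// mean fraction of photon energy transferred to the electron in a Compton
// scatter (midpoint-rule integral of the KN differential cross section)
double kn_transfer_frac(double e_kev) {
  double a = e_kev / ELECTRON_REST_KEV;
  double num = 0, den = 0;
  const int N = 256;
  for (int i = 0; i < N; ++i) {
    double ct = -1.0 + 2.0 * (i + 0.5) / N;
    double r = 1.0 / (1.0 + a * (1.0 - ct));
    double w = r * r * (r + 1.0 / r - (1.0 - ct * ct));
    num += w * (1.0 - r);
    den += w;
  }
  return num / den;
}

// sample Klein-Nishina scattering cosine by rejection
double kn_sample_costheta(double e_kev, SplitMix& rng) {
  double a = e_kev / ELECTRON_REST_KEV;
  for (;;) {
    double ct = 2.0 * rng.u() - 1.0;
    double r = 1.0 / (1.0 + a * (1.0 - ct));
    double w = r * r * (r + 1.0 / r - (1.0 - ct * ct));
    if (rng.u() * 2.0 <= w) return ct;
  }
}

// advance a ray starting outside the box to its entry point; returns false
// if the ray misses the box
bool advance_to_box(double& px, double& py, double& pz, double dx, double dy,
                    double dz, double x0, double x1, double y0, double y1,
                    double z0, double z1) {
  double tmin = 0.0, tmax = 1e300;
  const double p[3] = {px, py, pz}, d[3] = {dx, dy, dz};
  const double lo[3] = {x0, y0, z0}, hi[3] = {x1, y1, z1};
  for (int i = 0; i < 3; ++i) {
    if (std::fabs(d[i]) < 1e-12) {
      if (p[i] < lo[i] || p[i] >= hi[i]) return false;
    } else {
      double t1 = (lo[i] - p[i]) / d[i];
      double t2 = (hi[i] - p[i]) / d[i];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
      if (tmin > tmax) return false;
    }
  }
  double t = tmin + 1e-9;
  px += t * dx; py += t * dy; pz += t * dz;
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".transport_cpp")]]
List transport_cpp(NumericVector hu, IntegerVector dims, NumericVector spacing,
                   NumericVector origin, double src_radius, double z_start,
                   double z_end, double pitch, double collimation,
                   double fan_half_width, NumericVector energies,
                   NumericVector energy_weights, double n_histories,
                   int n_batches, bool photoelectric, bool compton,
                   bool follow_scatter, double cutoff_kev, double score_boost,
                   double rng_seed,
                   NumericVector atten_e, NumericVector atten_mu_water,
                   NumericVector atten_cbone) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // grid bounding box (voxel edges) in world mm
  const double x0 = origin[0] - 0.5 * sx, y0 = origin[1] - 0.5 * sy,
               z0 = origin[2] - 0.5 * sz;
  const double x1 = x0 + nx * sx, y1 = y0 + ny * sy, z1g = z0 + nz * sz;

  // attenuation model per voxel: mu_tot(E) = mu_water(E) * (f0 + f1*cbone(E))
  std::vector<double> f0(nvox), f1(nvox), rho(nvox);
  double f0max = 0, f1max = 0;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    double h = hu[v];
    if (h <= 100.0) {
      f0[v] = 1.0 + h / 1000.0;
      f1[v] = 0.0;
      rho[v] = std::max(0.0012, 1.0 + h / 1000.0);
    } else {
      f0[v] = 1.1;
      f1[v] = (h - 100.0) / 1000.0;
      rho[v] = 1.1 + (h - 100.0) * (1.92 - 1.1) / 1300.0;
    }
    if (f0[v] > f0max) f0max = f0[v];
    if (f1[v] > f1max) f1max = f1[v];
  }

  std::vector<double> loge(atten_e.size()), logmw(atten_e.size());
  for (int i = 0; i < atten_e.size(); ++i) {
    loge[i] = std::log(atten_e[i]);
    logmw[i] = std::log(atten_mu_water[i]);
  }
  std::vector<double> logcb(atten_cbone.size());
  for (int i = 0; i < atten_cbone.size(); ++i) logcb[i] = std::log(atten_cbone[i]);

  // cumulative spectrum weights
  int nE = energies.size();
  std::vector<double> cumw(nE);
  double wsum = 0;
  for (int i = 0; i < nE; ++i) { wsum += energy_weights[i]; cumw[i] = wsum; }
  for (int i = 0; i < nE; ++i) cumw[i] /= wsum;

  const R_xlen_t nhist = static_cast<R_xlen_t>(n_histories);
  NumericMatrix edep_batch(nvox, n_batches);
  double* eb = REAL(edep_batch);
  double emitted = 0.0, deposited = 0.0;
  const double zspan = z_end - z_start;

  for (R_xlen_t h = 0; h < nhist; ++h) {
    int batch = static_cast<int>((static_cast<double>(h) * n_batches) / nhist);
    double* edep = eb + static_cast<R_xlen_t>(batch) * nvox;
    SplitMix rng(static_cast<uint64_t>(rng_seed) * 0x9E3779B97f4A7C15ULL +
                 static_cast<uint64_t>(h) + 1ULL);
    rng.next();  // decorrelate nearby seeds

    // source position on the helix
    double t = rng.u();
    double zs = z_start + zspan * t;
    double nrot = zspan / (pitch * collimation);
    double theta = 2.0 * M_PI * nrot * t;
    double cth = std::cos(theta), sth = std::sin(theta);
    double px = src_radius * cth, py = src_radius * sth, pz = zs;

    // aim at a point on the collimated rectangle through the axis
    double u = (2.0 * rng.u() - 1.0) * fan_half_width;
    double v = (2.0 * rng.u() - 1.0) * 0.5 * collimation;
    double tx = -u * sth - px, ty = u * cth - py, tz = zs + v - pz;
    double norm = std::sqrt(tx * tx + ty * ty + tz * tz);
    double dx = tx / norm, dy = ty / norm, dz = tz / norm;

    // sample photon energy
    double E;
    if (nE == 1) {
      E = energies[0];
    } else {
      double uE = rng.u();
      int i = 0;
      while (cumw[i] < uE && i < nE - 1) ++i;
      E = energies[i];
    }
    emitted += E;

    // fly from the source to the scored grid
    if (px < x0 || px >= x1 || py < y0 || py >= y1 || pz < z0 || pz >= z1g) {
      if (!advance_to_box(px, py, pz, dx, dy, dz, x0, x1, y0, y1, z0, z1g)) {
        continue;  // missed the grid entirely
      }
    }

    bool alive = true;
    while (alive) {
      double muw = grid_interp(loge, logmw, E) / 10.0;  // per mm
      double cb = grid_interp(loge, logcb, E);
      // Woodcock majorant, inflated by score_boost: extra virtual collisions
      // serve as scoring points for the expected-value (collision kerma)
      // dose estimator without changing the transported physics
      double mumax = muw * (f0max + f1max * cb) * score_boost;
      if (mumax <= 0.0) break;  // fully transparent grid (e.g. pure air)
      double sig_kn_vox = kn_sigma(E) * NE_WATER_PER_CM3 / 10.0;  // per mm per unit rho
      double ftr = kn_transfer_frac(E);

      for (;;) {
        double s = -std::log(rng.u()) / mumax;
        px += s * dx; py += s * dy; pz += s * dz;
        if (px < x0 || px >= x1 || py < y0 || py >= y1 || pz < z0 || pz >= z1g) {
          alive = false;  // escaped the scored volume
          break;
        }
        int ix = static_cast<int>((px - x0) / sx);
        int iy = static_cast<int>((py - y0) / sy);
        int iz = static_cast<int>((pz - z0) / sz);
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
          alive = false;
          break;
        }
        R_xlen_t vox = ix + static_cast<R_xlen_t>(nx) * (iy + static_cast<R_xlen_t>(ny) * iz);
        double mu = muw * (f0[vox] + f1[vox] * cb);

        // expected-value dose scoring at every (virtual or real) collision:
        // the score E * mu_tr / mu_majorant has expectation equal to the
        // track-length integral of the energy-transfer coefficient
        double mu_kn = compton ? std::min(mu, sig_kn_vox * rho[vox]) : 0.0;
        double mu_kn_eff, tau_eff;
        if (compton && photoelectric) {
          mu_kn_eff = mu_kn; tau_eff = mu - mu_kn;
        } else if (compton) {
          mu_kn_eff = mu; tau_eff = 0.0;
        } else {
          mu_kn_eff = 0.0; tau_eff = photoelectric ? mu : 0.0;
        }
        edep[vox] += E * (tau_eff + mu_kn_eff * ftr) / mumax;

        if (rng.u() * mumax > mu) continue;  // virtual collision

        // real collision: split photoelectric vs Compton
        double p_compton = (mu > 0) ? mu_kn / mu : 0.0;
        if (!photoelectric && compton) p_compton = 1.0;
        if (rng.u() < p_compton) {
          double ct = kn_sample_costheta(E, rng);
          double a = E / ELECTRON_REST_KEV;
          double Eprime = E / (1.0 + a * (1.0 - ct));
          double transfer = E - Eprime;
          deposited += transfer;
          if (!follow_scatter) { alive = false; break; }
          if (Eprime < cutoff_kev) {
            deposited += Eprime;
            alive = false;
            break;
          }
          // rotate direction by (theta_s, uniform phi)
          double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
          double phi = 2.0 * M_PI * rng.u();
          double ax, ay, az;  // build orthonormal frame around (dx,dy,dz)
          if (std::fabs(dz) < 0.99) { ax = -dy; ay = dx; az = 0; }
          else { ax = 0; ay = -dz; az = dy; }
          double an = std::sqrt(ax * ax + ay * ay + az * az);
          ax /= an; ay /= an; az /= an;
          double bx = dy * az - dz * ay, by = dz * ax - dx * az, bz = dx * ay - dy * ax;
          double ndx = ct * dx + st * (std::cos(phi) * ax + std::sin(phi) * bx);
          double ndy = ct * dy + st * (std::cos(phi) * ay + std::sin(phi) * by);
          double ndz = ct * dz + st * (std::cos(phi) * az + std::sin(phi) * bz);
          double nn = std::sqrt(ndx * ndx + ndy * ndy + ndz * ndz);
          dx = ndx / nn; dy = ndy / nn; dz = ndz / nn;
          E = Eprime;
          break;  // re-enter outer loop with new energy (new mumax)
        } else {
          deposited += E;  // photoelectric: local absorption
          alive = false;
          break;
        }
      }
    }
  }

  return List::create(_["edep_batch"] = edep_batch, _["emitted_kev"] = emitted,
                      _["deposited_kev"] = deposited);
}
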