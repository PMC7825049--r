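// Weighted-photon Monte Carlo transport through a planar multilayer
// (hop-drop-spin with implicit capture, Henyey-Greenstein scattering,
// unpolarized Fresnel boundaries, Russian roulette), MCML-style.
//
// Determinism contract: each packet draws from its own counter-based
// substream seeded from (run seed, packet index), so results are
// bit-identical for a fixed configuration and independent of packet count
// for the packets shared between two runs.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t s) : state(s) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in the open interval (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

inline uint64_t packet_seed(uint64_t base, uint64_t i) {
  SplitMix64 s(base ^ (0xD1B54A32D192ED03ULL * (i + 1)));
  return s.next();
}

// unpolarized Fresnel reflectance; cos_i >= 0
inline double fresnel_R(double n1, double n2, double cos_i) {
  if (n1 == n2) return 0.0;
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n1 / n2 * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t * sin_t));
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// refract through a z-normal interface, preserving the sign of uz
inline void refract_z(double n1, double n2, double &ux, double &uy,
                      double &uz) {
  if (n1 == n2) return;
  double cos_i = std::fabs(uz);
  double sin_t = n1 / n2 * std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t * sin_t));
  double scale = n1 / n2;
  ux *= scale;
  uy *= scale;
  uz = (uz >= 0.0 ? cos_t : -cos_t);
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// Henyey-Greenstein deflection about the current direction
inline void hg_spin(double g, double u1, double u2, double &ux, double &uy,
                    double &uz) {
  double ct;
  if (std::fabs(g) < 1e-6) {
    ct = 2.0 * u1 - 1.0;
  } else {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u1);
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * u2;
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -den * st * cp + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_transport(NumericVector thickness, NumericVector mua,
                       NumericVector mus, NumericVector g, NumericVector nidx,
                       double n_front, double n_back, NumericMatrix entry_xy,
                       double half_angle_rad, int n_photons, double seed,
                       int det_nx, int det_ny, double det_w, double det_h,
                       bool roulette, double w_threshold, double p_survive,
                       int n_paths, int max_events) {
  const int K = thickness.size();
  if (n_photons < 1) stop("n_photons must be >= 1");
  std::vector<double> zb(K + 1, 0.0);
  for (int i = 0; i < K; ++i) {
    if (thickness[i] <= 0.0) stop("engine layers must have thickness > 0");
    zb[i + 1] = zb[i] + thickness[i];
  }
  const double z_back = (K > 0 ? zb[K] : 0.0);
  const int n_entry = entry_xy.nrow();

  double refl = 0.0, trans_in = 0.0, trans_out = 0.0;
  double trans_in_sq = 0.0, trans_total_sq = 0.0;
  std::vector<double> absorbed(std::max(K, 1), 0.0);
  NumericMatrix det(det_nx, det_ny);
  const double hw = det_w / 2.0, hh = det_h / 2.0;

  std::vector<double> path_buf;        // x,y,z triplets
  std::vector<int> path_id, path_len;  // per recorded packet
  const uint64_t base = static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
                        0x243F6A8885A308D3ULL;

  for (int i = 0; i < n_photons; ++i) {
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    SplitMix64 rng(packet_seed(base, static_cast<uint64_t>(i)));
    double x = entry_xy(i % n_entry, 0), y = entry_xy(i % n_entry, 1),
           z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    if (half_angle_rad > 0.0) {
      double ct = 1.0 - rng.unif() * (1.0 - std::cos(half_angle_rad));
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * rng.unif();
      ux = st * std::cos(phi); uy = st * std::sin(phi); uz = ct;
    }
    double w = 1.0;
    const bool rec = (i < n_paths);
    size_t path_start = path_buf.size();
    if (rec) {
      path_buf.push_back(x); path_buf.push_back(y); path_buf.push_back(z);
    }

    if (K == 0) {  // degenerate zero-thickness stack: one interface
      double R = fresnel_R(n_front, n_back, std::fabs(uz));
      if (rng.unif() < R) {
        refl += w;
      } else {
        trans_in += 0.0;  // binned below
        refract_z(n_front, n_back, ux, uy, uz);
        int bx = (int)std::floor((x + hw) / det_w * det_nx);
        int by = (int)std::floor((y + hh) / det_h * det_ny);
        if (bx >= 0 && bx < det_nx && by >= 0 && by < det_ny) {
          det(bx, by) += w; trans_in += w; trans_in_sq += w * w;
        } else {
          trans_out += w;
        }
        trans_total_sq += w * w;
      }
      if (rec) { path_id.push_back(i); path_len.push_back(1); }
      continue;
    }

    // entry interface: ambient -> first layer
    {
      double R = fresnel_R(n_front, nidx[0], std::fabs(uz));
      if (rng.unif() < R) {
        refl += w;
        if (rec) { path_id.push_back(i);
                   path_len.push_back((int)((path_buf.size() - path_start) / 3)); }
        continue;
      }
      refract_z(n_front, nidx[0], ux, uy, uz);
    }

    int layer = 0;
    double s = 0.0;  // remaining dimensionless step
    int events = 0;
    bool done = false;
    while (!done) {
      if (++events > max_events)
        stop("photon packet exceeded max_events (%d); "
             "check for a non-physical configuration", max_events);
      if (!std::isfinite(x + y + z + w + ux + uy + uz))
        stop("non-finite photon state encountered (packet %d)", i);
      double mt = mua[layer] + mus[layer];
      double d_bound;
      if (uz > 0.0)      d_bound = (zb[layer + 1] - z) / uz;
      else if (uz < 0.0) d_bound = (zb[layer] - z) / uz;
      else               d_bound = R_PosInf;

      if (mt <= 0.0) {
        if (!std::isfinite(d_bound))
          stop("packet trapped in a non-interacting layer (uz = 0)");
        x += ux * d_bound; y += uy * d_bound; z += uz * d_bound;
      } else {
        if (s <= 0.0) s = -std::log(rng.unif());
        double d_free = s / mt;
        if (d_free < d_bound) {
          x += ux * d_free; y += uy * d_free; z += uz * d_free;
          s = 0.0;
          absorbed[layer] += w * mua[layer] / mt;
          w *= mus[layer] / mt;
          if (rec) { path_buf.push_back(x); path_buf.push_back(y);
                     path_buf.push_back(z); }
          if (w <= 0.0) { done = true; break; }
          hg_spin(g[layer], rng.unif(), rng.unif(), ux, uy, uz);
          if (roulette && w < w_threshold) {
            if (rng.unif() < p_survive) w /= p_survive;
            else { done = true; break; }
          }
          continue;
        }
        x += ux * d_bound; y += uy * d_bound; z += uz * d_bound;
        s -= d_bound * mt;
        if (s < 0.0) s = 0.0;
      }

      // at a boundary
      if (rec) { path_buf.push_back(x); path_buf.push_back(y);
                 path_buf.push_back(z); }
      bool down = (uz > 0.0);
      double n1 = nidx[layer];
      double n2 = down ? (layer + 1 < K ? nidx[layer + 1] : n_back)
                       : (layer > 0 ? nidx[layer - 1] : n_front);
      double R = fresnel_R(n1, n2, std::fabs(uz));
      if (rng.unif() < R) {
        uz = -uz;  // specular internal reflection
        continue;
      }
      refract_z(n1, n2, ux, uy, uz);
      if (down) {
        if (layer + 1 < K) { layer += 1; continue; }
        // transmitted through the back face
        int bx = (int)std::floor((x + hw) / det_w * det_nx);
        int by = (int)std::floor((y + hh) / det_h * det_ny);
        if (bx >= 0 && bx < det_nx && by >= 0 && by < det_ny) {
          det(bx, by) += w; trans_in += w; trans_in_sq += w * w;
        } else {
          trans_out += w;
        }
        trans_total_sq += w * w;
        done = true;
      } else {
        if (layer > 0) { layer -= 1; continue; }
        refl += w;  // escaped through the front face
        done = true;
      }
    }
    if (rec) { path_id.push_back(i);
               path_len.push_back((int)((path_buf.size() - path_start) / 3)); }
  }
  (void)z_back;

  return List::create(
      _["reflected"] = refl,
      _["absorbed"] = NumericVector(absorbed.begin(),
                                    absorbed.begin() + std::max(K, 1)),
      _["transmitted_in"] = trans_in,
      _["transmitted_out"] = trans_out,
      _["transmitted_in_sq"] = trans_in_sq,
      _["transmitted_total_sq"] = trans_total_sq,
      _["detector"] = det,
      _["path_xyz"] = NumericVector(path_buf.begin(), path_buf.end()),
      _["path_id"] = IntegerVector(path_id.begin(), path_id.end()),
      _["path_len"] = IntegerVector(path_len.begin(), path_len.end()));
}
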