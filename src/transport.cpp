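// Photon-packet Monte Carlo transport in a layered slab.
//
// Geometry: z increases downward from the illuminated (conjunctival)
// surface; layers are half-open intervals [z_top, z_bottom); lateral extent
// is unbounded. A pencil beam enters at normal incidence; specular loss at
// the ambient/first-layer interface is deducted once. The walk alternates
// hop (exponential step against mu_t), boundary handling (partial step to
// the interface, Fresnel decision, layer change or exit, leftover optical
// path rescaled by the mu_t ratio), drop (weight split exactly between the
// layer absorption bin and the surviving packet) and spin
// (Henyey-Greenstein deflection, uniform azimuth).
//
// RNG: xoshiro256++ seeded through splitmix64 from (seed, stream, photon
// index), so every photon has its own reproducible stream independent of
// execution order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <numeric>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t root, uint64_t stream, uint64_t photon) {
    uint64_t x = root * 0x9E3779B97F4A7C15ULL ^ (stream + 0x632BE59BD9B4E019ULL);
    x ^= splitmix(x) + photon * 0xD1B54A32D192ED03ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform on (0, 1]
  double open01() { return ((next() >> 11) + 1) * 0x1.0p-53; }
  // uniform on [0, 1)
  double co01() { return (next() >> 11) * 0x1.0p-53; }
};

inline double fresnel_unpolarized(double n1, double n2, double cosi,
                                  double *cost_out) {
  if (cosi > 1.0) cosi = 1.0;
  if (n1 == n2) { *cost_out = cosi; return 0.0; }
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n1 / n2 * sini;
  if (sint >= 1.0) { *cost_out = 0.0; return 1.0; }  // total internal reflection
  double cost = std::sqrt(std::max(0.0, 1.0 - sint * sint));
  *cost_out = cost;
  if (cosi < 1e-12) return 1.0;  // grazing
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

inline double hg_cos(double g, double xi) {
  if (std::fabs(g) < 1e-12) return 2.0 * xi - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

inline void spin(double *ux, double *uy, double *uz, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double x = *ux, y = *uy, z = *uz;
  if (std::fabs(z) > 0.99999) {
    *ux = st * cp;
    *uy = st * sp;
    *uz = ct * (z >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - z * z);
    *ux = st * (x * z * cp - y * sp) / den + x * ct;
    *uy = st * (y * z * cp + x * sp) / den + y * ct;
    *uz = -den * st * cp + z * ct;
  }
  // renormalize to absorb rounding drift
  double nrm = std::sqrt(*ux * *ux + *uy * *uy + *uz * *uz);
  *ux /= nrm; *uy /= nrm; *uz /= nrm;
}

}  // namespace

// [[Rcpp::export(name = ".mc_run")]]
List mc_run(NumericVector mua, NumericVector mus, NumericVector g,
            NumericVector n, NumericVector thickness,
            double n_above, double n_below,
            int n_photons, double seed, double stream,
            double w_th, int roulette_m, int hard_mode,
            double max_events, bool per_photon) {
  const int L = mua.size();
  std::vector<double> ztop(L), zbot(L);
  double z0 = 0.0;
  for (int i = 0; i < L; ++i) { ztop[i] = z0; zbot[i] = z0 + thickness[i]; z0 = zbot[i]; }

  double R_spec = 0.0, R_diff = 0.0, T_tot = 0.0, roul_net = 0.0, leak = 0.0;
  std::vector<double> A(L, 0.0);
  double max_resid = 0.0;
  bool cap_hit = false;

  NumericMatrix pp(per_photon ? n_photons : 0, per_photon ? (5 + L) : 0);

  Xoshiro rng;
  const uint64_t useed = (uint64_t)(int64_t)seed;
  const uint64_t ustream = (uint64_t)(int64_t)stream;

  for (int ph = 0; ph < n_photons; ++ph) {
    rng.seed(useed, ustream, (uint64_t)ph);

    // per-photon bins (for the exact ledger identity)
    double p_spec = 0.0, p_rd = 0.0, p_t = 0.0, p_roul = 0.0, p_leak = 0.0;
    double exit_phi = NA_REAL;
    std::vector<double> p_a(L, 0.0);

    // launch
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    int lay = 0;
    {
      double ct;
      double rsp = fresnel_unpolarized(n_above, n[0], 1.0, &ct);
      p_spec = rsp;
      w = 1.0 - rsp;
    }

    double events = 0.0;
    bool alive = true;
    double s_left = 0.0;  // dimensionless leftover optical path (in units of mfp)

    while (alive) {
      if (++events > max_events)
        stop("photon exceeded the configured event cap (runaway photon)");
      double mt = mua[lay] + mus[lay];
      double s;  // geometric step in current layer
      if (s_left > 0.0) {
        s = (mt > 0.0) ? s_left / mt : R_PosInf;
        s_left = 0.0;
      } else {
        double xi = rng.open01();
        s = (mt > 0.0) ? -std::log(xi) / mt : R_PosInf;
      }

      // distance to layer boundary along the flight direction
      double db = R_PosInf;
      int bnd = 0;  // -1 top, +1 bottom
      if (uz > 1e-12) { db = (zbot[lay] - z) / uz; bnd = 1; }
      else if (uz < -1e-12) { db = (ztop[lay] - z) / uz; bnd = -1; }

      if (db <= s) {
        // move to boundary, bank leftover optical path
        x += ux * db; y += uy * db; z += uz * db;
        if (mt > 0.0 && std::isfinite(s)) s_left = (s - db) * mt;
        double n1 = n[lay];
        double n2 = (bnd == 1) ? (lay == L - 1 ? n_below : n[lay + 1])
                               : (lay == 0 ? n_above : n[lay - 1]);
        double cosi = std::fabs(uz), cost;
        double R = fresnel_unpolarized(n1, n2, cosi, &cost);
        if (rng.co01() < R) {
          uz = -uz;  // internal reflection
          z = (bnd == 1) ? zbot[lay] : ztop[lay];
        } else {
          // refract
          double scale = n1 / n2;
          ux *= scale; uy *= scale;
          uz = (uz >= 0 ? cost : -cost);
          double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= nrm; uy /= nrm; uz /= nrm;
          if (bnd == 1) {
            if (lay == L - 1) { p_t += w; alive = false; }
            else { ++lay; z = ztop[lay]; }
          } else {
            if (lay == 0) {
              p_rd += w;
              exit_phi = std::atan2(uy, ux);
              alive = false;
            } else { --lay; z = zbot[lay]; }
          }
        }
        continue;
      }

      if (!std::isfinite(s)) {
        // vacuum layer, moving parallel to boundaries: photon is lost to the
        // lateral infinity; book as leak (cannot happen with physical stacks)
        p_leak += w; alive = false; continue;
      }

      // hop
      x += ux * s; y += uy * s; z += uz * s;

      // drop: exact split of w into absorbed + surviving
      if (mt > 0.0) {
        double w_new = w * (mus[lay] / mt);
        p_a[lay] += w - w_new;
        w = w_new;
      }

      // spin
      double ct = hg_cos(g[lay], rng.co01());
      double phi = 2.0 * M_PI * rng.co01();
      spin(&ux, &uy, &uz, ct, phi);

      // termination
      if (w < w_th) {
        if (hard_mode) { p_leak += w; alive = false; }
        else {
          if (rng.co01() < 1.0 / roulette_m) {
            double w_new = roulette_m * w;
            p_roul -= (w_new - w);  // boost borrowed from the roulette bin
            w = w_new;
          } else {
            p_roul += w;  // killed weight banked
            alive = false;
          }
        }
      }
    }

    double resid = std::fabs(p_spec + p_rd + p_t + p_roul + p_leak +
                             std::accumulate(p_a.begin(), p_a.end(), 0.0) - 1.0);
    if (resid > max_resid) max_resid = resid;

    R_spec += p_spec; R_diff += p_rd; T_tot += p_t;
    roul_net += p_roul; leak += p_leak;
    for (int i = 0; i < L; ++i) A[i] += p_a[i];

    if (per_photon) {
      pp(ph, 0) = p_spec; pp(ph, 1) = p_rd; pp(ph, 2) = p_t; pp(ph, 3) = p_roul + p_leak;
      for (int i = 0; i < L; ++i) pp(ph, 4 + i) = p_a[i];
      pp(ph, 4 + L) = exit_phi;
    }
  }

  double N = (double)n_photons;
  List out = List::create(
    _["R_specular"] = R_spec / N,
    _["R_diffuse"] = R_diff / N,
    _["T"] = T_tot / N,
    _["A_per_layer"] = NumericVector(A.begin(), A.end()) / N,
    _["roulette_net"] = roul_net / N,
    _["leak"] = leak / N,
    _["max_photon_residual"] = max_resid,
    _["n_photons"] = n_photons);
  if (per_photon) out["per_photon"] = pp;
  return out;
}

// [[Rcpp::export(name = ".cpp_fresnel")]]
NumericVector cpp_fresnel(double n1, double n2, double cos_incident) {
  double cost;
  double R = fresnel_unpolarized(n1, n2, cos_incident, &cost);
  return NumericVector::create(R, cost);
}

// [[Rcpp::export(name = ".cpp_hg_cos")]]
double cpp_hg_cos(double g, double xi) { return hg_cos(g, xi); }

// [[Rcpp::export(name = ".cpp_spin")]]
NumericVector cpp_spin(NumericVector u, double cos_theta, double phi) {
  double ux = u[0], uy = u[1], uz = u[2];
  spin(&ux, &uy, &uz, cos_theta, phi);
  return NumericVector::create(ux, uy, uz);
}
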