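// Voxel Monte Carlo photon transport with Henyey-Greenstein scattering,
// Fresnel reflection/refraction at voxel faces where the refractive index
// changes, weight attenuation by the single-scatter albedo, track-length
// fluence scoring and Russian roulette. Self-contained xoshiro256++ RNG so
// a (seed, stream) pair reproduces a kernel bit-for-bit on any platform.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (0x9E3779B97f4A7C15ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0,1): never exactly 0 or 1
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// Henyey-Greenstein inverse-CDF sample of the scattering-angle cosine.
inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-9) return 2.0 * u - 1.0;
  const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return clamp1((1.0 + g * g - f * f) / (2.0 * g));
}

// Unpolarized Fresnel reflectance for incidence cosine ci (>0), n1 -> n2.
inline double fresnel(double n1, double n2, double ci) {
  if (std::fabs(n1 - n2) < 1e-12) return 0.0;
  const double si2 = 1.0 - ci * ci;
  const double st2 = (n1 / n2) * (n1 / n2) * si2;
  if (st2 >= 1.0) return 1.0;  // total internal reflection
  const double ct = std::sqrt(1.0 - st2);
  const double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  const double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Rotate direction (ux,uy,uz) by polar cosine ct and azimuth phi.
inline void spin(double &ux, double &uy, double &uz, double ct, double phi) {
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  const double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.999999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz > 0 ? 1.0 : -1.0) * ct;
  } else {
    const double d = std::sqrt(1.0 - uz * uz);
    const double nx = st * (ux * uz * cp - uy * sp) / d + ux * ct;
    const double ny = st * (uy * uz * cp + ux * sp) / d + uy * ct;
    const double nz = -d * st * cp + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  const double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

struct SourceSpec {
  int kind;  // 0 = isotropic point, 1 = cut-end fibre, 2 = cylindrical diffuser
  double px, py, pz;        // point/tip position or endpoint a
  double ax, ay, az;        // axis (cut-end) or endpoint b (diffuser)
  double radius;            // core or diffuser radius
  double cos_max;           // cone half-angle cosine (cut-end)
};

SourceSpec parse_source(const List &src) {
  SourceSpec s;
  s.kind = as<int>(src["kind"]);
  NumericVector p = src["position"];
  s.px = p[0]; s.py = p[1]; s.pz = p[2];
  s.ax = s.ay = s.az = 0.0;
  s.radius = 0.0;
  s.cos_max = 1.0;
  if (s.kind == 1) {
    NumericVector a = src["axis"];
    double nrm = std::sqrt(a[0]*a[0] + a[1]*a[1] + a[2]*a[2]);
    s.ax = a[0]/nrm; s.ay = a[1]/nrm; s.az = a[2]/nrm;
    s.radius = as<double>(src["radius"]);
    s.cos_max = as<double>(src["cos_max"]);
  } else if (s.kind == 2) {
    NumericVector b = src["endpoint_b"];
    s.ax = b[0]; s.ay = b[1]; s.az = b[2];
    s.radius = as<double>(src["radius"]);
  }
  return s;
}

// Build an orthonormal frame (e1, e2) perpendicular to unit vector w.
inline void frame(double wx, double wy, double wz,
                  double &e1x, double &e1y, double &e1z,
                  double &e2x, double &e2y, double &e2z) {
  if (std::fabs(wx) < 0.9) { e1x = 0.0; e1y = -wz; e1z = wy; }
  else                     { e1x = -wz; e1y = 0.0; e1z = wx; }
  double nrm = std::sqrt(e1x*e1x + e1y*e1y + e1z*e1z);
  e1x /= nrm; e1y /= nrm; e1z /= nrm;
  e2x = wy * e1z - wz * e1y;
  e2y = wz * e1x - wx * e1z;
  e2z = wx * e1y - wy * e1x;
}

// Draw one emission sample (position + direction) from a source.
inline void emit(const SourceSpec &s, Xoshiro &rng,
                 double &x, double &y, double &z,
                 double &ux, double &uy, double &uz) {
  const double TWOPI = 6.283185307179586;
  if (s.kind == 0) {  // isotropic point
    x = s.px; y = s.py; z = s.pz;
    uz = 2.0 * rng.unif() - 1.0;
    const double st = std::sqrt(std::max(0.0, 1.0 - uz * uz));
    const double phi = TWOPI * rng.unif();
    ux = st * std::cos(phi); uy = st * std::sin(phi);
  } else if (s.kind == 1) {  // cut-end fibre
    double e1x, e1y, e1z, e2x, e2y, e2z;
    frame(s.ax, s.ay, s.az, e1x, e1y, e1z, e2x, e2y, e2z);
    const double r = s.radius * std::sqrt(rng.unif());
    const double psi = TWOPI * rng.unif();
    x = s.px + r * (std::cos(psi) * e1x + std::sin(psi) * e2x);
    y = s.py + r * (std::cos(psi) * e1y + std::sin(psi) * e2y);
    z = s.pz + r * (std::cos(psi) * e1z + std::sin(psi) * e2z);
    // uniform in solid angle within the acceptance cone
    const double ct = 1.0 - rng.unif() * (1.0 - s.cos_max);
    const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    const double phi = TWOPI * rng.unif();
    ux = ct * s.ax + st * (std::cos(phi) * e1x + std::sin(phi) * e2x);
    uy = ct * s.ay + st * (std::cos(phi) * e1y + std::sin(phi) * e2y);
    uz = ct * s.az + st * (std::cos(phi) * e1z + std::sin(phi) * e2z);
  } else {  // cylindrical diffuser: uniform along axis, Lambertian radial
    double tx = s.ax - s.px, ty = s.ay - s.py, tz = s.az - s.pz;
    const double len = std::sqrt(tx*tx + ty*ty + tz*tz);
    tx /= len; ty /= len; tz /= len;
    double e1x, e1y, e1z, e2x, e2y, e2z;
    frame(tx, ty, tz, e1x, e1y, e1z, e2x, e2y, e2z);
    const double t = rng.unif() * len;
    const double psi = TWOPI * rng.unif();
    const double nxr = std::cos(psi) * e1x + std::sin(psi) * e2x;
    const double nyr = std::cos(psi) * e1y + std::sin(psi) * e2y;
    const double nzr = std::cos(psi) * e1z + std::sin(psi) * e2z;
    x = s.px + t * tx + s.radius * nxr;
    y = s.py + t * ty + s.radius * nyr;
    z = s.pz + t * tz + s.radius * nzr;
    // cosine-weighted about the outward radial normal
    const double ct = std::sqrt(rng.unif());
    const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    const double phi = TWOPI * rng.unif();
    const double wx = ty * nzr - tz * nyr;
    const double wy = tz * nxr - tx * nzr;
    const double wz = tx * nyr - ty * nxr;
    ux = ct * nxr + st * (std::cos(phi) * tx + std::sin(phi) * wx);
    uy = ct * nyr + st * (std::cos(phi) * ty + std::sin(phi) * wy);
    uz = ct * nzr + st * (std::cos(phi) * tz + std::sin(phi) * wz);
  }
}

}  // namespace

// [[Rcpp::export(name = ".hg_sample_cpp")]]
NumericVector hg_sample_cpp(double g, NumericVector u) {
  const int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g, u[i]);
  return out;
}

// [[Rcpp::export(name = ".fresnel_cpp")]]
NumericVector fresnel_cpp(double n1, double n2, NumericVector cos_i) {
  const int n = cos_i.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fresnel(n1, n2, cos_i[i]);
  return out;
}

// [[Rcpp::export(name = ".sample_emission_cpp")]]
List sample_emission_cpp(List source, int n, int seed, int stream) {
  SourceSpec s = parse_source(source);
  Xoshiro rng;
  rng.seed((uint64_t)seed, (uint64_t)stream);
  NumericMatrix pos(n, 3), dir(n, 3);
  double x, y, z, ux, uy, uz;
  for (int i = 0; i < n; ++i) {
    emit(s, rng, x, y, z, ux, uy, uz);
    pos(i, 0) = x; pos(i, 1) = y; pos(i, 2) = z;
    dir(i, 0) = ux; dir(i, 1) = uy; dir(i, 2) = uz;
  }
  return List::create(_["positions"] = pos, _["directions"] = dir,
                      _["weights"] = NumericVector(n, 1.0));
}

// [[Rcpp::export(name = ".mc_kernel_cpp")]]
List mc_kernel_cpp(IntegerVector labels, IntegerVector dims,
                   NumericVector spacing, NumericVector origin,
                   NumericMatrix optics,  // rows: label code; cols mu_a, mu_s, g, n
                   List source, int n_packets, int seed, int stream,
                   double w_min, double p_survive, int n_batches,
                   int max_events) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double voxvol = sx * sy * sz;
  const int nlab = optics.nrow();
  const int *lab = INTEGER(labels);

  std::vector<double> mua(nlab), mus(nlab), gg(nlab), nn(nlab), mut(nlab);
  for (int l = 0; l < nlab; ++l) {
    mua[l] = optics(l, 0); mus[l] = optics(l, 1);
    gg[l] = optics(l, 2); nn[l] = optics(l, 3);
    mut[l] = mua[l] + mus[l];
  }

  SourceSpec src = parse_source(source);
  Xoshiro rng;
  rng.seed((uint64_t)seed, (uint64_t)stream);

  std::vector<double> batch(nvox, 0.0), ksum(nvox, 0.0), ksumsq(nvox, 0.0);
  double absorbed = 0.0, escaped = 0.0, roulette_net = 0.0;
  const double TWOPI = 6.283185307179586;
  if (n_batches < 1) n_batches = 1;
  const int per_batch = (n_packets + n_batches - 1) / n_batches;
  int done_batches = 0, in_batch = 0;
  const double inv_pb = 1.0;

  auto fold_batch = [&](int npk) {
    if (npk == 0) return;
    for (R_xlen_t v = 0; v < nvox; ++v) {
      const double m = batch[v] / ((double)npk * voxvol);
      ksum[v] += m; ksumsq[v] += m * m;
      batch[v] = 0.0;
    }
    ++done_batches;
  };

  for (int p = 0; p < n_packets; ++p) {
    double x, y, z, ux, uy, uz;
    emit(src, rng, x, y, z, ux, uy, uz);
    int ix = (int)std::floor((x - ox) / sx);
    int iy = (int)std::floor((y - oy) / sy);
    int iz = (int)std::floor((z - oz) / sz);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
      Rcpp::stop("emission sample outside the voxel grid");
    int cur = lab[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
    if (cur <= 0) Rcpp::stop("emission sample in a non-tissue voxel");

    double w = 1.0;
    bool alive = true;
    int events = 0;
    while (alive) {
      double tau = -std::log(rng.unif());
      // propagate until the sampled optical depth is consumed
      while (tau > 0.0 && alive) {
        const R_xlen_t vidx =
          (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        const int l = lab[vidx];
        const double mt = mut[l];
        // distances to the three candidate voxel faces
        double dbx = (ux > 0) ? ((ox + (ix + 1) * sx) - x) / ux
                   : (ux < 0) ? ((ox + ix * sx) - x) / ux : 1e30;
        double dby = (uy > 0) ? ((oy + (iy + 1) * sy) - y) / uy
                   : (uy < 0) ? ((oy + iy * sy) - y) / uy : 1e30;
        double dbz = (uz > 0) ? ((oz + (iz + 1) * sz) - z) / uz
                   : (uz < 0) ? ((oz + iz * sz) - z) / uz : 1e30;
        if (dbx < 0) dbx = 0; if (dby < 0) dby = 0; if (dbz < 0) dbz = 0;
        int axis = 0; double db = dbx;
        if (dby < db) { db = dby; axis = 1; }
        if (dbz < db) { db = dbz; axis = 2; }
        const double dint = (mt > 0) ? tau / mt : 1e30;
        if (dint < db) {
          // interaction inside this voxel
          x += ux * dint; y += uy * dint; z += uz * dint;
          batch[vidx] += w * dint;
          tau = 0.0;
          absorbed += w * (mua[l] / mt);
          w *= mus[l] / mt;
          const double ct = hg_cos(gg[l], rng.unif());
          spin(ux, uy, uz, ct, TWOPI * rng.unif());
          if (w < w_min) {
            if (rng.unif() < p_survive) {
              roulette_net += w * (1.0 / p_survive - 1.0);
              w /= p_survive;
            } else {
              roulette_net -= w;
              alive = false;
            }
          }
          if (++events >= max_events) { escaped += w; alive = false; }
        } else {
          // advance to the voxel face
          x += ux * db; y += uy * db; z += uz * db;
          batch[vidx] += w * db;
          if (mt > 0) tau -= db * mt;
          int jx = ix, jy = iy, jz = iz;
          double nd;  // direction cosine along the face normal
          if (axis == 0) { jx += (ux > 0) ? 1 : -1; nd = ux; }
          else if (axis == 1) { jy += (uy > 0) ? 1 : -1; nd = uy; }
          else { jz += (uz > 0) ? 1 : -1; nd = uz; }
          const bool outside_grid =
            (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz);
          const int lnew = outside_grid ? 0 :
            lab[(R_xlen_t)jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz)];
          const double n1 = nn[l], n2 = nn[lnew];
          bool transmitted = true;
          if (std::fabs(n1 - n2) > 1e-12) {
            const double ci = std::fabs(nd);
            const double R = fresnel(n1, n2, ci);
            if (rng.unif() < R) {
              transmitted = false;
              if (axis == 0) ux = -ux;
              else if (axis == 1) uy = -uy;
              else uz = -uz;
            } else {
              // Snell refraction: scale tangential components
              const double eta = n1 / n2;
              const double ct2 = std::sqrt(std::max(0.0,
                  1.0 - eta * eta * (1.0 - ci * ci)));
              const double sgn = (nd > 0) ? 1.0 : -1.0;
              if (axis == 0) { uy *= eta; uz *= eta; ux = sgn * ct2; }
              else if (axis == 1) { ux *= eta; uz *= eta; uy = sgn * ct2; }
              else { ux *= eta; uy *= eta; uz = sgn * ct2; }
              const double nrm = std::sqrt(ux*ux + uy*uy + uz*uz);
              ux /= nrm; uy /= nrm; uz /= nrm;
            }
          }
          if (transmitted) {
            if (outside_grid || lnew == 0) {
              escaped += w;
              alive = false;
            } else {
              ix = jx; iy = jy; iz = jz;
            }
          }
        }
      }
    }
    if (++in_batch == per_batch) { fold_batch(in_batch); in_batch = 0; }
    if ((p & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  fold_batch(in_batch);

  NumericVector fluence(nvox), rel_se(nvox);
  const int nb = done_batches;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    const double mean = ksum[v] / nb;
    fluence[v] = mean;
    if (nb > 1 && mean > 0) {
      double var = (ksumsq[v] - ksum[v] * ksum[v] / nb) / (nb - 1);
      if (var < 0) var = 0;
      rel_se[v] = std::sqrt(var / nb) / mean;
    } else {
      rel_se[v] = 0.0;
    }
  }
  fluence.attr("dim") = dims;
  rel_se.attr("dim") = dims;
  return List::create(
    _["fluence"] = fluence, _["rel_se"] = rel_se,
    _["absorbed"] = absorbed / n_packets,
    _["escaped"] = escaped / n_packets,
    _["roulette_net"] = roulette_net / n_packets,
    _["launched"] = 1.0, _["n_batches"] = nb);
}
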