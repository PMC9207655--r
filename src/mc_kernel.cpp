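// Voxelized Monte Carlo photon transport for homogeneous turbid media.
//
// Weighted-packet scheme: free path sampled from the scattering coefficient,
// continuous absorption weighting along each sub-voxel segment, Henyey-
// Greenstein deflection at every scattering event, Russian roulette for
// low-weight packets.  Fluence is tallied with the path-length estimator
// (integral of packet weight over the segment, per voxel volume, per
// launched packet).  Voxel walking uses incremental DDA: per-axis distances
// to the next voxel plane are maintained between segments so the hot loop
// carries no divisions or floor operations.  Per-photon RNG substreams are
// derived by counter from the run seed so results never depend on launch
// order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

const double C_MM_PER_NS = 299.792458; // vacuum speed of light
const double BIG = 1e300;

inline std::uint64_t splitmix64(std::uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  std::uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoroshiro128+ seeded per photon: counter-based substreams.
struct PhotonRng {
  std::uint64_t s0, s1;
  void seed(std::uint64_t run_seed, std::uint64_t photon) {
    std::uint64_t x = run_seed ^ (photon * 0x632BE59BD9B4E019ULL + 0xD1B54A32D192ED03ULL);
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if ((s0 | s1) == 0) s1 = 0x9E3779B97F4A7C15ULL;
  }
  inline std::uint64_t next() {
    std::uint64_t a = s0, b = s1, r = a + b;
    b ^= a;
    s0 = ((a << 24) | (a >> 40)) ^ b ^ (b << 16);
    s1 = (b << 37) | (b >> 27);
    return r;
  }
  // uniform on [0, 1)
  inline double unif() { return (double)(next() >> 11) * 1.1102230246251565e-16; }
  // random point on the unit circle without trig (Marsaglia rejection)
  inline void circle(double &c, double &s) {
    double a, b, q;
    do {
      a = 2.0 * unif() - 1.0;
      b = 2.0 * unif() - 1.0;
      q = a * a + b * b;
    } while (q >= 1.0 || q < 1e-12);
    double inv = 1.0 / q;
    c = (a * a - b * b) * inv;
    s = 2.0 * a * b * inv;
  }
};

inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// unpolarized Fresnel reflectance, medium n1 -> n2, incidence cosine ci > 0
inline double fresnel_R(double n1, double n2, double ci) {
  if (n1 == n2) return 0.0;
  double si2 = 1.0 - ci * ci;
  double st2 = (n1 / n2) * (n1 / n2) * si2; // sin^2(theta_t)
  if (st2 >= 1.0) return 1.0;               // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// 1 - exp(-x) with a series branch for small x (dominant case: mua*seg << 1)
inline double one_m_exp(double x) {
  if (x < 1e-4) return x * (1.0 - 0.5 * x * (1.0 - x / 3.0));
  return 1.0 - std::exp(-x);
}

struct Walker {
  double px, py, pz;    // position, mm
  double dx, dy, dz;    // unit direction
  double tx, ty, tz;    // distance along the ray to the next voxel plane
  double ddx, ddy, ddz; // plane-to-plane distance along the ray per axis
  int ix, iy, iz;       // voxel indices (may leave the grid in infinite mode)
  int sx, sy, sz;       // index step per crossing (+1/-1/0)

  // recompute per-axis crossing distances after a direction change
  // (one reciprocal per axis; everything else is multiplies)
  inline void reset_axes(double h) {
    if (dx > 0)      { sx = 1;  double q = 1.0 / dx; tx = ((ix + 1) * h - px) * q; ddx = h * q; }
    else if (dx < 0) { sx = -1; double q = 1.0 / dx; tx = (ix * h - px) * q;       ddx = -h * q; }
    else             { sx = 0;  tx = BIG;                      ddx = BIG; }
    if (dy > 0)      { sy = 1;  double q = 1.0 / dy; ty = ((iy + 1) * h - py) * q; ddy = h * q; }
    else if (dy < 0) { sy = -1; double q = 1.0 / dy; ty = (iy * h - py) * q;       ddy = -h * q; }
    else             { sy = 0;  ty = BIG;                      ddy = BIG; }
    if (dz > 0)      { sz = 1;  double q = 1.0 / dz; tz = ((iz + 1) * h - pz) * q; ddz = h * q; }
    else if (dz < 0) { sz = -1; double q = 1.0 / dz; tz = (iz * h - pz) * q;       ddz = -h * q; }
    else             { sz = 0;  tz = BIG;                      ddz = BIG; }
    if (tx < 0) tx = 0;
    if (ty < 0) ty = 0;
    if (tz < 0) tz = 0;
  }
};

} // namespace

// [[Rcpp::export(name = ".mc_fluence_cpp")]]
List mc_fluence_cpp(IntegerVector dims, double voxel,
                    double mua, double mus, double g, double n_medium,
                    NumericVector src_pos, NumericVector src_dir,
                    std::string src_type,
                    double n_photons, double time_gate_ns,
                    double seed, double roulette_threshold,
                    double roulette_survival, bool bounded) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double h = voxel;
  const double max_path = time_gate_ns * C_MM_PER_NS / n_medium; // mm
  const std::uint64_t N = (std::uint64_t)(n_photons + 0.5);
  const bool pencil = (src_type == "pencil");
  const double inv_mua = (mua > 0.0) ? 1.0 / mua : 0.0;
  const double inv_mus = 1.0 / mus;
  const R_xlen_t kx = 1, ky = nx, kz = (R_xlen_t)nx * ny;

  // single-precision tally: halves memory traffic; per-voxel rounding is
  // far below MC noise at the photon budgets used
  std::vector<float> tal((std::size_t)nx * ny * nz, 0.0f);
  float *F = tal.data();
  double absorbed = 0.0, escaped = 0.0, gated = 0.0;
  double roulette_loss = 0.0, roulette_gain = 0.0;

  PhotonRng rng;

  for (std::uint64_t ph = 0; ph < N; ++ph) {
    if ((ph & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    rng.seed((std::uint64_t)seed, ph);

    Walker wk;
    wk.px = src_pos[0]; wk.py = src_pos[1]; wk.pz = src_pos[2];
    if (pencil) {
      wk.dx = src_dir[0]; wk.dy = src_dir[1]; wk.dz = src_dir[2];
      if (wk.pz <= 0.0) wk.pz = 1e-12; // launch just inside the medium
    } else { // isotropic point source
      double ct = 2.0 * rng.unif() - 1.0;
      double st = std::sqrt(1.0 - ct * ct);
      double cp, sp;
      rng.circle(cp, sp);
      wk.dx = st * cp; wk.dy = st * sp; wk.dz = ct;
    }
    // launch voxel (nudged along the direction to resolve plane positions)
    wk.ix = (int)std::floor((wk.px + 1e-9 * wk.dx) / h);
    wk.iy = (int)std::floor((wk.py + 1e-9 * wk.dy) / h);
    wk.iz = (int)std::floor((wk.pz + 1e-9 * wk.dz) / h);
    wk.reset_axes(h);

    bool inside = wk.ix >= 0 && wk.ix < nx && wk.iy >= 0 && wk.iy < ny &&
                  wk.iz >= 0 && wk.iz < nz;
    R_xlen_t k = inside ?
      (R_xlen_t)wk.ix + ky * wk.iy + kz * wk.iz : 0;

    double w = 1.0, path = 0.0;
    bool alive = true;

    while (alive) {
      // scattering free path; single-precision log is ample for MC sampling
      double s = -(double)logf((float)(1.0 - rng.unif())) * inv_mus;

      while (s > 0.0) {
        // next event along the ray: voxel plane or end of free path
        int axis = 0;
        double seg = wk.tx;
        if (wk.ty < seg) { seg = wk.ty; axis = 1; }
        if (wk.tz < seg) { seg = wk.tz; axis = 2; }
        bool cross = seg <= s;
        if (!cross) { seg = s; axis = -1; }
        bool hit_gate = false;
        if (path + seg >= max_path) {
          seg = max_path - path; hit_gate = true; cross = false; axis = -1;
        }

        // continuous absorption + path-length fluence tally
        double att = one_m_exp(mua * seg);
        double dep = w * att;
        if (inside) F[k] += (float)((mua > 0.0) ? dep * inv_mua : w * seg);
        absorbed += dep;
        w -= dep;
        path += seg;
        wk.px += wk.dx * seg; wk.py += wk.dy * seg; wk.pz += wk.dz * seg;
        wk.tx -= seg; wk.ty -= seg; wk.tz -= seg;
        s -= seg;

        if (hit_gate) { gated += w; alive = false; break; }
        if (!cross) break; // free path exhausted: scatter

        // voxel-plane crossing
        if (axis == 0) {
          wk.ix += wk.sx; wk.tx += wk.ddx;
          if (wk.ix < 0 || wk.ix >= nx) {
            if (bounded) { escaped += w; alive = false; break; }
            inside = false; continue;
          }
          if (inside) { k += (wk.sx > 0) ? kx : -kx; continue; }
        } else if (axis == 1) {
          wk.iy += wk.sy; wk.ty += wk.ddy;
          if (wk.iy < 0 || wk.iy >= ny) {
            if (bounded) { escaped += w; alive = false; break; }
            inside = false; continue;
          }
          if (inside) { k += (wk.sy > 0) ? ky : -ky; continue; }
        } else {
          wk.iz += wk.sz; wk.tz += wk.ddz;
          if (wk.iz < 0) {
            if (bounded) {
              // tissue-air interface at z = 0: Fresnel reflect or escape
              double R = fresnel_R(n_medium, 1.0, -wk.dz);
              if (rng.unif() < R) {
                wk.iz = 0; wk.pz = 0.0;
                wk.dz = -wk.dz;
                wk.sz = 1; wk.ddz = h / wk.dz; wk.tz = wk.ddz;
                continue;
              }
              escaped += w; alive = false; break;
            }
            inside = false; continue;
          }
          if (wk.iz >= nz) {
            if (bounded) { escaped += w; alive = false; break; }
            inside = false; continue;
          }
          if (inside) { k += (wk.sz > 0) ? kz : -kz; continue; }
        }
        // was outside: did we re-enter the grid?
        if (!inside &&
            wk.ix >= 0 && wk.ix < nx && wk.iy >= 0 && wk.iy < ny &&
            wk.iz >= 0 && wk.iz < nz) {
          inside = true;
          k = (R_xlen_t)wk.ix + ky * wk.iy + kz * wk.iz;
        }
      }
      if (!alive) break;

      // scatter (Henyey-Greenstein)
      double ct = hg_cos(g, rng.unif());
      double st = std::sqrt(1.0 - ct * ct);
      double cp, sp;
      rng.circle(cp, sp);
      double dx = wk.dx, dy = wk.dy, dz = wk.dz;
      if (std::fabs(dz) > 0.99999) {
        wk.dx = st * cp; wk.dy = st * sp; wk.dz = ct * (dz > 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - dz * dz);
        double stden = st / den;
        double ndx = stden * (dx * dz * cp - dy * sp) + dx * ct;
        double ndy = stden * (dy * dz * cp + dx * sp) + dy * ct;
        double ndz = -st * cp * den + dz * ct;
        double norm = 1.0 / std::sqrt(ndx * ndx + ndy * ndy + ndz * ndz);
        wk.dx = ndx * norm; wk.dy = ndy * norm; wk.dz = ndz * norm;
      }
      wk.reset_axes(h);

      // Russian roulette
      if (w < roulette_threshold) {
        if (rng.unif() < roulette_survival) {
          roulette_gain += w * (1.0 / roulette_survival - 1.0);
          w /= roulette_survival;
        } else {
          roulette_loss += w;
          alive = false;
        }
      }
    }
  }

  // fluence per launched photon, mm^-2
  NumericVector flu((R_xlen_t)nx * ny * nz);
  double *out = REAL(flu);
  const double norm = 1.0 / (h * h * h * (double)N);
  for (R_xlen_t i = 0; i < flu.size(); ++i) out[i] = (double)F[i] * norm;

  return List::create(
    _["fluence"] = flu,
    _["absorbed_weight"] = absorbed / (double)N,
    _["escaped_weight"] = escaped / (double)N,
    _["gated_weight"] = gated / (double)N,
    _["roulette_loss"] = roulette_loss / (double)N,
    _["roulette_gain"] = roulette_gain / (double)N);
}

// Centered rolling median with symmetrically truncated edge windows:
// out[i] = median(x[i-m .. i+m]), m = min(k/2, i, n-1-i).  Two-multiset
// median maintenance gives O(n log k); window ends move monotonically so
// every element is inserted and erased at most twice.
// [[Rcpp::export(name = ".rolling_median_cpp")]]
NumericVector rolling_median_cpp(NumericVector x, int k) {
  const R_xlen_t n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  const R_xlen_t half = k / 2;
  std::multiset<double> low, high; // max(low) <= min(high); |low| = |high| + 1

  auto rebalance = [&]() {
    while (low.size() > high.size() + 1) {
      auto it = std::prev(low.end());
      high.insert(*it);
      low.erase(it);
    }
    while (low.size() < high.size()) {
      auto it = high.begin();
      low.insert(*it);
      high.erase(it);
    }
  };
  auto add = [&](double v) {
    if (low.empty() || v <= *low.rbegin()) low.insert(v); else high.insert(v);
    rebalance();
  };
  auto rem = [&](double v) {
    auto it = low.find(v);
    if (it != low.end()) low.erase(it);
    else high.erase(high.find(v));
    rebalance();
  };

  R_xlen_t a = 0, b = -1; // current window [a, b]
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t m = std::min(half, std::min(i, n - 1 - i));
    R_xlen_t a1 = i - m, b1 = i + m;
    while (b < b1) add(x[++b]);
    while (a < a1) rem(x[a++]);
    out[i] = *low.rbegin();
  }
  return out;
}

// Rolling MAD-based noise scale (x 1.4826) over a centered window, evaluated
// every `stride` samples and linearly interpolated in between.  Windows are
// truncated at the edges, never wrapped.
// [[Rcpp::export(name = ".rolling_mad_cpp")]]
NumericVector rolling_mad_cpp(NumericVector x, int window, int stride) {
  const R_xlen_t n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  if (stride < 1) stride = 1;
  const int half = window / 2;

  std::vector<double> buf, dev;
  std::vector<R_xlen_t> centers;
  std::vector<double> vals;
  for (R_xlen_t c = 0; c < n; c += stride) centers.push_back(c);
  if (centers.back() != n - 1) centers.push_back(n - 1);

  for (R_xlen_t ci = 0; ci < (R_xlen_t)centers.size(); ++ci) {
    R_xlen_t c = centers[ci];
    R_xlen_t lo = c - half; if (lo < 0) lo = 0;
    R_xlen_t hi = c + half; if (hi > n - 1) hi = n - 1;
    R_xlen_t m = hi - lo + 1;
    // upper median (exact for odd windows; bias negligible at these sizes)
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
    double med = buf[m / 2];
    dev.resize(m);
    for (R_xlen_t i = 0; i < m; ++i) dev[i] = std::fabs(x[lo + i] - med);
    std::nth_element(dev.begin(), dev.begin() + m / 2, dev.end());
    vals.push_back(1.4826 * dev[m / 2]);
  }

  // linear interpolation between evaluation points
  for (R_xlen_t ci = 0; ci + 1 < (R_xlen_t)centers.size(); ++ci) {
    R_xlen_t a = centers[ci], b = centers[ci + 1];
    double va = vals[ci], vb = vals[ci + 1];
    for (R_xlen_t i = a; i <= b; ++i) {
      double f = (b == a) ? 0.0 : (double)(i - a) / (double)(b - a);
      out[i] = va + f * (vb - va);
    }
  }
  if (centers.size() == 1) out[centers[0]] = vals[0];
  return out;
}
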