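// Core step loop of the lattice-free 2D diffusion/dimerisation Monte Carlo.
//
// Particles diffuse by independent per-axis Gaussian steps (sd = sqrt(2 D dT))
// on a periodic square box; monomer pairs within the collision diameter
// (minimum image) dimerise with probability p per step of overlap, pairs being
// resolved closest-first with each monomer in at most one event per step;
// dimers dissociate with probability 1 - exp(-k_off dT), the two monomers
// re-emitted at contact separation * (1 + tol) in a random orientation.
// Higher-order species never form.
//
// The RNG is a self-contained xoshiro256++ generator (polar Box-Muller for
// normals) seeded from a single integer: the step loop runs ~1e9 draws per
// call, and determinism per seed is part of the package contract.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
    have_norm = false;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  bool have_norm;
  double cached_norm;

  // standard normal, polar Box-Muller with caching
  inline double norm() {
    if (have_norm) {
      have_norm = false;
      return cached_norm;
    }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cached_norm = v * f;
    have_norm = true;
    return u * f;
  }
};

inline double wrap(double x, double box) {
  x -= box * std::floor(x / box);
  if (x >= box) x = 0.0;  // guard against floor rounding at the boundary
  return x;
}

// signed minimum-image separation component
inline double mindiff(double dx, double box) {
  if (dx > 0.5 * box) dx -= box;
  else if (dx < -0.5 * box) dx += box;
  return dx;
}

struct Pair {
  double d2;
  int i, j;
};

}  // namespace

// [[Rcpp::export]]
List mc_run_cpp(int n_receptors, double box, double d_mon, double d_dim,
                double coll_diam, double p_coll, double k_off, double dt,
                double n_steps_d, int sample_every, double offset_tol,
                double seed, int frame_every, int max_frames) {
  const long long n_steps = (long long)(n_steps_d + 0.5);
  const int cap = n_receptors;
  std::vector<double> x(cap), y(cap);
  std::vector<int> species(cap), id1(cap), id2(cap);  // species 0=mon,1=dim,2=dead

  Xoshiro256 rng((uint64_t)seed);

  int n = n_receptors;  // current particle count
  for (int i = 0; i < n; ++i) {
    x[i] = rng.unif() * box;
    y[i] = rng.unif() * box;
    species[i] = 0;
    id1[i] = i;
    id2[i] = -1;
  }

  // cell grid: cell size >= collision diameter, occupancy kept O(1)
  int ncell = (int)std::floor(box / coll_diam);
  const int ncell_cap = 4 * (int)std::ceil(std::sqrt((double)n_receptors)) + 1;
  if (ncell > ncell_cap) ncell = ncell_cap;
  if (ncell < 1) ncell = 1;
  const double cell_size = box / ncell;
  std::vector<int> head(ncell * ncell), nxt(cap);

  const double sd_mon = std::sqrt(2.0 * d_mon * dt);
  const double sd_dim = std::sqrt(2.0 * d_dim * dt);
  const double p_diss = 1.0 - std::exp(-k_off * dt);
  const double d2max = coll_diam * coll_diam;
  const double sep_out = coll_diam * (1.0 + offset_tol);

  const long long n_samples = n_steps / sample_every + 1;
  NumericVector out_t(n_samples);
  IntegerVector out_mon(n_samples), out_dim(n_samples), out_coll(n_samples),
      out_assoc(n_samples);

  const bool record = frame_every > 0 && max_frames > 0;
  NumericMatrix fx(record ? max_frames : 0, record ? cap : 0);
  NumericMatrix fy(record ? max_frames : 0, record ? cap : 0);
  IntegerMatrix fsp(record ? max_frames : 0, record ? cap : 0);
  IntegerMatrix fi1(record ? max_frames : 0, record ? cap : 0);
  IntegerMatrix fi2(record ? max_frames : 0, record ? cap : 0);
  IntegerVector fn(record ? max_frames : 0);
  NumericVector ft(record ? max_frames : 0);
  int frame_idx = 0;

  long long coll_acc = 0, assoc_acc = 0;
  double total_assoc = 0.0, total_dissoc = 0.0, integral_mm1 = 0.0;
  std::vector<Pair> pairs;
  pairs.reserve(64);

  int n_mon = n, n_dim = 0;
  long long sample_idx = 0;
  out_t[0] = 0.0; out_mon[0] = n_mon; out_dim[0] = 0;
  out_coll[0] = 0; out_assoc[0] = 0;
  sample_idx = 1;

  if (record) {
    fn[0] = n; ft[0] = 0.0;
    for (int i = 0; i < n; ++i) {
      fx(0, i) = x[i]; fy(0, i) = y[i];
      fsp(0, i) = species[i]; fi1(0, i) = id1[i]; fi2(0, i) = id2[i];
    }
    frame_idx = 1;
  }

  for (long long step = 1; step <= n_steps; ++step) {
    integral_mm1 += (double)n_mon * (double)(n_mon - 1) * dt;

    // diffusion
    for (int i = 0; i < n; ++i) {
      const double sd = species[i] == 0 ? sd_mon : sd_dim;
      x[i] = wrap(x[i] + sd * rng.norm(), box);
      y[i] = wrap(y[i] + sd * rng.norm(), box);
    }

    // rebuild grid
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)(x[i] / cell_size); if (cx >= ncell) cx = ncell - 1;
      int cy = (int)(y[i] / cell_size); if (cy >= ncell) cy = ncell - 1;
      const int c = cy * ncell + cx;
      nxt[i] = head[c];
      head[c] = i;
    }

    // collision detection among monomers
    pairs.clear();
    if (p_coll > 0.0 && n_mon > 1) {
      if (ncell < 4) {
        // grid too coarse to dedupe periodic neighbours; brute-force scan
        for (int i = 0; i < n; ++i) {
          if (species[i] != 0) continue;
          for (int j = i + 1; j < n; ++j) {
            if (species[j] != 0) continue;
            const double dx = mindiff(x[j] - x[i], box);
            const double dy = mindiff(y[j] - y[i], box);
            const double d2 = dx * dx + dy * dy;
            if (d2 <= d2max) pairs.push_back({d2, i, j});
          }
        }
      } else {
        for (int i = 0; i < n; ++i) {
          if (species[i] != 0) continue;
          const int cx = (int)(x[i] / cell_size) >= ncell ? ncell - 1
                         : (int)(x[i] / cell_size);
          const int cy = (int)(y[i] / cell_size) >= ncell ? ncell - 1
                         : (int)(y[i] / cell_size);
          for (int oy = -1; oy <= 1; ++oy) {
            for (int ox = -1; ox <= 1; ++ox) {
              const int ccx = (cx + ox + ncell) % ncell;
              const int ccy = (cy + oy + ncell) % ncell;
              for (int j = head[ccy * ncell + ccx]; j >= 0; j = nxt[j]) {
                if (j <= i || species[j] != 0) continue;
                const double dx = mindiff(x[j] - x[i], box);
                const double dy = mindiff(y[j] - y[i], box);
                const double d2 = dx * dx + dy * dy;
                if (d2 <= d2max) pairs.push_back({d2, i, j});
              }
            }
          }
        }
      }
      coll_acc += (long long)pairs.size();
      if (!pairs.empty()) {
        std::sort(pairs.begin(), pairs.end(),
                  [](const Pair& a, const Pair& b) { return a.d2 < b.d2; });
        for (const Pair& pr : pairs) {
          if (species[pr.i] != 0 || species[pr.j] != 0) continue;
          if (rng.unif() < p_coll) {
            const int i = pr.i, j = pr.j;
            const double dx = mindiff(x[j] - x[i], box);
            const double dy = mindiff(y[j] - y[i], box);
            x[i] = wrap(x[i] + 0.5 * dx, box);
            y[i] = wrap(y[i] + 0.5 * dy, box);
            species[i] = 1;
            id2[i] = id1[j];
            species[j] = 2;  // dead, compacted below
            n_mon -= 2;
            n_dim += 1;
            assoc_acc += 1;
            total_assoc += 1.0;
          }
        }
      }
    }

    // dissociation (new monomers appended, never re-tested this step)
    if (p_diss > 0.0 && n_dim > 0) {
      const int n_now = n;
      for (int i = 0; i < n_now; ++i) {
        if (species[i] != 1) continue;
        if (rng.unif() < p_diss) {
          const double ang = rng.unif() * 6.283185307179586;
          const double hx = 0.5 * sep_out * std::cos(ang);
          const double hy = 0.5 * sep_out * std::sin(ang);
          const int k = n++;
          x[k] = wrap(x[i] + hx, box);
          y[k] = wrap(y[i] + hy, box);
          species[k] = 0;
          id1[k] = id2[i];
          id2[k] = -1;
          x[i] = wrap(x[i] - hx, box);
          y[i] = wrap(y[i] - hy, box);
          species[i] = 0;
          id2[i] = -1;
          n_mon += 2;
          n_dim -= 1;
          total_dissoc += 1.0;
        }
      }
    }

    // compact dead slots
    for (int i = 0; i < n;) {
      if (species[i] == 2) {
        --n;
        x[i] = x[n]; y[i] = y[n];
        species[i] = species[n]; id1[i] = id1[n]; id2[i] = id2[n];
        species[n] = 2;
      } else {
        ++i;
      }
    }

    if (step % sample_every == 0 && sample_idx < n_samples) {
      out_t[sample_idx] = step * dt;
      out_mon[sample_idx] = n_mon;
      out_dim[sample_idx] = n_dim;
      out_coll[sample_idx] = (int)coll_acc;
      out_assoc[sample_idx] = (int)assoc_acc;
      coll_acc = 0;
      assoc_acc = 0;
      ++sample_idx;
    }

    if (record && step % frame_every == 0 && frame_idx < max_frames) {
      fn[frame_idx] = n; ft[frame_idx] = step * dt;
      for (int i = 0; i < n; ++i) {
        fx(frame_idx, i) = x[i]; fy(frame_idx, i) = y[i];
        fsp(frame_idx, i) = species[i];
        fi1(frame_idx, i) = id1[i]; fi2(frame_idx, i) = id2[i];
      }
      ++frame_idx;
    }
  }

  List out = List::create(
      _["times"] = out_t[Range(0, (int)sample_idx - 1)],
      _["n_monomer"] = out_mon[Range(0, (int)sample_idx - 1)],
      _["n_dimer"] = out_dim[Range(0, (int)sample_idx - 1)],
      _["n_collisions"] = out_coll[Range(0, (int)sample_idx - 1)],
      _["n_associations"] = out_assoc[Range(0, (int)sample_idx - 1)],
      _["total_associations"] = total_assoc,
      _["total_dissociations"] = total_dissoc,
      _["integral_mm1_dt"] = integral_mm1);
  if (record) {
    out["frames"] = List::create(
        _["time"] = ft[Range(0, frame_idx - 1)], _["n"] = fn[Range(0, frame_idx - 1)],
        _["x"] = fx, _["y"] = fy, _["species"] = fsp,
        _["id1"] = fi1, _["id2"] = fi2, _["n_frames"] = frame_idx);
  }
  return out;
}

// Independent 2D Brownian track generator used by the synthetic-data module:
// per-axis Gaussian steps with sd sqrt(2 D dt) plus localisation noise.
// Kept in C++ only because the acceptance-scale datasets run to ~1e5 points.
// [[Rcpp::export]]
List brownian_tracks_cpp(int n_tracks, IntegerVector lengths, double d_coef,
                         double frame_interval, double loc_noise, double seed) {
  Xoshiro256 rng((uint64_t)seed);
  const double sd = std::sqrt(2.0 * d_coef * frame_interval);
  long long total = 0;
  for (int i = 0; i < n_tracks; ++i) total += lengths[i];
  IntegerVector track_id(total), frame(total);
  NumericVector xs(total), ys(total);
  long long k = 0;
  for (int i = 0; i < n_tracks; ++i) {
    double px = 0.0, py = 0.0;
    for (int f = 0; f < lengths[i]; ++f) {
      if (f > 0) {
        px += sd * rng.norm();
        py += sd * rng.norm();
      }
      track_id[k] = i + 1;
      frame[k] = f;
      xs[k] = px + (loc_noise > 0 ? loc_noise * rng.norm() : 0.0);
      ys[k] = py + (loc_noise > 0 ? loc_noise * rng.norm() : 0.0);
      ++k;
    }
  }
  return List::create(_["track_id"] = track_id, _["frame"] = frame,
                      _["x_um"] = xs, _["y_um"] = ys);
}
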