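// Overdamped Brownian-dynamics propagator with optional bias controllers.
// Uses R's RNG (norm_rand) in a fixed draw order — per step, per particle,
// per axis — so a run is bit-reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Decision {
  double fx, fy, fz;
  int reason; // matches bias_reason_codes on the R side
};

// protocol: 0 none, 1 steer, 2 flat-bottom
inline Decision decide(double x, double y, double z,
                       double rx, double ry, double rz,
                       int protocol, double f0, double cutoff,
                       double k_fb, double cone_apex) {
  Decision d = {0.0, 0.0, 0.0, 0};
  if (protocol == 0) return d;
  double dx = rx - x, dy = ry - y, dz = rz - z;
  double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (protocol == 1) {
    double rad = z + cone_apex;
    bool in_cone = (z > 0.0) && (x * x + y * y < rad * rad);
    if (!in_cone) { d.reason = 3; return d; }            // outside_region
    if (dist <= cutoff) { d.reason = 2; return d; }      // within_cutoff
    if (dist < 1e-12) { d.reason = 6; return d; }        // degenerate_zero
    double s = f0 / dist;
    d.fx = s * dx; d.fy = s * dy; d.fz = s * dz;
    d.reason = 1;                                        // beyond_cutoff_in_region
    return d;
  }
  // flat-bottom
  if (dist <= cutoff) { d.reason = 4; return d; }        // inside_flat_region
  double s = k_fb * (dist - cutoff) / dist;
  d.fx = s * dx; d.fy = s * dy; d.fz = s * dz;
  d.reason = 5;                                          // in_harmonic_region
  return d;
}

} // namespace

// [[Rcpp::export]]
List bd_run_cpp(NumericMatrix init,        // N x 3 initial positions
                NumericVector ref,         // reference atom position (3)
                NumericVector box_len,     // 3 edge lengths
                LogicalVector periodic,    // 3 flags (wrap on axis)
                bool wall_lo, bool wall_hi,// reflective walls at z=0 / z=Lz
                int n_steps, double dt, double D, double kBT,
                int stride, int protocol,
                double f0, double cutoff, double k_fb, double cone_apex,
                int update_period,
                double well_depth, double well_sigma,
                double rep_radius, double rep_k) {
  const int N = init.nrow();
  if (N < 1) stop("need at least one particle");
  if (stride < 1) stop("stride must be >= 1");
  const int n_frames = n_steps / stride + 1;

  std::vector<double> px(N), py(N), pz(N);
  for (int i = 0; i < N; ++i) { px[i] = init(i, 0); py[i] = init(i, 1); pz[i] = init(i, 2); }
  const double rx = ref[0], ry = ref[1], rz = ref[2];
  const double Lx = box_len[0], Ly = box_len[1], Lz = box_len[2];
  const bool perx = periodic[0], pery = periodic[1], perz = periodic[2];
  const double mu = D / kBT;
  const double noise = std::sqrt(2.0 * D * dt);
  const double inv2s2 = (well_sigma > 0) ? 1.0 / (2.0 * well_sigma * well_sigma) : 0.0;
  const double wpref = (well_sigma > 0) ? well_depth / (well_sigma * well_sigma) : 0.0;

  NumericVector coords(static_cast<R_xlen_t>(n_frames) * N * 3);
  coords.attr("dim") = IntegerVector::create(n_frames, N, 3);
  IntegerMatrix reasons(n_frames, N);
  NumericVector times(n_frames);

  std::vector<Decision> held(N);
  for (int i = 0; i < N; ++i) held[i] = Decision{0, 0, 0, 0};
  double max_drift = 0.0;

  int fi = 0;
  for (int s = 0; s <= n_steps; ++s) {
    if (s % update_period == 0) {
      for (int i = 0; i < N; ++i)
        held[i] = decide(px[i], py[i], pz[i], rx, ry, rz,
                         protocol, f0, cutoff, k_fb, cone_apex);
    }
    if (s % stride == 0 && fi < n_frames) {
      times[fi] = s * dt;
      for (int i = 0; i < N; ++i) {
        coords[fi + n_frames * (static_cast<R_xlen_t>(i))] = px[i];
        coords[fi + n_frames * (static_cast<R_xlen_t>(i) + N)] = py[i];
        coords[fi + n_frames * (static_cast<R_xlen_t>(i) + 2 * static_cast<R_xlen_t>(N))] = pz[i];
        reasons(fi, i) = held[i].reason;
      }
      ++fi;
    }
    if (s == n_steps) break;

    // deterministic forces: held bias + attractive Gaussian well (+ repulsion)
    std::vector<double> fxv(N), fyv(N), fzv(N);
    for (int i = 0; i < N; ++i) {
      double fx = held[i].fx, fy = held[i].fy, fz = held[i].fz;
      if (well_depth > 0.0) {
        double dx = rx - px[i], dy = ry - py[i], dz = rz - pz[i];
        double d2 = dx * dx + dy * dy + dz * dz;
        double w = wpref * std::exp(-d2 * inv2s2);
        fx += w * dx; fy += w * dy; fz += w * dz;
      }
      fxv[i] = fx; fyv[i] = fy; fzv[i] = fz;
    }
    if (rep_k > 0.0 && rep_radius > 0.0 && N > 1) {
      for (int i = 0; i < N - 1; ++i) {
        for (int j = i + 1; j < N; ++j) {
          double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
          if (perx) dx -= Lx * std::round(dx / Lx);
          if (pery) dy -= Ly * std::round(dy / Ly);
          if (perz) dz -= Lz * std::round(dz / Lz);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < rep_radius * rep_radius && d2 > 1e-20) {
            double d = std::sqrt(d2);
            double s2 = rep_k * (rep_radius - d) / d;
            fxv[i] += s2 * dx; fyv[i] += s2 * dy; fzv[i] += s2 * dz;
            fxv[j] -= s2 * dx; fyv[j] -= s2 * dy; fzv[j] -= s2 * dz;
          }
        }
      }
    }

    for (int i = 0; i < N; ++i) {
      double drift = mu * dt * std::sqrt(fxv[i] * fxv[i] + fyv[i] * fyv[i] + fzv[i] * fzv[i]);
      if (drift > max_drift) max_drift = drift;
      px[i] += mu * fxv[i] * dt + noise * norm_rand();
      py[i] += mu * fyv[i] * dt + noise * norm_rand();
      pz[i] += mu * fzv[i] * dt + noise * norm_rand();
      // reflective walls in z (membrane surface at 0, cell top at Lz)
      if (wall_lo || wall_hi) {
        for (int it = 0; it < 8; ++it) {
          bool moved = false;
          if (wall_lo && pz[i] < 0.0) { pz[i] = -pz[i]; moved = true; }
          if (wall_hi && pz[i] > Lz) { pz[i] = 2.0 * Lz - pz[i]; moved = true; }
          if (!moved) break;
        }
      }
      if (perx) px[i] -= Lx * std::round(px[i] / Lx);
      if (pery) py[i] -= Ly * std::round(py[i] / Ly);
      if (perz) pz[i] -= Lz * std::round(pz[i] / Lz);
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]) || !std::isfinite(pz[i]))
        stop("non-finite position at step %d, particle %d", s + 1, i + 1);
    }
  }

  return List::create(_["times"] = times, _["coords"] = coords,
                      _["reasons"] = reasons, _["max_drift"] = max_drift);
}
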