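// Particle-simulation core: uniform-grid sphere index, signed surface
// queries, specular reflection of Brownian steps, and the main stepping
// loop with hazard-based binding near astroglial surfaces.
//
// Units: lengths in micrometres, times in milliseconds throughout.
// All randomness comes from R's RNG (unif_rand), so a given set.seed()
// reproduces trajectories exactly, and the R-level step functions
// (propose/resolve/bind) consume the stream in the identical order.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double NUDGE = 1e-9;   // push-off after reflection, um
static const double BIG = 1e30;

struct SphereIndex {
  int n;
  std::vector<double> cx, cy, cz, rad;
  std::vector<int> kind;            // 1 neuronal, 2 astroglial
  double half;                      // arena half-edge; arena = [-half, half]^3
  int nc;                           // grid cells per dimension
  double cell;
  std::vector<int> start, items;    // CSR cell -> sphere ids
  mutable std::vector<int> stamp;
  mutable int cur;

  inline int cidx(double v) const {
    int i = (int)std::floor((v + half) / cell);
    if (i < 0) i = 0;
    if (i >= nc) i = nc - 1;
    return i;
  }

  void build(const NumericMatrix &centers, const NumericVector &radii,
             const IntegerVector &kinds, double arena_edge, double cell_edge) {
    n = centers.nrow();
    half = arena_edge / 2.0;
    cx.resize(n); cy.resize(n); cz.resize(n); rad.resize(n); kind.resize(n);
    for (int i = 0; i < n; ++i) {
      cx[i] = centers(i, 0); cy[i] = centers(i, 1); cz[i] = centers(i, 2);
      rad[i] = radii[i]; kind[i] = kinds[i];
    }
    nc = std::max(1, (int)std::ceil(arena_edge / cell_edge));
    cell = arena_edge / nc;
    // count pass, then fill: register each sphere in every cell its AABB meets
    std::vector<int> cnt(nc * nc * nc + 1, 0);
    for (int s = 0; s < n; ++s) {
      int x0 = cidx(cx[s] - rad[s]), x1 = cidx(cx[s] + rad[s]);
      int y0 = cidx(cy[s] - rad[s]), y1 = cidx(cy[s] + rad[s]);
      int z0 = cidx(cz[s] - rad[s]), z1 = cidx(cz[s] + rad[s]);
      for (int ix = x0; ix <= x1; ++ix)
        for (int iy = y0; iy <= y1; ++iy)
          for (int iz = z0; iz <= z1; ++iz)
            cnt[(ix * nc + iy) * nc + iz + 1]++;
    }
    start.assign(nc * nc * nc + 1, 0);
    for (size_t c = 1; c < start.size(); ++c) start[c] = start[c - 1] + cnt[c];
    items.assign(start.back(), 0);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int s = 0; s < n; ++s) {
      int x0 = cidx(cx[s] - rad[s]), x1 = cidx(cx[s] + rad[s]);
      int y0 = cidx(cy[s] - rad[s]), y1 = cidx(cy[s] + rad[s]);
      int z0 = cidx(cz[s] - rad[s]), z1 = cidx(cz[s] + rad[s]);
      for (int ix = x0; ix <= x1; ++ix)
        for (int iy = y0; iy <= y1; ++iy)
          for (int iz = z0; iz <= z1; ++iz)
            items[fill[(ix * nc + iy) * nc + iz]++] = s;
    }
    stamp.assign(n, -1);
    cur = 0;
  }

  // spheres whose AABB-registered cells overlap box [lo, hi]
  void gather(const double lo[3], const double hi[3],
              std::vector<int> &out) const {
    out.clear();
    if (n == 0) return;
    ++cur;
    int x0 = cidx(lo[0]), x1 = cidx(hi[0]);
    int y0 = cidx(lo[1]), y1 = cidx(hi[1]);
    int z0 = cidx(lo[2]), z1 = cidx(hi[2]);
    for (int ix = x0; ix <= x1; ++ix)
      for (int iy = y0; iy <= y1; ++iy)
        for (int iz = z0; iz <= z1; ++iz) {
          int c = (ix * nc + iy) * nc + iz;
          for (int k = start[c]; k < start[c + 1]; ++k) {
            int s = items[k];
            if (stamp[s] != cur) { stamp[s] = cur; out.push_back(s); }
          }
        }
  }
};

static inline double sq(double x) { return x * x; }

// distance from p to nearest arena wall (positive inside)
static inline double wall_dist(const double p[3], double half) {
  double m = std::fabs(p[0]);
  if (std::fabs(p[1]) > m) m = std::fabs(p[1]);
  if (std::fabs(p[2]) > m) m = std::fabs(p[2]);
  return half - m;
}

// distance from p to the nearer of the two cleft membrane disks
// (radius R, planes z = +-h, centred on the origin, axis z)
static inline double cleft_face_dist(const double p[3], double R, double h) {
  double rho = std::sqrt(sq(p[0]) + sq(p[1]));
  double dr = rho > R ? rho - R : 0.0;
  double d1 = std::sqrt(sq(dr) + sq(p[2] - h));
  double d2 = std::sqrt(sq(dr) + sq(p[2] + h));
  return d1 < d2 ? d1 : d2;
}

// signed distance to the union sphere surface and to astroglial surfaces
// within scan radius q around p; values capped at q when nothing is found
struct Scan { double d_any; double d_astro; };

static Scan scan_point(const double p[3], double q, const SphereIndex &S,
                       double cleftR, double cleftH,
                       std::vector<int> &buf) {
  double lo[3] = { p[0] - q, p[1] - q, p[2] - q };
  double hi[3] = { p[0] + q, p[1] + q, p[2] + q };
  S.gather(lo, hi, buf);
  Scan sc; sc.d_any = q; sc.d_astro = q + 1.0;
  for (size_t k = 0; k < buf.size(); ++k) {
    int s = buf[k];
    double d = std::sqrt(sq(p[0] - S.cx[s]) + sq(p[1] - S.cy[s]) +
                         sq(p[2] - S.cz[s])) - S.rad[s];
    if (d < sc.d_any) sc.d_any = d;
    if (S.kind[s] == 2 && d < sc.d_astro) sc.d_astro = d;
  }
  double w = wall_dist(p, S.half);
  if (w < sc.d_any) sc.d_any = w;
  double f = cleft_face_dist(p, cleftR, cleftH);
  if (f < sc.d_any) sc.d_any = f;
  return sc;
}

// Move a particle by displacement d with specular reflection off sphere
// surfaces, arena walls, and the two cleft membrane disks. Returns false
// (position untouched beyond partial advance is rolled back by caller)
// when max_reflect reflections do not finish the step.
static bool step_particle(double p[3], double d[3], const SphereIndex &S,
                          double cleftR, double cleftH, int max_reflect,
                          std::vector<int> &buf, int *nrefl) {
  for (int it = 0; it <= max_reflect; ++it) {
    double L2 = sq(d[0]) + sq(d[1]) + sq(d[2]);
    if (L2 < 1e-28) return true;
    double tmin = 2.0, nrm[3] = {0, 0, 0};
    // arena walls
    for (int a = 0; a < 3; ++a) {
      if (d[a] > 0 && p[a] + d[a] > S.half) {
        double t = (S.half - p[a]) / d[a];
        if (t >= 0 && t < tmin) { tmin = t; nrm[0] = nrm[1] = nrm[2] = 0; nrm[a] = -1; }
      } else if (d[a] < 0 && p[a] + d[a] < -S.half) {
        double t = (-S.half - p[a]) / d[a];
        if (t >= 0 && t < tmin) { tmin = t; nrm[0] = nrm[1] = nrm[2] = 0; nrm[a] = 1; }
      }
    }
    // cleft membrane disks at z = +-h (two-sided, radius cleftR)
    if (d[2] != 0) {
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double zp = sgn * cleftH;
        if ((p[2] - zp) * (p[2] + d[2] - zp) < 0) {
          double t = (zp - p[2]) / d[2];
          double x = p[0] + t * d[0], y = p[1] + t * d[1];
          if (sq(x) + sq(y) <= sq(cleftR) && t >= 0 && t < tmin) {
            tmin = t; nrm[0] = nrm[1] = 0; nrm[2] = d[2] > 0 ? -1 : 1;
          }
        }
      }
    }
    // spheres along the segment
    double lo[3], hi[3];
    for (int a = 0; a < 3; ++a) {
      double q = p[a] + d[a];
      lo[a] = p[a] < q ? p[a] : q;
      hi[a] = p[a] > q ? p[a] : q;
    }
    S.gather(lo, hi, buf);
    int hit_s = -1;
    for (size_t k = 0; k < buf.size(); ++k) {
      int s = buf[k];
      double ex = p[0] - S.cx[s], ey = p[1] - S.cy[s], ez = p[2] - S.cz[s];
      double c0 = sq(ex) + sq(ey) + sq(ez) - sq(S.rad[s]);
      if (c0 <= 0) continue;                       // already on/inside: skip
      double b = 2.0 * (d[0] * ex + d[1] * ey + d[2] * ez);
      if (b >= 0) continue;                        // moving away
      double disc = sq(b) - 4.0 * L2 * c0;
      if (disc <= 0) continue;
      double t = (-b - std::sqrt(disc)) / (2.0 * L2);
      if (t >= 0 && t <= 1 && t < tmin) { tmin = t; hit_s = s; }
    }
    if (tmin > 1.0) {                              // no obstacle: finish
      p[0] += d[0]; p[1] += d[1]; p[2] += d[2];
      return true;
    }
    p[0] += tmin * d[0]; p[1] += tmin * d[1]; p[2] += tmin * d[2];
    if (hit_s >= 0) {
      double nx = p[0] - S.cx[hit_s], ny = p[1] - S.cy[hit_s], nz = p[2] - S.cz[hit_s];
      double nn = std::sqrt(sq(nx) + sq(ny) + sq(nz));
      nrm[0] = nx / nn; nrm[1] = ny / nn; nrm[2] = nz / nn;
    }
    double rem[3] = { (1 - tmin) * d[0], (1 - tmin) * d[1], (1 - tmin) * d[2] };
    double dot = rem[0] * nrm[0] + rem[1] * nrm[1] + rem[2] * nrm[2];
    d[0] = rem[0] - 2 * dot * nrm[0];
    d[1] = rem[1] - 2 * dot * nrm[1];
    d[2] = rem[2] - 2 * dot * nrm[2];
    p[0] += NUDGE * nrm[0]; p[1] += NUDGE * nrm[1]; p[2] += NUDGE * nrm[2];
    (*nrefl)++;
  }
  return false;
}

// [[Rcpp::export]]
IntegerVector cpp_classify_points(NumericMatrix points, NumericMatrix centers,
                                  NumericVector radii, IntegerVector kinds,
                                  double arena_edge, double cell_edge) {
  SphereIndex S;
  S.build(centers, radii, kinds, arena_edge, cell_edge);
  int m = points.nrow();
  IntegerVector out(m);               // 0 ECS, 1 neuronal, 2 astroglial
  std::vector<int> buf;
  for (int i = 0; i < m; ++i) {
    double p[3] = { points(i, 0), points(i, 1), points(i, 2) };
    double lo[3] = { p[0], p[1], p[2] }, hi[3] = { p[0], p[1], p[2] };
    S.gather(lo, hi, buf);
    int cls = 0;
    for (size_t k = 0; k < buf.size(); ++k) {
      int s = buf[k];
      double d2 = sq(p[0] - S.cx[s]) + sq(p[1] - S.cy[s]) + sq(p[2] - S.cz[s]);
      if (d2 <= sq(S.rad[s])) {
        if (S.kind[s] == 2) { cls = 2; break; }   // astroglial wins overlaps
        cls = 1;
      }
    }
    out[i] = cls;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_query_surface(NumericMatrix points, NumericMatrix centers,
                       NumericVector radii, IntegerVector kinds,
                       double arena_edge, double cell_edge,
                       double max_radius, bool use_index) {
  SphereIndex S;
  S.build(centers, radii, kinds, arena_edge, cell_edge);
  int m = points.nrow();
  NumericVector dist(m), astro(m);
  IntegerVector nkind(m), nid(m);
  std::vector<int> buf;
  for (int i = 0; i < m; ++i) {
    double p[3] = { points(i, 0), points(i, 1), points(i, 2) };
    double dmin = BIG, amin = BIG;
    int best = -1;
    if (use_index) {
      double lo[3] = { p[0] - max_radius, p[1] - max_radius, p[2] - max_radius };
      double hi[3] = { p[0] + max_radius, p[1] + max_radius, p[2] + max_radius };
      S.gather(lo, hi, buf);
    } else {
      buf.resize(S.n);
      for (int s = 0; s < S.n; ++s) buf[s] = s;
    }
    for (size_t k = 0; k < buf.size(); ++k) {
      int s = buf[k];
      double d = std::sqrt(sq(p[0] - S.cx[s]) + sq(p[1] - S.cy[s]) +
                           sq(p[2] - S.cz[s])) - S.rad[s];
      if (d > max_radius) continue;
      if (d < dmin) { dmin = d; best = s; }
      if (S.kind[s] == 2 && d < amin) amin = d;
    }
    if (best < 0) {
      dist[i] = R_PosInf; nkind[i] = 0; nid[i] = NA_INTEGER;
    } else {
      dist[i] = dmin; nkind[i] = S.kind[best]; nid[i] = best + 1;
    }
    astro[i] = amin >= BIG ? R_PosInf : amin;
  }
  return List::create(_["distance"] = dist, _["nearest_kind"] = nkind,
                      _["nearest_id"] = nid, _["astro_distance"] = astro);
}

// [[Rcpp::export]]
List cpp_resolve_motion(NumericMatrix old_pos, NumericMatrix proposed,
                        NumericMatrix centers, NumericVector radii,
                        IntegerVector kinds, double arena_edge,
                        double cell_edge, double cleft_radius,
                        double cleft_half_height, int max_reflect) {
  SphereIndex S;
  S.build(centers, radii, kinds, arena_edge, cell_edge);
  int m = old_pos.nrow();
  NumericMatrix fin(m, 3);
  LogicalVector rejected(m);
  IntegerVector nrefl(m);
  std::vector<int> buf;
  for (int i = 0; i < m; ++i) {
    double p[3] = { old_pos(i, 0), old_pos(i, 1), old_pos(i, 2) };
    double d[3] = { proposed(i, 0) - p[0], proposed(i, 1) - p[1],
                    proposed(i, 2) - p[2] };
    int nr = 0;
    bool ok = step_particle(p, d, S, cleft_radius, cleft_half_height,
                            max_reflect, buf, &nr);
    if (ok) {   // final containment guard against degenerate round-off
      Scan sc = scan_point(p, 1e-6, S, cleft_radius, cleft_half_height, buf);
      if (sc.d_any < -1e-9) ok = false;
    }
    if (!ok) {
      rejected[i] = true;
      fin(i, 0) = old_pos(i, 0); fin(i, 1) = old_pos(i, 1); fin(i, 2) = old_pos(i, 2);
    } else {
      fin(i, 0) = p[0]; fin(i, 1) = p[1]; fin(i, 2) = p[2];
    }
    nrefl[i] = nr;
  }
  return List::create(_["final"] = fin, _["rejected"] = rejected,
                      _["reflections"] = nrefl);
}

// Main loop. Per step and per free particle, in particle order: two
// uniform deviates give the isotropic fixed-length step; a third deviate
// is drawn only when the particle sits within the astroglial proximity
// shell (binding hazard 1 - exp(-dt/psi)). Free-flight bookkeeping skips
// geometry scans while a particle is provably farther than the shell from
// every surface; it consumes the RNG stream identically.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos0, NumericMatrix centers,
                  NumericVector radii, IntegerVector kinds,
                  double arena_edge, double cell_edge,
                  double cleft_radius, double cleft_half_height,
                  double step_length, double dt, double psi, double shell,
                  int n_steps, IntegerVector snapshot_steps,
                  int series_stride, int max_reflect, double scan_radius,
                  int binding_law) {
  SphereIndex S;
  S.build(centers, radii, kinds, arena_edge, cell_edge);
  int n = pos0.nrow();
  std::vector<double> px(n), py(n), pz(n), btime(n, NA_REAL), clock(n, 0.0),
      slack(n, 0.0), astro_d(n, BIG);
  std::vector<int> state(n, 0);
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1); pz[i] = pos0(i, 2);
  }
  double pbind = (psi == R_PosInf) ? 0.0 : 1.0 - std::exp(-dt / psi);
  int n_rejected = 0, nbound = 0;
  std::vector<int> buf;
  std::vector<double> ser_t;
  std::vector<int> ser_n;
  List snaps;
  int snap_ptr = 0;
  const double twopi = 2.0 * M_PI;

  for (int s = 1; s <= n_steps; ++s) {
    // motion pass
    for (int i = 0; i < n; ++i) {
      if (state[i]) continue;
      double u1 = unif_rand(), u2 = unif_rand();
      double z = 2.0 * u1 - 1.0;
      double sz = std::sqrt(std::max(0.0, 1.0 - z * z));
      double phi = twopi * u2;
      // grouped to match the R-level propose_step() arithmetic exactly;
      // the proposed-position round trip mirrors resolve_motion(), which
      // receives positions and re-derives the displacement
      double d[3] = { step_length * (sz * std::cos(phi)),
                      step_length * (sz * std::sin(phi)),
                      step_length * z };
      d[0] = (px[i] + d[0]) - px[i];
      d[1] = (py[i] + d[1]) - py[i];
      d[2] = (pz[i] + d[2]) - pz[i];
      if (slack[i] >= step_length) {              // provably obstacle-free
        px[i] += d[0]; py[i] += d[1]; pz[i] += d[2];
        slack[i] -= step_length;
        astro_d[i] = BIG;
        continue;
      }
      // fast path: one gather around the step; if no sphere can touch the
      // segment (surface farther than one step from the start) and neither
      // walls nor cleft faces are crossed, the step is collision-free and
      // endpoint clearances come from the same candidate list
      double p0[3] = { px[i], py[i], pz[i] };
      double pe[3] = { p0[0] + d[0], p0[1] + d[1], p0[2] + d[2] };
      double q = scan_radius + step_length;
      double lo[3] = { p0[0] - q, p0[1] - q, p0[2] - q };
      double hi[3] = { p0[0] + q, p0[1] + q, p0[2] + q };
      S.gather(lo, hi, buf);
      bool slow = false;
      double dmin = scan_radius, dastro = scan_radius + 1.0;
      for (size_t k = 0; k < buf.size(); ++k) {
        int sidx = buf[k];
        double r = S.rad[sidx];
        double d2s = sq(p0[0] - S.cx[sidx]) + sq(p0[1] - S.cy[sidx]) +
                     sq(p0[2] - S.cz[sidx]);
        if (d2s <= sq(r + step_length)) { slow = true; break; }
        double d2e = sq(pe[0] - S.cx[sidx]) + sq(pe[1] - S.cy[sidx]) +
                     sq(pe[2] - S.cz[sidx]);
        if (d2e < sq(r + scan_radius)) {
          double de = std::sqrt(d2e) - r;
          if (de < dmin) dmin = de;
          if (S.kind[sidx] == 2 && de < dastro) dastro = de;
        }
      }
      if (!slow) {
        // wall crossing?
        if (std::fabs(pe[0]) > S.half || std::fabs(pe[1]) > S.half ||
            std::fabs(pe[2]) > S.half) slow = true;
        // cleft face crossing?
        if (!slow && d[2] != 0) {
          for (int sgn = -1; sgn <= 1 && !slow; sgn += 2) {
            double zp = sgn * cleft_half_height;
            if ((p0[2] - zp) * (pe[2] - zp) < 0) {
              double t = (zp - p0[2]) / d[2];
              double x = p0[0] + t * d[0], y = p0[1] + t * d[1];
              if (sq(x) + sq(y) <= sq(cleft_radius)) slow = true;
            }
          }
        }
      }
      if (!slow) {
        px[i] = pe[0]; py[i] = pe[1]; pz[i] = pe[2];
        double w = wall_dist(pe, S.half);
        if (w < dmin) dmin = w;
        double f = cleft_face_dist(pe, cleft_radius, cleft_half_height);
        if (f < dmin) dmin = f;
        slack[i] = std::max(0.0, dmin - shell);
        astro_d[i] = dastro;
        continue;
      }
      double p[3] = { p0[0], p0[1], p0[2] };
      int nr = 0;
      bool ok = step_particle(p, d, S, cleft_radius, cleft_half_height,
                              max_reflect, buf, &nr);
      if (!ok) { p[0] = p0[0]; p[1] = p0[1]; p[2] = p0[2]; n_rejected++; }
      Scan sc = scan_point(p, scan_radius, S, cleft_radius, cleft_half_height, buf);
      if (ok && sc.d_any < -1e-9) {               // round-off safety net
        p[0] = p0[0]; p[1] = p0[1]; p[2] = p0[2];
        n_rejected++;
        sc = scan_point(p, scan_radius, S, cleft_radius, cleft_half_height, buf);
      }
      px[i] = p[0]; py[i] = p[1]; pz[i] = p[2];
      slack[i] = std::max(0.0, std::min(sc.d_any, scan_radius) - shell);
      astro_d[i] = sc.d_astro;
    }
    // binding pass
    for (int i = 0; i < n; ++i) {
      if (state[i]) continue;
      if (astro_d[i] <= shell) {
        clock[i] += dt;
        double u = unif_rand();
        double p = (binding_law == 1)
          ? ((psi == R_PosInf) ? 0.0 : 1.0 - std::exp(-clock[i] / psi))
          : pbind;
        if (u < p) {
          state[i] = 1;
          btime[i] = s * dt;
          nbound++;
        }
      } else {
        clock[i] = 0.0;
      }
    }
    if (series_stride > 0 && (s % series_stride == 0 || s == n_steps)) {
      ser_t.push_back(s * dt);
      ser_n.push_back(nbound);
    }
    while (snap_ptr < snapshot_steps.size() && snapshot_steps[snap_ptr] <= s) {
      NumericMatrix sp(n, 3);
      IntegerVector st(n);
      NumericVector bt(n), ck(n);
      for (int i = 0; i < n; ++i) {
        sp(i, 0) = px[i]; sp(i, 1) = py[i]; sp(i, 2) = pz[i];
        st[i] = state[i]; bt[i] = btime[i]; ck[i] = clock[i];
      }
      snaps.push_back(List::create(_["step"] = s, _["time"] = s * dt,
                                   _["positions"] = sp, _["state"] = st,
                                   _["bound_time"] = bt, _["shell_clock"] = ck));
      snap_ptr++;
    }
  }
  return List::create(_["snapshots"] = snaps,
                      _["series_time"] = NumericVector(ser_t.begin(), ser_t.end()),
                      _["series_bound"] = IntegerVector(ser_n.begin(), ser_n.end()),
                      _["n_rejected"] = n_rejected,
                      _["n_bound"] = nbound);
}
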