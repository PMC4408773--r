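#include <Rcpp.h>
using namespace Rcpp;

// Two-state Markov chemotaxis stepper. Each model larva is a jointed
// two-segment object (head + tail segment, 2.15 mm each). Run state:
// both segments advance along the (noisy) heading at constant speed.
// Turn state: the head segment pivots about the joint at constant
// angular speed toward a drawn turning angle while the tail segment
// stays put; on completion the body axis adopts the head heading.
// Larvae are mutually independent (collisions only matter for the
// post-hoc fragmentation of tracks), so they are simulated one by one.

static const double DEG = M_PI / 180.0;

static inline double wrap180(double x) {
  double z = x + 180.0;
  double y = z - std::floor(z / 360.0) * 360.0 - 180.0;
  if (y == -180.0) y = 180.0;
  return y;
}

static inline double circdist(double a, double b) {
  return std::fabs(wrap180(a - b));
}

struct RateSpec {
  int kind;                    // 0 parametric, 1 grid
  double base, amp, slope, ref;
  NumericVector bgrid, dgrid;
  NumericMatrix grid;          // per-second rates, NA = undefined
  double mean_rate;            // per second
};

static int nearest(const NumericVector &g, double x) {
  int n = g.size(), lo = 0, hi = n - 1;
  if (x <= g[0]) return 0;
  if (x >= g[n - 1]) return n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (g[mid] <= x) lo = mid; else hi = mid;
  }
  return (x - g[lo] <= g[hi] - x) ? lo : hi;
}

static double eval_rate(const RateSpec &rs, double bearing, double dist) {
  if (rs.kind == 0) {
    double g = 1.0 + rs.slope * (dist - rs.ref) / rs.ref;
    if (g < 0) g = 0;
    double r = rs.base * (1.0 - rs.amp * std::cos(bearing * DEG)) * g;
    return r > 0 ? r : 0.0;
  }
  int bi = nearest(rs.bgrid, wrap180(bearing));
  int di = nearest(rs.dgrid, dist);
  double r = rs.grid(bi, di);
  if (NumericVector::is_na(r)) return rs.mean_rate;
  return r;
}

// uniform draw from the bank subsample around (bearing, dist) with the
// fallback chain: double the distance window once, then bearing-only,
// then the full bank
static double draw_bank_angle(const NumericVector &bb, const NumericVector &bd,
                              const NumericVector &ba, double bearing,
                              double dist, double bwin, double dwin,
                              std::vector<int> &buf, int *fallback) {
  int n = bb.size();
  for (int level = 0; level < 4; ++level) {
    buf.clear();
    double dw = (level == 1) ? 2 * dwin : dwin;
    for (int i = 0; i < n; ++i) {
      bool okb = (level == 3) || circdist(bb[i], bearing) <= bwin;
      bool okd = (level >= 2) || std::fabs(bd[i] - dist) <= dw;
      if (okb && okd) buf.push_back(i);
    }
    if (!buf.empty()) {
      *fallback = level;
      int k = (int)std::floor(unif_rand() * buf.size());
      if (k >= (int)buf.size()) k = buf.size() - 1;
      return ba[buf[k]];
    }
  }
  *fallback = 3;
  return 0.0; // unreachable: level 3 always matches a non-empty bank
}

// [[Rcpp::export(name = ".sim_larvae")]]
List sim_larvae_cpp(int n_steps, double dt, double seglen,
                    double run_speed, double ang_speed_deg_s,
                    double noise_hw_deg, double arena_r,
                    NumericMatrix start_mid, NumericVector start_heading,
                    double sx, double sy,
                    int rate_kind, double base_rate, double amplitude,
                    double dist_slope, double dist_ref,
                    NumericVector rate_bgrid, NumericVector rate_dgrid,
                    NumericMatrix rate_grid, double mean_rate,
                    NumericVector bank_bearing, NumericVector bank_dist,
                    NumericVector bank_angle,
                    bool random_rate, bool random_dir,
                    double bwin, double dwin, double rd_lo, double rd_hi) {
  int n_larvae = start_mid.nrow();
  RateSpec rs{rate_kind, base_rate, amplitude, dist_slope, dist_ref,
              rate_bgrid, rate_dgrid, rate_grid, mean_rate};
  std::vector<int> buf;
  buf.reserve(bank_bearing.size());

  List tracks(n_larvae);
  std::vector<double> ev_larva, ev_t0, ev_t1, ev_bear, ev_dist,
      ev_drawn, ev_realized;
  int n_clipped = 0;
  IntegerVector fallback_counts(4);

  for (int a = 0; a < n_larvae; ++a) {
    NumericMatrix M(n_steps + 1, 8); // t hx hy mx my tx ty state
    double jx = start_mid(a, 0), jy = start_mid(a, 1);
    double th = start_heading[a]; // body heading, deg
    double ha = 0.0;              // head angle rel. to body, deg (turn state)
    double phi = 0.0;             // drawn turning angle
    int state = 0;                // 0 run, 1 turn
    int ev_open = -1;

    for (int k = 0; k <= n_steps; ++k) {
      double hx = jx + seglen * std::cos((th + ha) * DEG);
      double hy = jy + seglen * std::sin((th + ha) * DEG);
      double tx = jx - seglen * std::cos(th * DEG);
      double ty = jy - seglen * std::sin(th * DEG);
      M(k, 0) = k * dt;
      M(k, 1) = hx; M(k, 2) = hy; M(k, 3) = jx; M(k, 4) = jy;
      M(k, 5) = tx; M(k, 6) = ty; M(k, 7) = state;
      if (k == n_steps) break;

      if (state == 0) {
        // possible run -> turn transition at the current bearing/distance
        double sdir = std::atan2(sy - jy, sx - jx) / DEG;
        double bearing = wrap180(sdir - th);
        double dist = std::sqrt((sx - jx) * (sx - jx) + (sy - jy) * (sy - jy));
        double r = random_rate ? mean_rate : eval_rate(rs, bearing, dist);
        double p = r * dt;
        if (p > 1.0) { p = 1.0; ++n_clipped; }
        if (unif_rand() < p) {
          double qb = bearing, qd = dist;
          if (random_dir) {
            qb = unif_rand() * 360.0 - 180.0;
            qd = rd_lo + unif_rand() * (rd_hi - rd_lo);
          }
          int fb = 0;
          phi = draw_bank_angle(bank_bearing, bank_dist, bank_angle,
                                qb, qd, bwin, dwin, buf, &fb);
          fallback_counts[fb]++;
          state = 1; ha = 0.0;
          ev_open = (int)ev_t0.size();
          ev_larva.push_back(a + 1);
          ev_t0.push_back(k * dt);
          ev_t1.push_back(NA_REAL);
          ev_bear.push_back(bearing);
          ev_dist.push_back(dist);
          ev_drawn.push_back(phi);
          ev_realized.push_back(NA_REAL);
        }
      }

      if (state == 1) {
        // head segment pivots about the joint toward the drawn angle
        double dha = (phi >= 0 ? 1.0 : -1.0) * ang_speed_deg_s * dt;
        ha += dha;
        bool done = std::fabs(ha) >= std::fabs(phi);
        if (done) ha = phi; // designated angle assumed exactly
        double hxp = jx + seglen * std::cos((th + ha) * DEG);
        double hyp = jy + seglen * std::sin((th + ha) * DEG);
        if (!done && hxp * hxp + hyp * hyp > arena_r * arena_r)
          done = true; // head rotated into the border
        if (done) {
          th = wrap180(th + ha);
          ev_t1[ev_open] = (k + 1) * dt;
          ev_realized[ev_open] = ha;
          ha = 0.0; state = 0; ev_open = -1;
        }
      } else {
        // run step: advance along the heading; redraw the angular noise
        // while the head segment would move into the border
        double best_th = th, best_r2 = R_PosInf;
        bool moved = false;
        for (int tries = 0; tries < 100; ++tries) {
          double thp = th + (unif_rand() * 2.0 - 1.0) * noise_hw_deg;
          double ux = std::cos(thp * DEG), uy = std::sin(thp * DEG);
          double jxp = jx + run_speed * dt * ux;
          double jyp = jy + run_speed * dt * uy;
          double hxp = jxp + seglen * ux, hyp = jyp + seglen * uy;
          double r2 = hxp * hxp + hyp * hyp;
          if (r2 <= arena_r * arena_r) {
            th = wrap180(thp); jx = jxp; jy = jyp; moved = true;
            break;
          }
          if (r2 < best_r2) { best_r2 = r2; best_th = thp; }
        }
        if (!moved) th = wrap180(best_th); // hold position, keep aligning
      }
    }
    tracks[a] = M;
  }

  DataFrame events = DataFrame::create(
      _["larva"] = ev_larva, _["t_start"] = ev_t0, _["t_end"] = ev_t1,
      _["bearing_init_deg"] = ev_bear, _["distance_init_mm"] = ev_dist,
      _["drawn_angle_deg"] = ev_drawn, _["realized_angle_deg"] = ev_realized);
  return List::create(_["tracks"] = tracks, _["events"] = events,
                      _["fallback_counts"] = fallback_counts,
                      _["n_rate_clipped"] = n_clipped);
}
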