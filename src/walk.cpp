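#include <Rcpp.h>
using namespace Rcpp;

// Goal-directed persistence walk on the room floor.
//
// The walker keeps a current goal landmark, sampled with probability
// proportional to the attraction weights and re-sampled with probability
// switch_prob per frame, so the expected dwell per goal is 1/switch_prob
// frames. Each frame it either rests (position and heading unchanged) or
// takes a step of length step_len along its heading. The heading relaxes
// towards a desired direction blending the previous heading (persistence),
// attraction towards the current goal, a wall-avoidance push that grows
// near the walls, and isotropic directional noise — but it can rotate by at
// most max_turn radians per frame, so body poses assembled around the track
// never jump. Attraction fades linearly inside sat_dist so the walker
// lingers around the goal instead of oscillating over it, and it pauses
// more often there (rest_near_prob). Positions are clamped to `margin`
// metres inside the walls so the whole body stays in the room. Uses R's
// RNG, so results are reproducible under set.seed().
//
// [[Rcpp::export]]
List walk_core(int n, NumericVector start, double step_len,
               double persistence, double rest_prob_frame,
               NumericMatrix landmarks, NumericVector weights,
               double dir_noise_sd, NumericVector floor_rect, double margin,
               double sat_dist, double switch_prob, double rest_near_prob,
               double max_turn) {
  const double avoid_dist = 0.4;   // wall-avoidance range beyond the margin
  const double avoid_gain = 1.5;   // strength of the inward push
  NumericMatrix pos(n, 2);
  NumericMatrix head(n, 2);
  double xmin = floor_rect[0] + margin, xmax = floor_rect[1] - margin;
  double ymin = floor_rect[2] + margin, ymax = floor_rect[3] - margin;
  double px = start[0], py = start[1];
  double ang = unif_rand() * 2.0 * M_PI;
  double hx = cos(ang), hy = sin(ang);
  int nl = landmarks.nrow();
  double wsum = 0.0;
  for (int k = 0; k < nl; ++k) wsum += weights[k];

  int goal = -1;
  for (int t = 0; t < n; ++t) {
    if (wsum > 0.0 && (goal < 0 || unif_rand() < switch_prob)) {
      double u = unif_rand() * wsum, acc = 0.0;
      for (int k = 0; k < nl; ++k) {
        acc += weights[k];
        if (u <= acc) { goal = k; break; }
      }
    }
    // near the goal the walker pauses often (sniffing/standing), so
    // occupancy accumulates at the landmark rather than in transit
    bool near_goal = false;
    double ax = 0.0, ay = 0.0;
    if (goal >= 0) {
      double gx = landmarks(goal, 0) - px, gy = landmarks(goal, 1) - py;
      double d = sqrt(gx * gx + gy * gy);
      near_goal = d < sat_dist;
      if (d > 1e-12) {
        double fade = near_goal ? d / sat_dist : 1.0;
        ax = fade * gx / d;
        ay = fade * gy / d;
      }
    }
    double p_rest = near_goal && rest_near_prob > rest_prob_frame
                        ? rest_near_prob : rest_prob_frame;
    bool resting = unif_rand() < p_rest;
    if (!resting) {
      double dx = persistence * hx + (1.0 - persistence) * ax +
                  dir_noise_sd * norm_rand();
      double dy = persistence * hy + (1.0 - persistence) * ay +
                  dir_noise_sd * norm_rand();
      if (px - xmin < avoid_dist) dx += avoid_gain * (1.0 - (px - xmin) / avoid_dist);
      if (xmax - px < avoid_dist) dx -= avoid_gain * (1.0 - (xmax - px) / avoid_dist);
      if (py - ymin < avoid_dist) dy += avoid_gain * (1.0 - (py - ymin) / avoid_dist);
      if (ymax - py < avoid_dist) dy -= avoid_gain * (1.0 - (ymax - py) / avoid_dist);
      double dn = sqrt(dx * dx + dy * dy);
      if (dn > 1e-12) {
        dx /= dn; dy /= dn;
        // rotate the heading towards the desired direction, rate-limited
        double turn = atan2(hx * dy - hy * dx, hx * dx + hy * dy);
        if (turn > max_turn) turn = max_turn;
        if (turn < -max_turn) turn = -max_turn;
        double c = cos(turn), s = sin(turn);
        double nx = c * hx - s * hy, ny = s * hx + c * hy;
        hx = nx; hy = ny;
      }
      px += step_len * hx;
      py += step_len * hy;
      if (px < xmin) px = xmin;
      if (px > xmax) px = xmax;
      if (py < ymin) py = ymin;
      if (py > ymax) py = ymax;
    }
    pos(t, 0) = px;
    pos(t, 1) = py;
    head(t, 0) = hx;
    head(t, 1) = hy;
  }
  return List::create(_["pos"] = pos, _["heading"] = head);
}
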