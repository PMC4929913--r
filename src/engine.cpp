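#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fast trial engine. Mirrors the pure-R reference engine (R/engine_r.R)
// draw-for-draw on R's RNG stream; any change to draw order here must be
// matched there (equivalence is asserted by tests).
//
// Draw conventions:
//  - index among k options: one uniform, floor(u*k) clamped to k-1;
//  - random cardinal step: one draw, order N, E, S, W;
//  - selection tie-break draw only when >= 2 candidates tie exactly;
//  - random-choice selection always consumes one draw;
//  - rule-switch coin only on a scene match and switch_prob > 0;
//  - spatial-memory return coin only when eligible sites exist and prob > 0.
//
// model: 0 rule_change, 1 fixed_exploitation, 2 fixed_exploration,
//        3 random_choice, 4 spatial_memory.
// rule codes in output: 1 exploitation, 2 exploration, 3 random, 4 return.

static inline int draw_index(int k) {
  int j = (int)(unif_rand() * k);
  if (j >= k) j = k - 1;
  return j;
}

static inline double bounded(double v, double upper, bool reflect) {
  if (reflect) {
    if (v < 0) return -v;
    if (v > upper) return 2 * upper - v;
    return v;
  }
  if (v < 0) return 0;
  if (v > upper) return upper;
  return v;
}

// [[Rcpp::export]]
List sim_engine_cpp(NumericVector sx, NumericVector sy, IntegerVector sid,
                    double field_width, double field_height,
                    double visual_radius, double step_size, int n_steps,
                    double start_x, double start_y, int model,
                    int theta, double switch_prob,
                    int theta_reference, int theta_work, double prob,
                    int n_locations, bool reflect) {
  const int n = sx.size();
  const double r2 = visual_radius * visual_radius;

  double x = start_x, y = start_y;
  int rule = (model == 2) ? 2 : 1;            // 1 exploitation, 2 exploration
  int mem_sum = -1, mem_step = -1;            // scene memory (-1 = empty)
  int n_switch = 0;

  NumericMatrix pos(n_steps + 1, 2);
  IntegerVector codes(n_steps + 1);
  std::vector<int> ev_step, ev_site;
  ev_step.reserve(n_steps);
  ev_site.reserve(n_steps);

  std::vector<int> ms_idx, ms_last;           // spatial memory: site index, last visit
  std::vector<int> cand, tied, elig;
  std::vector<double> cd2;
  cand.reserve(64); tied.reserve(64); cd2.reserve(64);

  pos(0, 0) = x; pos(0, 1) = y;
  codes[0] = (model == 3) ? 3 : rule;

  for (int t = 1; t <= n_steps; ++t) {
    bool moved = false;
    int code = 0;

    if (model == 4) {
      // forget entries beyond the reference-memory horizon (order preserved)
      size_t m = 0;
      for (size_t j = 0; j < ms_idx.size(); ++j) {
        if (t - ms_last[j] <= theta_reference) {
          ms_idx[m] = ms_idx[j]; ms_last[m] = ms_last[j]; ++m;
        }
      }
      ms_idx.resize(m); ms_last.resize(m);
      elig.clear();
      for (size_t j = 0; j < ms_idx.size(); ++j)
        if (t - ms_last[j] > theta_work) elig.push_back((int)j);
      if (!elig.empty() && prob > 0 && unif_rand() < prob) {
        int j = (elig.size() > 1) ? elig[draw_index((int)elig.size())] : elig[0];
        int i = ms_idx[j];
        x = sx[i]; y = sy[i];
        ms_last[j] = t;
        ev_step.push_back(t);
        ev_site.push_back(sid[i]);
        code = 4;
        moved = true;
      }
    }

    if (!moved) {
      cand.clear(); cd2.clear();
      for (int i = 0; i < n; ++i) {
        double dx = sx[i] - x, dy = sy[i] - y;
        double d2 = dx * dx + dy * dy;
        if (d2 <= r2 && d2 > 0) { cand.push_back(i); cd2.push_back(d2); }
      }
      int nl = (int)cand.size();
      if (nl == 0) {
        int dir = draw_index(4);
        if (dir == 0) y += step_size;
        else if (dir == 1) x += step_size;
        else if (dir == 2) y -= step_size;
        else x -= step_size;
        x = bounded(x, field_width, reflect);
        y = bounded(y, field_height, reflect);
        code = (model == 3) ? 3 : rule;
      } else {
        if (model == 0) {
          if (mem_sum < 0 || (t - mem_step) > theta) {
            mem_sum = nl; mem_step = t;       // store; no comparison this step
          } else if (nl == mem_sum && switch_prob > 0 &&
                     unif_rand() < switch_prob) {
            rule = 3 - rule;
            ++n_switch;
          }
        }
        int pick;
        if (model == 3) {
          pick = draw_index(nl);
          code = 3;
        } else {
          bool nearest = (rule == 1);
          double best = cd2[0];
          for (int j = 1; j < nl; ++j) {
            if (nearest ? (cd2[j] < best) : (cd2[j] > best)) best = cd2[j];
          }
          tied.clear();
          for (int j = 0; j < nl; ++j) if (cd2[j] == best) tied.push_back(j);
          pick = (tied.size() > 1) ? tied[draw_index((int)tied.size())] : tied[0];
          code = rule;
        }
        int i = cand[pick];
        x = sx[i]; y = sy[i];
        ev_step.push_back(t);
        ev_site.push_back(sid[i]);
        if (model == 4) {
          int k = -1;
          for (size_t j = 0; j < ms_idx.size(); ++j)
            if (ms_idx[j] == i) { k = (int)j; break; }
          if (k >= 0) {
            ms_last[k] = t;
          } else {
            ms_idx.push_back(i);
            ms_last.push_back(t);
            if ((int)ms_idx.size() > n_locations) {
              size_t drop = 0;
              for (size_t j = 1; j < ms_last.size(); ++j)
                if (ms_last[j] < ms_last[drop]) drop = j;
              ms_idx.erase(ms_idx.begin() + drop);
              ms_last.erase(ms_last.begin() + drop);
            }
          }
        }
      }
    }

    pos(t, 0) = x; pos(t, 1) = y;
    codes[t] = code;
  }

  return List::create(
    _["positions"] = pos,
    _["rule_codes"] = codes,
    _["event_steps"] = IntegerVector(ev_step.begin(), ev_step.end()),
    _["event_sites"] = IntegerVector(ev_site.begin(), ev_site.end()),
    _["n_rule_switches"] = n_switch,
    _["final_rule"] = rule);
}
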