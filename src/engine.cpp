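#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Event-driven engine for discrete activity networks.
//
// Semantics: each unclamped node v with net rate rho != 0 (and not pinned
// against a bound in the direction of rho) owns a timeout
//     t_v = t_last(v) + (1/levels_v) / |rho_v|
// where t_last(v) is the time of v's previous +-1 update (its clock reset).
// The earliest timeout fires (ties broken by lowest node index), the node
// moves by sign(rho_v), and every timeout is recomputed from the new state.
// A timeout already in the past fires immediately at the current time.
//
// Attractor detection: quiescence (no schedulable node) is a fixed point.
// A candidate limit cycle opens when the integer activity vector recurs; it
// is confirmed only after a full extra period replays with identical states
// and event spacings, which guards against transient coincidences of the
// activity vector at different clock phases.

static void compute_rates(int n_edges,
                          const std::vector<int>& a,
                          const IntegerVector& levels,
                          const IntegerVector& reg1,
                          const IntegerVector& reg2,
                          const IntegerVector& target,
                          const IntegerVector& sign,
                          const IntegerVector& scen,
                          const NumericVector& k,
                          std::vector<double>& rho) {
  std::fill(rho.begin(), rho.end(), 0.0);
  for (int e = 0; e < n_edges; ++e) {
    const int tg = target[e];
    const double ar = (double)a[reg1[e]] / (double)levels[reg1[e]];
    double r;
    if (scen[e] == 1) {
      r = k[e] * ar;
    } else if (scen[e] == 2) {
      const double at = (double)a[tg] / (double)levels[tg];
      r = k[e] * ar * (sign[e] > 0 ? (1.0 - at) : at);
    } else {
      r = k[e] * ar * ((double)a[reg2[e]] / (double)levels[reg2[e]]);
    }
    rho[tg] += (double)sign[e] * r;
  }
}

static std::string state_key(const std::vector<int>& a) {
  std::string s;
  s.reserve(a.size() * 4);
  for (size_t i = 0; i < a.size(); ++i) {
    s += std::to_string(a[i]);
    s += ',';
  }
  return s;
}

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(IntegerVector levels,
                IntegerVector init,
                LogicalVector clamped,
                IntegerVector reg1,
                IntegerVector reg2,
                IntegerVector target,
                IntegerVector sign,
                IntegerVector scenario,
                NumericVector k,
                int max_events,
                bool record,
                int intervene_after,
                int intervene_node,
                int intervene_level) {
  const int n = levels.size();
  const int m = reg1.size();
  std::vector<int> a(n);
  std::vector<bool> clamp(n);
  for (int i = 0; i < n; ++i) { a[i] = init[i]; clamp[i] = clamped[i]; }

  std::vector<double> t_last(n, 0.0), rho(n, 0.0);
  double t = 0.0;
  int n_events = 0;
  bool intervened = (intervene_after < 0);
  int intervention_event = -1;

  // trajectory record
  std::vector<double> ev_time;
  std::vector<int> ev_node, ev_level;

  // state history for cycle detection
  std::vector<std::string> keys;
  std::vector<double> entry;
  std::vector< std::vector<int> > hist;
  std::unordered_map<std::string, int> seen;
  int cand = -1, period = 0, matched = 0;

  keys.push_back(state_key(a));
  entry.push_back(0.0);
  hist.push_back(a);
  seen[keys[0]] = 0;

  std::string kind = "unresolved";
  int cycle_start = -1;
  int events_to_reach = -1;

  auto apply_intervention = [&]() {
    intervened = true;
    intervention_event = n_events;
    clamp[intervene_node] = true;
    if (a[intervene_node] != intervene_level) {
      a[intervene_node] = intervene_level;
      ev_time.push_back(t);
      ev_node.push_back(intervene_node);
      ev_level.push_back(intervene_level);
    }
    // dynamics changed: restart cycle detection from here
    seen.clear();
    cand = -1;
    std::string kk = state_key(a);
    keys.push_back(kk);
    entry.push_back(t);
    hist.push_back(a);
    seen[kk] = (int)keys.size() - 1;
  };

  while (n_events < max_events) {
    if (!intervened && n_events >= intervene_after) apply_intervention();

    compute_rates(m, a, levels, reg1, reg2, target, sign, scenario, k, rho);

    int best = -1;
    double best_t = 0.0;
    for (int v = 0; v < n; ++v) {
      if (clamp[v]) continue;
      const double r = rho[v];
      if (r == 0.0) continue;
      if (r > 0.0 && a[v] >= levels[v]) continue;
      if (r < 0.0 && a[v] <= 0) continue;
      double tv = t_last[v] + (1.0 / (double)levels[v]) / std::fabs(r);
      if (tv < t) tv = t;
      if (best < 0 || tv < best_t) { best = v; best_t = tv; }
    }

    if (best < 0) {                      // quiescent
      if (!intervened) { apply_intervention(); continue; }
      kind = "fixed_point";
      events_to_reach = n_events;
      break;
    }

    // fire the event
    t = best_t;
    a[best] += (rho[best] > 0.0 ? 1 : -1);
    t_last[best] = t;
    ++n_events;
    ev_time.push_back(t);
    ev_node.push_back(best);
    ev_level.push_back(a[best]);

    std::string kk = state_key(a);
    const int idx = (int)keys.size();
    keys.push_back(kk);
    entry.push_back(t);
    hist.push_back(a);

    bool confirmed = false;
    if (cand >= 0) {
      const int ref = cand + 1 + matched;
      const double dur_new = entry[idx] - entry[idx - 1];
      const double dur_old = entry[ref] - entry[ref - 1];
      if (keys[idx] == keys[ref] &&
          std::fabs(dur_new - dur_old) <= 1e-9 * (1.0 + std::fabs(dur_old))) {
        ++matched;
        if (matched == period) confirmed = true;
      } else {
        cand = -1;
      }
    }
    if (confirmed) {
      kind = "limit_cycle";
      cycle_start = cand;
      events_to_reach = n_events - 2 * period;
      break;
    }
    if (cand < 0) {
      auto it = seen.find(kk);
      if (it != seen.end()) {
        cand = it->second;
        period = idx - cand;
        matched = 0;
      }
    }
    seen[kk] = idx;
  }

  // reported levels
  NumericVector reported(n);
  int out_period = 1;
  if (kind == "limit_cycle") {
    out_period = period;
    double tot = 0.0;
    std::vector<double> acc(n, 0.0);
    for (int j = 0; j < period; ++j) {
      const double d = entry[cycle_start + j + 1] - entry[cycle_start + j];
      tot += d;
      for (int v = 0; v < n; ++v) acc[v] += d * (double)hist[cycle_start + j][v];
    }
    if (tot <= 0.0) {                     // degenerate: fall back to plain mean
      for (int v = 0; v < n; ++v) {
        double s = 0.0;
        for (int j = 0; j < period; ++j) s += hist[cycle_start + j][v];
        reported[v] = s / period;
      }
    } else {
      for (int v = 0; v < n; ++v) reported[v] = acc[v] / tot;
    }
  } else {
    for (int v = 0; v < n; ++v) reported[v] = (double)a[v];
    if (kind == "unresolved") events_to_reach = n_events;
  }

  IntegerVector final_levels(n);
  for (int v = 0; v < n; ++v) final_levels[v] = a[v];

  List traj;
  if (record) {
    traj = List::create(_["time"] = wrap(ev_time),
                        _["node"] = wrap(ev_node),
                        _["level"] = wrap(ev_level));
  }

  return List::create(_["kind"] = kind,
                      _["final"] = final_levels,
                      _["reported_raw"] = reported,
                      _["period"] = out_period,
                      _["n_events"] = n_events,
                      _["events_to_reach"] = events_to_reach,
                      _["time"] = t,
                      _["intervention_event"] = intervention_event,
                      _["trajectory"] = traj);
}

// Independent continuous oracle: explicit Euler on the normalised rate
// equations da/dt = net_rate(a), a in [0,1]^n, with projection onto the box.
// Shares no code with the event-driven engine above (rates are recomputed
// here from scratch) so the two can check each other.

// [[Rcpp::export(name = ".ode_engine")]]
List ode_engine(IntegerVector levels,
                NumericVector init01,
                LogicalVector clamped,
                IntegerVector reg1,
                IntegerVector reg2,
                IntegerVector target,
                IntegerVector sign,
                IntegerVector scenario,
                NumericVector k,
                double dt,
                double t_max,
                double tol) {
  const int n = init01.size();
  const int m = reg1.size();
  std::vector<double> a(n), da(n);
  for (int i = 0; i < n; ++i) a[i] = init01[i];

  double t = 0.0;
  bool converged = false;
  while (t < t_max) {
    for (int v = 0; v < n; ++v) da[v] = 0.0;
    for (int e = 0; e < m; ++e) {
      const int tg = target[e];
      double r = k[e] * a[reg1[e]];
      if (scenario[e] == 2) r *= (sign[e] > 0 ? (1.0 - a[tg]) : a[tg]);
      else if (scenario[e] == 3) r *= a[reg2[e]];
      da[tg] += (double)sign[e] * r;
    }
    double resid = 0.0;
    for (int v = 0; v < n; ++v) {
      if (clamped[v]) { da[v] = 0.0; continue; }
      if (a[v] >= 1.0 && da[v] > 0.0) da[v] = 0.0;
      if (a[v] <= 0.0 && da[v] < 0.0) da[v] = 0.0;
      if (std::fabs(da[v]) > resid) resid = std::fabs(da[v]);
    }
    if (resid < tol) { converged = true; break; }
    for (int v = 0; v < n; ++v) {
      a[v] += dt * da[v];
      if (a[v] > 1.0) a[v] = 1.0;
      if (a[v] < 0.0) a[v] = 0.0;
    }
    t += dt;
  }
  return List::create(_["fixed_point"] = wrap(a),
                      _["converged"] = converged,
                      _["t"] = t);
}
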