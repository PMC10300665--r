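// Compiled simulation core. Mirrors the R reference implementation
// (step_agent) exactly in the deterministic regime; uses R's RNG (via
// RNGScope) so replicates are reproducible from set.seed().
//
// Conventions: roles and agents are 0-based here, -1 is the "none"
// sentinel for occupation/performing and for "no favoured type".
// status codes: 0 untried, 1 tried-and-abandoned, 2 continuing.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Engine {
  int n, R;
  IntegerVector type, created_at, occupation, performing;
  NumericMatrix ability;
  IntegerMatrix status;
  IntegerVector favoured;
  NumericVector offset;

  // config
  double death_rate, theta, tie_tol, price_scale, mu, sigma, q, s, delta;
  int E, model_id, vanish_step;
  bool perfect;

  // derived state
  std::vector<int> occ;               // living performers per role
  std::vector<int> cont0, cont1, aban0, aban1;  // social counts
  std::vector<int> tried_n;           // distinct roles tried per agent
  std::vector<double> bias;           // cached s*sigma*(A0-A1) per role
  std::vector<bool> dirty;
  std::vector<double> vals;           // scratch per-role values
  double price_base;
  double lq, l1m2q, lp, lm, l5;       // log prior/likelihood constants

  void init_derived() {
    occ.assign(R, 0);
    cont0.assign(R, 0); cont1.assign(R, 0);
    aban0.assign(R, 0); aban1.assign(R, 0);
    tried_n.assign(n, 0);
    bias.assign(R, 0.0);
    dirty.assign(R, true);
    vals.assign(R, 0.0);
    for (int i = 0; i < n; ++i) {
      if (performing[i] >= 0) occ[performing[i]]++;
      for (int r = 0; r < R; ++r) {
        int st = status(i, r);
        if (st != 0) tried_n[i]++;
        if (st == 2) { (type[i] == 0 ? cont0 : cont1)[r]++; }
        else if (st == 1) { (type[i] == 0 ? aban0 : aban1)[r]++; }
      }
    }
    price_base = price_scale * ((double)n / (double)R);
    if (q > 0) {
      lq = std::log(q); l1m2q = std::log1p(-2.0 * q);
      lp = std::log(0.5 + delta); lm = std::log(0.5 - delta);
      l5 = std::log(0.5);
    }
  }

  double price(int r) const { return price_base / (occ[r] + 1.0); }

  // posterior bias term s*sigma*(A0 - A1) for one role, cached
  double role_bias(int r) {
    if (q <= 0) return 0.0;
    if (dirty[r]) {
      // aggregated exponents, matching the R-level posterior exactly
      double kp = cont0[r] + aban1[r];
      double km = aban0[r] + cont1[r];
      double ll0 = kp * lp + km * lm;
      double ll1 = km * lp + kp * lm;
      double lln = (kp + km) * l5;
      double w0 = lq + ll0, w1 = lq + ll1, wn = l1m2q + lln;
      double m = std::max(w0, std::max(w1, wn));
      double e0 = std::exp(w0 - m), e1 = std::exp(w1 - m), en = std::exp(wn - m);
      bias[r] = s * sigma * (e0 - e1) / (e0 + e1 + en);
      dirty[r] = false;
    }
    return bias[r];
  }

  // value agent i assigns to role r at current prices/counts
  double role_value(int i, int r) {
    if (perfect || status(i, r) != 0) return ability(i, r) * price(r);
    double b = role_bias(r);
    double shift = (type[i] == 0) ? b : -b;
    return price(r) * (mu + shift);
  }

  // max expected payoff over untried roles; if none, max known value over
  // roles other than exclude_role
  double search_value(int i, int exclude_role) {
    double best = R_NegInf;
    bool any_untried = false;
    for (int r = 0; r < R; ++r) {
      if (status(i, r) == 0) {
        any_untried = true;
        double v = role_value(i, r);
        if (v > best) best = v;
      }
    }
    if (any_untried) return best;
    for (int r = 0; r < R; ++r) {
      if (r == exclude_role) continue;
      double v = ability(i, r) * price(r);
      if (v > best) best = v;
    }
    return best;
  }

  void mark_abandoned(int i, int r) {
    status(i, r) = 1;
    (type[i] == 0 ? aban0 : aban1)[r]++;
    dirty[r] = true;
  }

  void act(int i, int t) {
    int tp = type[i];
    if (death_rate > 0 && unif_rand() < death_rate) {
      if (performing[i] >= 0) occ[performing[i]]--;
      for (int r = 0; r < R; ++r) {
        int st = status(i, r);
        if (st == 2) { (tp == 0 ? cont0 : cont1)[r]--; dirty[r] = true; }
        else if (st == 1) { (tp == 0 ? aban0 : aban1)[r]--; dirty[r] = true; }
        status(i, r) = 0;
      }
      occupation[i] = -1;
      performing[i] = -1;
      created_at[i] = t;
      tried_n[i] = 0;
      bool vanished = (model_id >= 4) && (t > vanish_step);
      for (int r = 0; r < R; ++r) {
        double a = norm_rand() * sigma + mu;
        if (!vanished && favoured[r] >= 0) {
          a += (favoured[r] == tp) ? offset[r] : -offset[r];
        }
        ability(i, r) = a;
      }
      return;
    }
    if (performing[i] >= 0) { occ[performing[i]]--; performing[i] = -1; }

    int c = occupation[i];
    if (c >= 0) {
      double cur = ability(i, c) * price(c);
      double sv = search_value(i, c);
      if (cur < theta * sv) {
        status(i, c) = 1;
        (tp == 0 ? cont0 : cont1)[c]--;
        (tp == 0 ? aban0 : aban1)[c]++;
        dirty[c] = true;
        occupation[i] = -1;
      } else {
        performing[i] = c;
        occ[c]++;
        return;
      }
    }

    // choose the best candidate role
    bool forced = tried_n[i] < E;
    double best = R_NegInf;
    for (int r = 0; r < R; ++r) {
      double v;
      if (forced && status(i, r) != 0) v = R_NegInf;
      else v = role_value(i, r);
      vals[r] = v;
      if (v > best) best = v;
    }
    if (!R_FINITE(best)) stop("no candidate roles available");
    double cut = best - tie_tol * std::fabs(best);
    int k = 0;
    for (int r = 0; r < R; ++r) if (vals[r] >= cut) ++k;
    int chosen = -1;
    if (k == 1) {
      for (int r = 0; r < R; ++r) if (vals[r] >= cut) { chosen = r; break; }
    } else {
      int pick = (int)(unif_rand() * k);
      if (pick >= k) pick = k - 1;
      for (int r = 0; r < R; ++r) {
        if (vals[r] >= cut && pick-- == 0) { chosen = r; break; }
      }
    }

    double payoff = ability(i, chosen) * price(chosen);
    if (status(i, chosen) == 0) {
      mark_abandoned(i, chosen);  // provisional: tried, not (yet) adopted
      tried_n[i]++;
    }
    double threshold = search_value(i, chosen);
    if (payoff > threshold && tried_n[i] >= E) {
      status(i, chosen) = 2;
      (tp == 0 ? aban0 : aban1)[chosen]--;
      (tp == 0 ? cont0 : cont1)[chosen]++;
      dirty[chosen] = true;
      occupation[i] = chosen;
    }
    performing[i] = chosen;
    occ[chosen]++;
  }

  double segregation() const {
    std::vector<int> n0(R, 0), n1(R, 0);
    for (int i = 0; i < n; ++i) {
      if (performing[i] >= 0) (type[i] == 0 ? n0 : n1)[performing[i]]++;
    }
    double num = 0.0, den = 0.0;
    for (int r = 0; r < R; ++r) {
      double tot = n0[r] + n1[r];
      if (tot > 0) {
        num += tot * std::fabs(n0[r] / tot - 0.5);
        den += tot;
      }
    }
    if (den <= 0) return NA_REAL;
    return 2.0 * num / den;
  }
};

}  // namespace

// [[Rcpp::export]]
List sim_steps_cpp(IntegerVector type, IntegerVector created_at,
                   NumericMatrix ability, IntegerMatrix status,
                   IntegerVector occupation, IntegerVector performing,
                   IntegerVector favoured, NumericVector offset,
                   List cfg, int n_steps, int t0,
                   Nullable<IntegerVector> first_order) {
  Engine e;
  e.n = type.size();
  e.R = offset.size();
  e.type = type;
  e.created_at = clone(created_at);
  e.ability = clone(ability);
  e.status = clone(status);
  e.occupation = clone(occupation);
  e.performing = clone(performing);
  e.favoured = favoured;
  e.offset = offset;
  e.death_rate = as<double>(cfg["death_rate"]);
  e.theta = as<double>(cfg["theta"]);
  e.E = as<int>(cfg["forced_min_roles"]);
  e.perfect = as<bool>(cfg["perfect"]);
  e.q = as<double>(cfg["q"]);
  e.s = as<double>(cfg["s"]);
  e.delta = as<double>(cfg["delta"]);
  e.mu = as<double>(cfg["mu"]);
  e.sigma = as<double>(cfg["sigma"]);
  e.tie_tol = as<double>(cfg["tie_tol"]);
  e.price_scale = as<double>(cfg["price_scale"]);
  e.model_id = as<int>(cfg["model_id"]);
  e.vanish_step = as<int>(cfg["vanish_step"]);
  e.init_derived();

  NumericVector seg(n_steps);
  std::vector<int> order(e.n);
  for (int i = 0; i < e.n; ++i) order[i] = i;

  for (int s_i = 0; s_i < n_steps; ++s_i) {
    int t = t0 + s_i + 1;
    if (s_i == 0 && first_order.isNotNull()) {
      IntegerVector fo(first_order);
      for (int i = 0; i < e.n; ++i) order[i] = fo[i];
    } else {
      // Fisher-Yates permutation from R's RNG
      for (int i = 0; i < e.n; ++i) order[i] = i;
      for (int i = e.n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
    }
    for (int i = 0; i < e.n; ++i) e.act(order[i], t);
    seg[s_i] = e.segregation();
  }

  return List::create(
    _["segregation"] = seg,
    _["ability"] = e.ability,
    _["status"] = e.status,
    _["occupation"] = e.occupation,
    _["performing"] = e.performing,
    _["created_at"] = e.created_at
  );
}
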