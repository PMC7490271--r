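#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int NAA = 20;

// Mutation-selection fixation-rate multiplier g(S) = S / (1 - exp(-S)),
// continuous at S = 0 with g(0) = 1.  Stable for |S| up to ~1e4.
static double fix_factor(double S) {
  double a = std::fabs(S);
  if (a < 1e-5) return 1.0 + S / 2.0 + S * S / 12.0;
  if (S > 0.0) return S / (1.0 - std::exp(-S));
  double es = std::exp(S);            // S < 0: S e^S / (e^S - 1)
  return S * es / (es - 1.0);
}

// [[Rcpp::export]]
NumericVector cpp_fix_factor(NumericVector S) {
  int n = S.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fix_factor(S[i]);
  return out;
}

// Per-target substitution rates away from `res` given log-fitness vector f.
// rate[j] = (mu/19) * g(f[j] - f[res]); rate[res] = 0.
static double sub_rates(const std::vector<double>& f, int res, double mu,
                        std::vector<double>& rate) {
  double tot = 0.0, base = mu / (NAA - 1), fr = f[res];
  for (int j = 0; j < NAA; ++j) {
    if (j == res) { rate[j] = 0.0; continue; }
    double r = base * fix_factor(f[j] - fr);
    rate[j] = r;
    tot += r;
  }
  return tot;
}

static int sample_target(const std::vector<double>& rate, double tot) {
  double u = unif_rand() * tot, acc = 0.0;
  for (int j = 0; j < NAA; ++j) {
    acc += rate[j];
    if (u <= acc) return j;
  }
  return NAA - 1; // numeric guard
}

struct EventLog {
  std::vector<int> edge;
  std::vector<double> offset;
  std::vector<int> from;
  std::vector<int> to;
  std::vector<int> type;                   // 0 = substitution, 1 = landscape change
  std::vector<std::vector<double> > lands; // new landscape for type-1 events
  void sub(int e, double t, int a, int b) {
    edge.push_back(e); offset.push_back(t); from.push_back(a); to.push_back(b);
    type.push_back(0);
  }
  void land(int e, double t, int res, const std::vector<double>& f) {
    edge.push_back(e); offset.push_back(t); from.push_back(res); to.push_back(res);
    type.push_back(1); lands.push_back(f);
  }
};

// shape codes: 0 flat, 1 rugged, 2 gamma
static void redraw_landscape(std::vector<double>& f, int shape, double alpha) {
  if (shape == 2) {
    for (int j = 0; j < NAA; ++j) f[j] = R::rgamma(alpha, 1.0 / alpha);
  } else {
    // reshuffle: uniform random permutation of the current values
    for (int j = NAA - 1; j > 0; --j) {
      int i = (int)std::floor(unif_rand() * (j + 1));
      if (i > j) i = j;
      double tmp = f[j]; f[j] = f[i]; f[i] = tmp;
    }
  }
}

// Evolve one lineage along a branch of length L; res and f are updated in
// place.  mode: 0 static, 1 random (Poisson landscape changes at rate
// lambda), 2 allele_linear (resident log fitness drifts at rate k, fixed
// steps of dt).  Events, if log != NULL, are tagged with edge id `eid`.
static void evolve_branch(int& res, std::vector<double>& f, double L,
                          int mode, double lambda, double k, double dt,
                          double mu, int shape, double alpha,
                          int eid, EventLog* log,
                          std::vector<double>& rate) {
  if (L <= 0.0) return;
  if (mode == 2 && k != 0.0) {
    double t = 0.0;
    while (t < L - 1e-12) {
      double step = dt < (L - t) ? dt : (L - t);
      double tot = sub_rates(f, res, mu, rate);
      if (tot > 0.0 && unif_rand() < -std::expm1(-tot * step)) {
        int j = sample_target(rate, tot);
        if (log) log->sub(eid, t + unif_rand() * step, res, j);
        res = j; // replaced allele's fitness freezes; new one drifts below
      }
      f[res] += k * step;
      t += step;
    }
    return;
  }
  // static and random modes: piecewise-constant rates, exact jump times
  double t = 0.0;
  for (;;) {
    double tot = sub_rates(f, res, mu, rate);
    double all = tot + (mode == 1 ? lambda : 0.0);
    if (all <= 0.0) return;
    t += exp_rand() / all;
    if (t >= L) return;
    if (mode == 1 && unif_rand() < lambda / all) {
      redraw_landscape(f, shape, alpha);
      if (log) log->land(eid, t, res, f);
    } else {
      int j = sample_target(rate, tot);
      if (log) log->sub(eid, t, res, j);
      res = j;
    }
  }
}

static int draw_stationary(const std::vector<double>& f) {
  double m = f[0];
  for (int j = 1; j < NAA; ++j) if (f[j] > m) m = f[j];
  double z = 0.0;
  std::vector<double> w(NAA);
  for (int j = 0; j < NAA; ++j) { w[j] = std::exp(f[j] - m); z += w[j]; }
  double u = unif_rand() * z, acc = 0.0;
  for (int j = 0; j < NAA; ++j) { acc += w[j]; if (u <= acc) return j; }
  return NAA - 1;
}

// Simulate one site along a rooted tree.  Edges must be listed with every
// parent appearing as a child earlier (preorder); node ids are 0-based and
// the root carries the initial landscape logf0.  root_state = -1 draws the
// root allele from the stationary distribution pi propto exp(logf0).
// [[Rcpp::export]]
List cpp_sim_site(IntegerVector parent, IntegerVector child,
                  NumericVector elen, int nnodes, int root,
                  NumericVector logf0, int shape, double alpha,
                  int mode, double lambda, double k, double dt, double mu,
                  int root_state) {
  int ne = parent.size();
  std::vector<int> state(nnodes, -1);
  std::vector<std::vector<double> > land(nnodes);
  std::vector<double> f0(logf0.begin(), logf0.end());
  std::vector<double> rate(NAA);

  state[root] = (root_state >= 0) ? root_state : draw_stationary(f0);
  land[root] = f0;

  EventLog log;
  for (int e = 0; e < ne; ++e) {
    int p = parent[e], c = child[e];
    int res = state[p];
    std::vector<double> f = land[p];
    evolve_branch(res, f, elen[e], mode, lambda, k, dt, mu, shape, alpha,
                  e, &log, rate);
    state[c] = res;
    land[c] = f;
  }

  int nev = log.edge.size();
  NumericMatrix lmat(log.lands.size(), NAA);
  for (size_t i = 0; i < log.lands.size(); ++i)
    for (int j = 0; j < NAA; ++j) lmat(i, j) = log.lands[i][j];
  return List::create(
    _["state"] = IntegerVector(state.begin(), state.end()),
    _["edge"] = IntegerVector(log.edge.begin(), log.edge.end()),
    _["offset"] = NumericVector(log.offset.begin(), log.offset.end()),
    _["from"] = IntegerVector(log.from.begin(), log.from.end()),
    _["to"] = IntegerVector(log.to.begin(), log.to.end()),
    _["type"] = IntegerVector(log.type.begin(), log.type.end()),
    _["n_events"] = nev,
    _["landscapes"] = lmat);
}

// Batch simulator over substitution-subtree shapes for ABC.
// `shapes` is a list; each element is a list with integer vectors `parent`
// and `child` (0-based local node ids, root = 0, preorder), numeric `len`
// and `age` (age of each branch = distance from the gain node to the
// branch's parent), and integer `count`.  Every replicate gains allele B
// (index 0) at the root with all 20 log fitnesses drawn i.i.d. from
// Gamma(alpha, rate = alpha); with probability `fraction` the resident's
// log fitness then drifts at rate k (allele_linear), otherwise the
// landscape is static.  Observed member branches are those reachable from
// the root through nodes still carrying B; each contributes one
// (length, age, s) row with s = 1 if the branch's child no longer carries B.
// [[Rcpp::export]]
NumericMatrix cpp_sim_subtree_stats(List shapes, double alpha, double k,
                                    double fraction, double mu, double dt,
                                    int cap) {
  std::vector<double> out_len, out_age, out_s;
  std::vector<double> rate(NAA);
  int done = 0;
  for (int si = 0; si < shapes.size(); ++si) {
    List sh = shapes[si];
    IntegerVector parent = sh["parent"], child = sh["child"];
    NumericVector len = sh["len"], age = sh["age"];
    int count = as<int>(sh["count"]);
    int ne = parent.size();
    int nn = ne + 1;
    std::vector<int> res(nn);
    std::vector<char> onpath(nn);
    std::vector<std::vector<double> > land(nn);
    for (int r = 0; r < count; ++r) {
      if (done >= cap) break;
      ++done;
      std::vector<double> f(NAA);
      for (int j = 0; j < NAA; ++j) f[j] = R::rgamma(alpha, 1.0 / alpha);
      bool drift = (fraction >= 1.0) || (unif_rand() < fraction);
      int mode = (drift && k != 0.0) ? 2 : 0;
      std::fill(onpath.begin(), onpath.end(), 0);
      onpath[0] = 1;
      res[0] = 0;
      land[0] = f;
      for (int e = 0; e < ne; ++e) {
        int p = parent[e], c = child[e];
        if (!onpath[p]) continue;
        int rs = res[p];
        std::vector<double> fb = land[p];
        evolve_branch(rs, fb, len[e], mode, 0.0, k, dt, mu, 2, alpha,
                      e, 0, rate);
        out_len.push_back(len[e]);
        out_age.push_back(age[e]);
        out_s.push_back(rs == 0 ? 0.0 : 1.0);
        if (rs == 0) { onpath[c] = 1; res[c] = rs; land[c] = fb; }
      }
    }
    if (done >= cap) break;
  }
  int n = out_len.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = out_len[i];
    out(i, 1) = out_age[i];
    out(i, 2) = out_s[i];
  }
  colnames(out) = CharacterVector::create("length", "age", "s");
  return out;
}
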