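// Metropolis-Hastings structure search over discrete (3-state) Bayesian
// networks with a BDeu family score, candidate-parent restriction, and a
// parent-count prior. One chain per call; determinism comes from the
// std::mt19937 seed. States are integers 0..2; missing values are not
// supported here (callers complete-case the matrix).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int R_STATES = 3;

// BDeu marginal likelihood of one family plus -lambda * |parents|
static double family_score(const IntegerMatrix& st, int child,
                           const std::vector<int>& pa,
                           double kappa, double lambda) {
  const int n = st.ncol();
  const int np = (int)pa.size();
  int q = 1;
  for (int i = 0; i < np; ++i) q *= R_STATES;
  std::vector<int> counts((size_t)q * R_STATES, 0);
  for (int s = 0; s < n; ++s) {
    int idx = 0;
    for (int i = 0; i < np; ++i) idx = idx * R_STATES + st(pa[i], s);
    counts[(size_t)idx * R_STATES + st(child, s)]++;
  }
  const double a_j = kappa / q;
  const double a_jk = kappa / (q * (double)R_STATES);
  double sc = -lambda * np;
  for (int j = 0; j < q; ++j) {
    int nj = 0;
    for (int k = 0; k < R_STATES; ++k) nj += counts[(size_t)j * R_STATES + k];
    if (nj == 0) continue;
    sc += lgamma(a_j) - lgamma(a_j + nj);
    for (int k = 0; k < R_STATES; ++k) {
      int c = counts[(size_t)j * R_STATES + k];
      if (c > 0) sc += lgamma(a_jk + c) - lgamma(a_jk);
    }
  }
  return sc;
}

// would adding u -> v close a directed cycle? (is u reachable from v)
static bool creates_cycle(const std::vector<std::vector<int>>& children,
                          int u, int v, int n_nodes) {
  if (u == v) return true;
  std::vector<char> seen(n_nodes, 0);
  std::vector<int> stack{v};
  seen[v] = 1;
  while (!stack.empty()) {
    int x = stack.back(); stack.pop_back();
    if (x == u) return true;
    for (int c : children[x]) if (!seen[c]) { seen[c] = 1; stack.push_back(c); }
  }
  return false;
}

static void drop_val(std::vector<int>& v, int x) {
  v.erase(std::find(v.begin(), v.end(), x));
}

// [[Rcpp::export(name = ".mcmc_chain")]]
List mcmc_chain(IntegerMatrix states, List candidates, int seed, int n_iter,
                int max_parents, double kappa, double lambda,
                double anneal_from) {
  const int G = states.nrow();
  std::vector<std::vector<int>> cand(G);
  std::vector<std::pair<int, int>> pairs;  // (child, candidate parent), 0-based
  for (int j = 0; j < G; ++j) {
    IntegerVector cv = candidates[j];
    for (int k = 0; k < cv.size(); ++k) {
      int p = cv[k] - 1;
      cand[j].push_back(p);
      pairs.push_back({j, p});
    }
  }
  if (pairs.empty()) {
    double sc0 = 0.0;
    std::vector<int> none;
    for (int j = 0; j < G; ++j) sc0 += family_score(states, j, none, kappa, lambda);
    return List::create(_["edges"] = IntegerMatrix(0, 2), _["log_score"] = sc0,
                        _["accepted"] = 0, _["proposed"] = 0);
  }

  std::vector<std::vector<int>> parents(G), children(G);
  std::vector<double> fam(G);
  std::vector<int> none;
  double score = 0.0;
  for (int j = 0; j < G; ++j) {
    fam[j] = family_score(states, j, none, kappa, lambda);
    score += fam[j];
  }
  double best = score;
  std::vector<std::vector<int>> best_parents = parents;

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> pick(0, (int)pairs.size() - 1);

  int accepted = 0;
  for (int it = 0; it < n_iter; ++it) {
    // inverse temperature ramps geometrically from anneal_from to 1
    double beta = (anneal_from >= 1.0) ? 1.0
      : anneal_from * std::pow(1.0 / anneal_from, (double)it / std::max(1, n_iter - 1));
    auto pr = pairs[pick(rng)];
    int v = pr.first, u = pr.second;
    bool has = std::find(parents[v].begin(), parents[v].end(), u) != parents[v].end();
    if (!has) {
      // add u -> v
      if ((int)parents[v].size() >= max_parents) continue;
      if (creates_cycle(children, u, v, G)) continue;
      std::vector<int> np_ = parents[v]; np_.push_back(u);
      double f_new = family_score(states, v, np_, kappa, lambda);
      double delta = f_new - fam[v];
      if (delta >= 0 || unif(rng) < std::exp(beta * delta)) {
        parents[v] = np_; children[u].push_back(v);
        fam[v] = f_new; score += delta; ++accepted;
      }
    } else if (unif(rng) < 0.5) {
      // delete u -> v
      std::vector<int> np_ = parents[v]; drop_val(np_, u);
      double f_new = family_score(states, v, np_, kappa, lambda);
      double delta = f_new - fam[v];
      if (delta >= 0 || unif(rng) < std::exp(beta * delta)) {
        parents[v] = np_; drop_val(children[u], v);
        fam[v] = f_new; score += delta; ++accepted;
      }
    } else {
      // reverse u -> v  (requires v to be a candidate parent of u)
      if (std::find(cand[u].begin(), cand[u].end(), v) == cand[u].end()) continue;
      if ((int)parents[u].size() >= max_parents) continue;
      drop_val(children[u], v);  // temporarily remove for the cycle check
      bool cyc = creates_cycle(children, v, u, G);
      children[u].push_back(v);
      if (cyc) continue;
      std::vector<int> npv = parents[v]; drop_val(npv, u);
      std::vector<int> npu = parents[u]; npu.push_back(v);
      double fv = family_score(states, v, npv, kappa, lambda);
      double fu = family_score(states, u, npu, kappa, lambda);
      double delta = (fv - fam[v]) + (fu - fam[u]);
      if (delta >= 0 || unif(rng) < std::exp(beta * delta)) {
        parents[v] = npv; drop_val(children[u], v);
        parents[u] = npu; children[v].push_back(u);
        fam[v] = fv; fam[u] = fu; score += delta; ++accepted;
      }
    }
    if (score > best) { best = score; best_parents = parents; }
  }

  int n_edges = 0;
  for (int j = 0; j < G; ++j) n_edges += (int)best_parents[j].size();
  IntegerMatrix edges(n_edges, 2);
  int r = 0;
  for (int j = 0; j < G; ++j) {
    std::vector<int> ps = best_parents[j];
    std::sort(ps.begin(), ps.end());
    for (int p : ps) { edges(r, 0) = p + 1; edges(r, 1) = j + 1; ++r; }
  }
  return List::create(_["edges"] = edges, _["log_score"] = best,
                      _["accepted"] = accepted, _["proposed"] = n_iter);
}

// [[Rcpp::export(name = ".family_score_cpp")]]
double family_score_cpp(IntegerMatrix states, int child, IntegerVector parents,
                        double kappa, double lambda) {
  std::vector<int> pa(parents.begin(), parents.end());
  for (auto& p : pa) --p;
  return family_score(states, child - 1, pa, kappa, lambda);
}
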