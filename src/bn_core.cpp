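#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// BDeu family score.  data holds 0-based state indices; arity[i] >= 1 is the
// number of states of column i (declared, so unobserved states still shape the
// prior).  With q parent configurations and r child states the hyperparameters
// are alpha_ij = ess/q and alpha_ijk = ess/(q*r); parent configurations with
// zero counts contribute nothing, so an empty dataset scores exactly 0.
static double family_score_ll(const IntegerMatrix& data,
                              const IntegerVector& arity,
                              int child,
                              const std::vector<int>& par,
                              double ess) {
  const int n = data.nrow();
  const int r = arity[child];
  long long q = 1;
  for (int p : par) q *= arity[p];
  if (q * (long long)r > 50000000LL)
    stop("parent configuration space too large");
  std::vector<int> counts((size_t)(q * (long long)r), 0);
  for (int i = 0; i < n; ++i) {
    long long j = 0;
    for (int p : par) j = j * arity[p] + data(i, p);
    ++counts[(size_t)(j * r + data(i, child))];
  }
  const double aij  = ess / (double)q;
  const double aijk = ess / ((double)q * (double)r);
  const double lg_aij  = R::lgammafn(aij);
  const double lg_aijk = R::lgammafn(aijk);
  double s = 0.0;
  for (long long j = 0; j < q; ++j) {
    int nij = 0;
    for (int k = 0; k < r; ++k) nij += counts[(size_t)(j * r + k)];
    if (nij == 0) continue;
    s += lg_aij - R::lgammafn(aij + nij);
    for (int k = 0; k < r; ++k) {
      int nijk = counts[(size_t)(j * r + k)];
      if (nijk > 0) s += R::lgammafn(aijk + nijk) - lg_aijk;
    }
  }
  return s;
}

// [[Rcpp::export]]
double bdeu_family_score_cpp(IntegerMatrix data, IntegerVector arity,
                             int child, IntegerVector parents, double ess) {
  std::vector<int> par(parents.begin(), parents.end());
  return family_score_ll(data, arity, child, par, ess);
}

// ---- simulated annealing over DAG space ------------------------------------

typedef uint64_t mask_t;

static inline bool has_bit(mask_t m, int i) { return (m >> i) & 1ULL; }

// is `to` reachable from `from` following child edges, optionally ignoring
// the single edge skip_u -> skip_v?
static bool reachable(const std::vector<mask_t>& children, int p,
                      int from, int to, int skip_u, int skip_v) {
  if (from == to) return true;
  std::vector<int> stack;
  stack.push_back(from);
  mask_t seen = 1ULL << from;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    mask_t ch = children[u];
    if (u == skip_u && skip_v >= 0) ch &= ~(1ULL << skip_v);
    for (int v = 0; v < p; ++v) {
      if (!has_bit(ch, v) || has_bit(seen, v)) continue;
      if (v == to) return true;
      seen |= 1ULL << v;
      stack.push_back(v);
    }
  }
  return false;
}

static std::vector<int> mask_to_vec(mask_t m, int p) {
  std::vector<int> out;
  for (int i = 0; i < p; ++i) if (has_bit(m, i)) out.push_back(i);
  return out;
}

struct ScoreCache {
  std::vector<std::unordered_map<mask_t, double> > tab;
  const IntegerMatrix& data;
  const IntegerVector& arity;
  double ess;
  long long misses;
  ScoreCache(const IntegerMatrix& d, const IntegerVector& a, double e, int p)
    : tab(p), data(d), arity(a), ess(e), misses(0) {}
  double get(int child, mask_t parents) {
    std::unordered_map<mask_t, double>& m = tab[child];
    std::unordered_map<mask_t, double>::iterator it = m.find(parents);
    if (it != m.end()) return it->second;
    double s = family_score_ll(data, arity, child,
                               mask_to_vec(parents, data.ncol()), ess);
    m[parents] = s;
    ++misses;
    return s;
  }
};

// One annealing run per restart, starting from the empty DAG.  Moves are
// add/delete/reverse of a single edge, drawn uniformly from the syntactic move
// multiset (one add per non-adjacent ordered pair, one delete and one reverse
// per existing edge); cycle-creating or parent-limit-violating proposals are
// rejected without a state change.  Geometric cooling: T <- T*cool_factor
// every cool_every proposals, reset at each restart.  Within a restart every
// distinct structure whose score is within tie_tol of the restart best is
// retained (up to max_ties).
// [[Rcpp::export]]
List anneal_search_cpp(IntegerMatrix data, IntegerVector arity, double ess,
                       int max_parents, int n_restarts, int proposals,
                       double t0, double cool_factor, int cool_every,
                       double tie_tol, int max_ties) {
  const int p = data.ncol();
  if (p > 62) stop("at most 62 variables supported");
  ScoreCache cache(data, arity, ess, p);
  List restarts(n_restarts);
  long long accepted = 0;

  for (int rs = 0; rs < n_restarts; ++rs) {
    std::vector<mask_t> parents(p, 0ULL), children(p, 0ULL);
    std::vector<double> fs(p);
    for (int v = 0; v < p; ++v) fs[v] = cache.get(v, 0ULL);
    std::vector<std::pair<int,int> > edges;
    std::vector<int> edge_pos(p * p, -1);

    double total = 0.0;
    for (int v = 0; v < p; ++v) total += fs[v];
    double best = total;
    std::vector<std::vector<mask_t> > ties;
    ties.push_back(parents);

    double T = t0;
    for (int step = 0; step < proposals; ++step) {
      if (step > 0 && cool_every > 0 && step % cool_every == 0)
        T *= cool_factor;
      const long long E = (long long)edges.size();
      const long long n_nonadj = (long long)p * (p - 1) - 2 * E;
      const long long M = n_nonadj + 2 * E;
      if (M <= 0) continue;
      long long r = (long long)(unif_rand() * (double)M);
      if (r >= M) r = M - 1;

      int mv = -1, u = -1, v = -1; // mv: 0 add, 1 delete, 2 reverse
      if (r < 2 * E) {
        u = edges[(size_t)(r / 2)].first;
        v = edges[(size_t)(r / 2)].second;
        mv = (r % 2 == 0) ? 1 : 2;
      } else {
        mv = 0;
        do {
          u = (int)(unif_rand() * p); if (u >= p) u = p - 1;
          v = (int)(unif_rand() * p); if (v >= p) v = p - 1;
        } while (u == v || has_bit(parents[v], u) || has_bit(parents[u], v));
      }

      double delta; double new_fv = 0.0, new_fu = 0.0;
      if (mv == 0) { // add u -> v
        if (__builtin_popcountll(parents[v]) >= max_parents) continue;
        if (reachable(children, p, v, u, -1, -1)) continue; // would cycle
        new_fv = cache.get(v, parents[v] | (1ULL << u));
        delta = new_fv - fs[v];
      } else if (mv == 1) { // delete u -> v
        new_fv = cache.get(v, parents[v] & ~(1ULL << u));
        delta = new_fv - fs[v];
      } else { // reverse u -> v  becomes  v -> u
        if (__builtin_popcountll(parents[u]) >= max_parents) continue;
        if (reachable(children, p, u, v, u, v)) continue; // other u..v path
        new_fv = cache.get(v, parents[v] & ~(1ULL << u));
        new_fu = cache.get(u, parents[u] | (1ULL << v));
        delta = (new_fv - fs[v]) + (new_fu - fs[u]);
      }

      bool accept = delta >= 0.0 ||
        (T > 0.0 && unif_rand() < std::exp(delta / T));
      if (!accept) continue;
      ++accepted;

      if (mv == 0) {
        parents[v] |= 1ULL << u; children[u] |= 1ULL << v;
        edge_pos[u * p + v] = (int)edges.size();
        edges.push_back(std::make_pair(u, v));
        fs[v] = new_fv;
      } else {
        // remove edge u -> v (shared by delete and reverse)
        parents[v] &= ~(1ULL << u); children[u] &= ~(1ULL << v);
        int pos = edge_pos[u * p + v];
        int last = (int)edges.size() - 1;
        if (pos != last) {
          edges[pos] = edges[last];
          edge_pos[edges[pos].first * p + edges[pos].second] = pos;
        }
        edges.pop_back();
        edge_pos[u * p + v] = -1;
        fs[v] = new_fv;
        if (mv == 2) {
          parents[u] |= 1ULL << v; children[v] |= 1ULL << u;
          edge_pos[v * p + u] = (int)edges.size();
          edges.push_back(std::make_pair(v, u));
          fs[u] = new_fu;
        }
      }

      total = 0.0;
      for (int w = 0; w < p; ++w) total += fs[w];
      if (total > best + tie_tol) {
        best = total;
        ties.clear();
        ties.push_back(parents);
      } else if (total >= best - tie_tol && (int)ties.size() < max_ties) {
        bool dup = false;
        for (size_t t = 0; t < ties.size(); ++t)
          if (ties[t] == parents) { dup = true; break; }
        if (!dup) ties.push_back(parents);
      }
    }

    List dags((int)ties.size());
    for (size_t t = 0; t < ties.size(); ++t) {
      std::vector<int> from, to;
      for (int w = 0; w < p; ++w)
        for (int z = 0; z < p; ++z)
          if (has_bit(ties[t][z], w)) { from.push_back(w); to.push_back(z); }
      IntegerMatrix em((int)from.size(), 2);
      for (size_t i = 0; i < from.size(); ++i) {
        em(i, 0) = from[i] + 1; // 1-based for R
        em(i, 1) = to[i] + 1;
      }
      dags[t] = em;
    }
    restarts[rs] = List::create(_["score"] = best, _["edges"] = dags);
  }

  return List::create(_["restarts"] = restarts,
                      _["accepted"] = (double)accepted,
                      _["score_evals"] = (double)cache.misses);
}
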