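// Exhaustive enumeration of labeled molecular graphs under MCD constraints.
//
// Search: bond orders are assigned to atom pairs (i,j), i<j, in row-major
// order, so after finishing row i every bond incident to atoms 0..i is final.
// Pruning at each row completion:
//   - exact degree for atoms with known attached-H; flexible atoms keep
//     h = valence - degree >= 0 with the global free-H budget bracketed
//   - pi-bond count must match an allowed hybridization (sp3 0, sp2 1, sp 2)
//   - hetero-neighbor forbidden/obligatory flags
//   - no prematurely closed connected component
//   - optimistic-distance bound: a connectivity constraint [dlo,dhi] is
//     infeasible if even with every still-assignable bond added the two
//     atoms cannot come within dhi bonds (distances only shrink as bonds
//     are added, so current distance < dlo is also fatal)
// Constraints are existential over atom groups (degenerate peaks): satisfied
// if some pair of carrier atoms lies in range.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Constraint {
  std::vector<int> us, vs;
  int dlo, dhi;
};

struct Search {
  int n;
  std::vector<int> valence, h_fixed, elem_hetero, pi_allowed_mask, hetero_flag;
  std::vector<int> prev_same;   // previous member of an interchangeable-atom
                                // group (-1 if none): used for symmetry breaking
  int free_h;
  std::vector<std::vector<int>> min_ord, max_ord;
  std::vector<Constraint> cons;
  // state
  std::vector<std::vector<int>> B;      // bond order matrix
  std::vector<int> deg, pi;
  int used_h;
  long long nodes, node_budget;
  int max_structures;
  bool incomplete;
  std::vector<IntegerMatrix> out_bonds;
  std::vector<IntegerVector> out_h;

  int pimax(int a) const {
    int m = pi_allowed_mask[a];
    if (m & 4) return 2;
    if (m & 2) return 1;
    return 0;
  }
  bool pi_ok_final(int a) const {
    int p = pi[a];
    if (p > 2) return false;
    return (pi_allowed_mask[a] >> p) & 1;
  }

  // spare heavy-bond capacity of an atom (fixed hydrogens are committed)
  int cap(int x) const {
    return (h_fixed[x] >= 0) ? valence[x] - h_fixed[x] - deg[x]
                             : valence[x] - deg[x];
  }

  // BFS distance from u to v over current bonds plus (optimistic) all
  // still-undecided pairs with spare capacity; rows 0..row_done are final.
  // A midpath atom entered and left via two potential edges needs spare
  // capacity >= 2.  State: (atom, arrived-via-potential-edge).
  int bfs_dist(int u, int v, int row_done, bool optimistic) const {
    std::vector<int> dist(2 * n, -1);
    std::queue<int> q;
    dist[2 * u] = 0; q.push(2 * u);
    while (!q.empty()) {
      int st = q.front(); q.pop();
      int x = st / 2, pot = st % 2;
      if (x == v) return dist[st];
      for (int y = 0; y < n; ++y) {
        if (y == x) continue;
        if (B[x][y] > 0) {
          if (dist[2 * y] < 0) { dist[2 * y] = dist[st] + 1; q.push(2 * y); }
        } else if (optimistic) {
          int lo = std::min(x, y);
          if (lo > row_done && max_ord[x][y] > 0 &&
              cap(x) >= 1 + pot && cap(y) >= 1 && dist[2 * y + 1] < 0) {
            dist[2 * y + 1] = dist[st] + 1;
            q.push(2 * y + 1);
          }
        }
      }
    }
    int d0 = dist[2 * v], d1 = dist[2 * v + 1];
    if (d0 < 0) return d1;
    if (d1 < 0) return d0;
    return std::min(d0, d1);
  }

  bool constraint_feasible(const Constraint &c, int row_done) const {
    for (int u : c.us) for (int v : c.vs) {
      if (u == v) continue;
      int d = bfs_dist(u, v, row_done, true);
      if (d >= 0 && d <= c.dhi) {
        // lower bound: if both endpoints fully decided and already closer
        // than dlo the pair is dead, but another pair may still serve
        if (u <= row_done && v <= row_done) {
          int dc = bfs_dist(u, v, row_done, false);
          if (dc >= 0 && dc < c.dlo) continue;
        }
        return true;
      }
    }
    return false;
  }

  bool constraint_satisfied(const Constraint &c) const {
    for (int u : c.us) for (int v : c.vs) {
      if (u == v) continue;
      int d = bfs_dist(u, v, n - 1, false);
      if (d >= c.dlo && d <= c.dhi) return true;
    }
    return false;
  }

  // Interchangeable atoms a < b (identical element, H, properties and
  // constraint membership): require the bond matrix to be lexicographically
  // >= its image under the transposition (a b), in row-major upper-triangle
  // cell order.  The lex-greatest member of each orbit survives, so
  // completeness up to isomorphism is preserved while automorphic labeled
  // duplicates are pruned.  All compared cells are decided once row b is.
  bool swap_lex_ok(int a, int b) const {
    for (int r = 0; r <= b; ++r) {
      for (int c = r + 1; c < n; ++c) {
        if (r != a && r != b && c != a && c != b) continue;  // fixed point
        int sr = (r == a) ? b : (r == b) ? a : r;
        int sc = (c == a) ? b : (c == b) ? a : c;
        int v1 = B[r][c];
        int v2 = B[sr][sc];
        if (v1 != v2) return v1 > v2;
      }
    }
    return true;
  }

  bool row_complete_ok(int i) {
    if (prev_same[i] >= 0 && !swap_lex_ok(prev_same[i], i)) return false;
    // degree / H bookkeeping for atom i
    if (h_fixed[i] >= 0) {
      if (deg[i] != valence[i] - h_fixed[i]) return false;
    } else {
      int h = valence[i] - deg[i];
      if (h < 0) return false;
      if (n > 1 && deg[i] == 0) return false;
      used_h += h;  // caller restores
      if (used_h > free_h) return false;
      // can the remaining flexible atoms absorb the rest of the H budget?
      int max_rest = 0;
      for (int k = i + 1; k < n; ++k) {
        if (h_fixed[k] >= 0) continue;
        int cap = valence[k] - deg[k];
        if (n > 1 && deg[k] == 0) cap -= 1;
        if (cap > 0) max_rest += cap;
      }
      if (used_h + max_rest < free_h) return false;
    }
    if (!pi_ok_final(i)) return false;
    if (hetero_flag[i] != 0) {
      bool has_het = false;
      for (int y = 0; y < n; ++y)
        if (B[i][y] > 0 && elem_hetero[y]) { has_het = true; break; }
      if (hetero_flag[i] == 1 && has_het) return false;       // forbidden
      if (hetero_flag[i] == 2 && !has_het) return false;      // obligatory
    }
    // premature component closure: a component made only of decided atoms
    // (all indices <= i) of size < n can never reconnect
    if (i < n - 1) {
      std::vector<int> comp(n, -1);
      for (int s = 0; s < n; ++s) {
        if (comp[s] >= 0) continue;
        std::queue<int> q; q.push(s); comp[s] = s;
        int maxidx = s, size = 1;
        while (!q.empty()) {
          int x = q.front(); q.pop();
          for (int y = 0; y < n; ++y)
            if (B[x][y] > 0 && comp[y] < 0) {
              comp[y] = s; q.push(y);
              if (y > maxidx) maxidx = y;
              ++size;
            }
        }
        if (maxidx <= i && size < n) return false;
      }
      // feasibility of remaining required degrees
      for (int k = i + 1; k < n; ++k) {
        if (h_fixed[k] < 0) continue;
        int need = valence[k] - h_fixed[k] - deg[k];
        if (need < 0) return false;
        int cap = 0;
        for (int y = i + 1; y < n; ++y) {
          if (y == k || max_ord[k][y] == 0 || B[k][y] > 0) continue;
          int c2 = (h_fixed[y] >= 0) ? (valence[y] - h_fixed[y] - deg[y])
                                     : (valence[y] - deg[y]);
          cap += std::min(3, std::min(std::max(c2, 0), max_ord[k][y]));
        }
        if (need > cap) return false;
      }
    }
    for (const auto &c : cons)
      if (!constraint_feasible(c, i)) return false;
    return true;
  }

  void finalize() {
    if (used_h != free_h) return;
    // connectivity
    std::vector<char> seen(n, 0);
    std::queue<int> q; q.push(0); seen[0] = 1;
    int cnt = 1;
    while (!q.empty()) {
      int x = q.front(); q.pop();
      for (int y = 0; y < n; ++y)
        if (B[x][y] > 0 && !seen[y]) { seen[y] = 1; q.push(y); ++cnt; }
    }
    if (cnt != n) return;
    for (const auto &c : cons)
      if (!constraint_satisfied(c)) return;
    int nb = 0;
    for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j)
      if (B[i][j] > 0) ++nb;
    IntegerMatrix bm(nb, 3);
    int r = 0;
    for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j)
      if (B[i][j] > 0) { bm(r, 0) = i + 1; bm(r, 1) = j + 1; bm(r, 2) = B[i][j]; ++r; }
    IntegerVector hv(n);
    for (int i = 0; i < n; ++i)
      hv[i] = (h_fixed[i] >= 0) ? h_fixed[i] : (valence[i] - deg[i]);
    out_bonds.push_back(bm);
    out_h.push_back(hv);
  }

  void rec(int pair_idx) {
    if (incomplete || (int)out_bonds.size() >= max_structures) { incomplete = true; return; }
    if (++nodes > node_budget) { incomplete = true; return; }
    int npairs = n * (n - 1) / 2;
    if (pair_idx == npairs) { finalize(); return; }
    // decode pair index -> (i, j)
    int i = 0, rem = pair_idx;
    while (rem >= n - 1 - i) { rem -= n - 1 - i; ++i; }
    int j = i + 1 + rem;
    bool last_in_row = (j == n - 1);
    for (int o = min_ord[i][j]; o <= max_ord[i][j]; ++o) {
      if (o > 0) {
        if (deg[i] + o > valence[i] || deg[j] + o > valence[j]) break;
        if (pi[i] + o - 1 > pimax(i) || pi[j] + o - 1 > pimax(j)) break;
      }
      B[i][j] = B[j][i] = o;
      deg[i] += o; deg[j] += o;
      pi[i] += std::max(o - 1, 0); pi[j] += std::max(o - 1, 0);
      int saved_used_h = used_h;
      bool ok = true;
      if (last_in_row) ok = row_complete_ok(i);
      if (ok && last_in_row && i == n - 2) ok = row_complete_ok(n - 1);
      if (ok) rec(pair_idx + 1);
      used_h = saved_used_h;
      B[i][j] = B[j][i] = 0;
      deg[i] -= o; deg[j] -= o;
      pi[i] -= std::max(o - 1, 0); pi[j] -= std::max(o - 1, 0);
      if (incomplete) return;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_enumerate")]]
List cpp_enumerate(IntegerVector valence, IntegerVector h_fixed, int free_h,
                   IntegerVector elem_hetero, IntegerVector pi_allowed_mask,
                   IntegerVector hetero_flag, IntegerVector prev_same,
                   IntegerMatrix min_order, IntegerMatrix max_order,
                   List constraints, int max_structures, double node_budget) {
  Search s;
  s.n = valence.size();
  s.valence = as<std::vector<int>>(valence);
  s.h_fixed = as<std::vector<int>>(h_fixed);
  s.prev_same = as<std::vector<int>>(prev_same);
  s.free_h = free_h;
  s.elem_hetero = as<std::vector<int>>(elem_hetero);
  s.pi_allowed_mask = as<std::vector<int>>(pi_allowed_mask);
  s.hetero_flag = as<std::vector<int>>(hetero_flag);
  s.min_ord.assign(s.n, std::vector<int>(s.n, 0));
  s.max_ord.assign(s.n, std::vector<int>(s.n, 0));
  for (int i = 0; i < s.n; ++i) for (int j = 0; j < s.n; ++j) {
    s.min_ord[i][j] = min_order(i, j);
    s.max_ord[i][j] = max_order(i, j);
  }
  for (int k = 0; k < constraints.size(); ++k) {
    List c = constraints[k];
    Constraint cc;
    IntegerVector us = c["us"], vs = c["vs"];
    for (int u : us) cc.us.push_back(u - 1);
    for (int v : vs) cc.vs.push_back(v - 1);
    cc.dlo = as<int>(c["dlo"]);
    cc.dhi = as<int>(c["dhi"]);
    s.cons.push_back(cc);
  }
  s.B.assign(s.n, std::vector<int>(s.n, 0));
  s.deg.assign(s.n, 0);
  s.pi.assign(s.n, 0);
  s.used_h = 0;
  s.nodes = 0;
  s.node_budget = (long long)node_budget;
  s.max_structures = max_structures;
  s.incomplete = false;
  if (s.n == 1) {
    if (s.h_fixed[0] >= 0 ? (s.h_fixed[0] == s.valence[0] && free_h == 0)
                          : (s.valence[0] == free_h)) {
      s.used_h = (s.h_fixed[0] >= 0) ? 0 : free_h;
      s.finalize();
    }
  } else {
    s.rec(0);
  }
  return List::create(_["bonds"] = wrap(s.out_bonds),
                      _["hydrogens"] = wrap(s.out_h),
                      _["complete"] = !s.incomplete,
                      _["nodes"] = (double)s.nodes);
}
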