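// Canonical circular atom signatures.
//
// For a root atom, the height-h environment is the induced subgraph on all
// atoms within graph distance <= h.  Its canonical serialization is found by
// colour refinement with individualization (branch on the first non-singleton
// colour class, keep the lexicographically smallest emitted string), so two
// atoms receive the same signature text exactly when their rooted
// environments are isomorphic (element label, charge, implicit-H count,
// aromaticity and bond orders all live in the vertex/edge labels supplied
// from R).  The string is a depth-first spanning tree with numbered ring
// closures, parseable back into the environment graph.

#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <map>
#include <string>
#include <utility>
#include <vector>

using namespace Rcpp;

namespace {

struct Sub {
  int n = 0;
  int root = 0;
  std::vector<std::string> lab;
  std::vector<std::vector<std::pair<int, char>>> adj;  // (neighbour, bond symbol)
};

int count_colours(const std::vector<int>& col) {
  if (col.empty()) return 0;
  return 1 + *std::max_element(col.begin(), col.end());
}

// Iterated neighbourhood refinement; colours are ranks of (old colour,
// sorted multiset of (bond symbol, neighbour colour)) keys.
void refine(const Sub& g, std::vector<int>& col) {
  const int n = g.n;
  int ncol = count_colours(col);
  for (;;) {
    std::vector<std::vector<int>> key(n);
    for (int v = 0; v < n; ++v) {
      std::vector<std::pair<int, int>> nb;
      nb.reserve(g.adj[v].size());
      for (const auto& e : g.adj[v])
        nb.emplace_back(static_cast<int>(e.second), col[e.first]);
      std::sort(nb.begin(), nb.end());
      key[v].push_back(col[v]);
      for (const auto& p : nb) {
        key[v].push_back(p.first);
        key[v].push_back(p.second);
      }
    }
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return key[a] < key[b]; });
    std::vector<int> ncolv(n);
    int c = 0;
    for (int i = 0; i < n; ++i) {
      if (i > 0 && key[idx[i]] != key[idx[i - 1]]) ++c;
      ncolv[idx[i]] = c;
    }
    col = ncolv;
    if (c + 1 == ncol) break;  // partition stable
    ncol = c + 1;
    if (ncol == n) break;
  }
}

// Serialize under a discrete colouring: depth-first from the root, children
// in colour order; non-tree edges become numbered ring closures emitted at
// both endpoints.
std::string emit(const Sub& g, const std::vector<int>& col) {
  const int n = g.n;
  std::vector<int> parent(n, -2);
  std::vector<std::vector<int>> kids(n);
  std::vector<std::vector<std::pair<int, char>>> clos(n);  // (id, bond)
  std::map<std::pair<int, int>, int> ring_id;
  int next_id = 1;

  std::function<void(int)> dfs = [&](int v) {
    std::vector<std::pair<int, int>> order;  // (colour, adj slot)
    for (size_t i = 0; i < g.adj[v].size(); ++i)
      order.emplace_back(col[g.adj[v][i].first], static_cast<int>(i));
    std::sort(order.begin(), order.end());
    for (const auto& o : order) {
      const int u = g.adj[v][o.second].first;
      const char bc = g.adj[v][o.second].second;
      if (parent[u] == -2) {
        parent[u] = v;
        kids[v].push_back(u);
        dfs(u);
      } else if (u != parent[v] && parent[u] != v) {
        std::pair<int, int> e(std::min(u, v), std::max(u, v));
        if (ring_id.find(e) == ring_id.end()) {
          ring_id[e] = next_id++;
          clos[v].emplace_back(ring_id[e], bc);
          clos[u].emplace_back(ring_id[e], bc);
        }
      }
    }
  };
  parent[g.root] = -1;
  dfs(g.root);

  std::function<std::string(int)> write = [&](int v) {
    std::string s = "[" + g.lab[v] + "]";
    std::sort(clos[v].begin(), clos[v].end());
    for (const auto& c : clos[v]) {
      s += c.second;
      s += '%';
      s += std::to_string(c.first);
    }
    if (!kids[v].empty()) {
      s += '(';
      for (int u : kids[v]) {
        char bc = '-';
        for (const auto& e : g.adj[v])
          if (e.first == u) { bc = e.second; break; }
        s += bc;
        s += write(u);
      }
      s += ')';
    }
    return s;
  };
  return write(g.root);
}

void search(const Sub& g, std::vector<int> col, std::string& best, bool& have) {
  refine(g, col);
  const int n = g.n;
  const int ncol = count_colours(col);
  if (ncol == n) {
    std::string s = emit(g, col);
    if (!have || s < best) {
      best = s;
      have = true;
    }
    return;
  }
  std::vector<int> cnt(ncol, 0);
  for (int c : col) cnt[c]++;
  int target = 0;
  while (cnt[target] < 2) ++target;
  for (int v = 0; v < n; ++v) {
    if (col[v] != target) continue;
    std::vector<int> col2(n);
    for (int u = 0; u < n; ++u) col2[u] = 2 * col[u] + 1;
    col2[v] = 2 * target;  // individualize v just below its class
    search(g, col2, best, have);
  }
}

std::string signature_of(const std::vector<std::string>& lab,
                         const std::vector<std::vector<std::pair<int, char>>>& adj,
                         int root, int height) {
  const int n = static_cast<int>(lab.size());
  // BFS out to `height` bonds
  std::vector<int> dist(n, -1);
  std::vector<int> verts;
  dist[root] = 0;
  verts.push_back(root);
  for (size_t head = 0; head < verts.size(); ++head) {
    int v = verts[head];
    if (dist[v] == height) continue;
    for (const auto& e : adj[v]) {
      if (dist[e.first] < 0) {
        dist[e.first] = dist[v] + 1;
        verts.push_back(e.first);
      }
    }
  }
  std::sort(verts.begin(), verts.end());

  Sub g;
  g.n = static_cast<int>(verts.size());
  std::vector<int> local(n, -1);
  for (int i = 0; i < g.n; ++i) local[verts[i]] = i;
  g.root = local[root];
  g.lab.resize(g.n);
  g.adj.resize(g.n);
  for (int i = 0; i < g.n; ++i) {
    const int v = verts[i];
    g.lab[i] = lab[v];
    for (const auto& e : adj[v])
      if (local[e.first] >= 0) g.adj[i].emplace_back(local[e.first], e.second);
  }

  // initial colours: root unique, others by label
  std::vector<std::pair<std::pair<int, std::string>, int>> keys(g.n);
  for (int i = 0; i < g.n; ++i)
    keys[i] = {{i == g.root ? 0 : 1, g.lab[i]}, i};
  std::sort(keys.begin(), keys.end());
  std::vector<int> col(g.n);
  int c = 0;
  for (int i = 0; i < g.n; ++i) {
    if (i > 0 && keys[i].first != keys[i - 1].first) ++c;
    col[keys[i].second] = c;
  }

  std::string best;
  bool have = false;
  search(g, col, best, have);
  return best;
}

}  // namespace

// [[Rcpp::export]]
CharacterVector cpp_atom_signatures(CharacterVector atom_label,
                                    IntegerVector bond_a,
                                    IntegerVector bond_b,
                                    CharacterVector bond_sym,
                                    int height,
                                    IntegerVector roots) {
  const int n = atom_label.size();
  const int m = bond_a.size();
  if (height < 0) stop("height must be >= 0");
  std::vector<std::string> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = as<std::string>(atom_label[i]);
  std::vector<std::vector<std::pair<int, char>>> adj(n);
  for (int j = 0; j < m; ++j) {
    const int a = bond_a[j] - 1;
    const int b = bond_b[j] - 1;
    if (a < 0 || a >= n || b < 0 || b >= n || a == b)
      stop("invalid bond endpoints");
    const char bc = as<std::string>(bond_sym[j])[0];
    adj[a].emplace_back(b, bc);
    adj[b].emplace_back(a, bc);
  }
  CharacterVector out(roots.size());
  for (int i = 0; i < roots.size(); ++i) {
    const int r = roots[i] - 1;
    if (r < 0 || r >= n) stop("root atom index out of range");
    out[i] = signature_of(lab, adj, r, height);
  }
  return out;
}
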