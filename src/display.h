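#ifndef AGREETREE_DISPLAY_H
#define AGREETREE_DISPLAY_H

#include <vector>
#include <unordered_set>
#include <stdexcept>
#include <string>
#include <algorithm>
#include <cstdint>

// Decremental connectivity over the display graph of a profile.
//
// Vertices are taxa (0-based).  Edges are undirected parent-child label
// pairs pooled over all input trees, deduplicated.  Vertices and edges are
// deleted at most once over a whole run.  Two backends:
//
//   * "forest": a spanning forest with replacement-edge search.  Deleting a
//     non-forest edge is O(1); deleting a forest edge triggers a
//     simultaneous alternating BFS over forest edges from both endpoints,
//     the side whose frontier exhausts first (the smaller side) is scanned
//     for a replacement edge; if none exists the smaller side is split off
//     into a new component.
//   * "bfs": the same alternating search run over graph (not forest)
//     adjacency; simple and obviously correct, used as a cross-check.
//
// Every split records the vertices moved to the new component, which is
// always the smaller side, so a vertex moves at most ~log2(V) times.

struct SplitEvent {
  int from_comp;
  int new_comp;
  std::vector<int> moved; // vertices moved into new_comp
};

class DisplayGraph {
public:
  int nv;
  bool use_forest;
  std::vector<std::unordered_set<int>> adj;
  std::vector<char> alive;
  std::vector<int> comp;      // component id per vertex, -1 once dead
  std::vector<long long> comp_size;
  int next_comp;
  std::vector<std::unordered_set<int>> fadj; // spanning forest adjacency
  std::vector<int> move_count;
  std::vector<SplitEvent> split_log;
  long long n_edge_del, n_vertex_del;

  DisplayGraph(int n, const std::vector<std::pair<int,int>> &edges,
               bool forest_backend)
      : nv(n), use_forest(forest_backend), adj(n), alive(n, 1), comp(n, -1),
        next_comp(0), fadj(n), move_count(n, 0), n_edge_del(0),
        n_vertex_del(0), stamp_(n, 0), side_(n, 0), cur_stamp_(0) {
    for (const auto &e : edges) {
      if (e.first == e.second) continue; // no self loops
      adj[e.first].insert(e.second);
      adj[e.second].insert(e.first);
    }
    init_components();
  }

  bool has_edge(int u, int v) const {
    return alive[u] && alive[v] && adj[u].count(v) > 0;
  }

  // Remove edge {u,v}; update components, possibly logging a split.
  void delete_edge(int u, int v) {
    if (!alive[u] || !alive[v])
      throw std::runtime_error("delete_edge: dead endpoint");
    if (!adj[u].count(v))
      throw std::runtime_error("delete_edge: edge not present");
    adj[u].erase(v);
    adj[v].erase(u);
    ++n_edge_del;
    if (use_forest) {
      if (fadj[u].count(v)) {
        fadj[u].erase(v);
        fadj[v].erase(u);
        forest_edge_deleted(u, v);
      }
    } else {
      graph_edge_deleted(u, v);
    }
  }

  // Delete all incident edges (one at a time), then the vertex itself.
  void delete_vertex(int u) {
    if (!alive[u]) throw std::runtime_error("delete_vertex: already deleted");
    std::vector<int> nbs(adj[u].begin(), adj[u].end());
    std::sort(nbs.begin(), nbs.end()); // deterministic deletion order
    for (int v : nbs) delete_edge(u, v);
    // u is now isolated: its component is a singleton
    comp_size[comp[u]] -= 1;
    comp[u] = -1;
    alive[u] = 0;
    ++n_vertex_del;
  }

  bool connected(int u, int v) const {
    return alive[u] && alive[v] && comp[u] == comp[v];
  }

private:
  std::vector<int> stamp_;
  std::vector<char> side_; // 0 = side of u, 1 = side of v, valid when stamp matches
  int cur_stamp_;

  void init_components() {
    std::vector<int> queue;
    for (int s = 0; s < nv; ++s) {
      if (comp[s] >= 0) continue;
      int c = next_comp++;
      comp_size.push_back(0);
      queue.clear();
      queue.push_back(s);
      comp[s] = c;
      comp_size[c] = 1;
      size_t head = 0;
      while (head < queue.size()) {
        int x = queue[head++];
        for (int y : adj[x]) {
          if (comp[y] < 0) {
            comp[y] = comp[x];
            comp_size[c] += 1;
            if (use_forest) {
              fadj[x].insert(y);
              fadj[y].insert(x);
            }
            queue.push_back(y);
          }
        }
      }
    }
  }

  void split_off(std::vector<int> &side_vertices, int old_comp) {
    int nc = next_comp++;
    comp_size.push_back((long long)side_vertices.size());
    comp_size[old_comp] -= (long long)side_vertices.size();
    std::sort(side_vertices.begin(), side_vertices.end());
    for (int x : side_vertices) {
      comp[x] = nc;
      move_count[x] += 1;
    }
    SplitEvent ev;
    ev.from_comp = old_comp;
    ev.new_comp = nc;
    ev.moved = side_vertices;
    split_log.push_back(std::move(ev));
  }

  // Alternating BFS over `g` from u and v.  Returns 0 if side-of-u
  // exhausted first, 1 if side-of-v exhausted first, -1 if the two
  // searches met (graph mode only; never happens over a forest).
  // The exhausted side's vertex set is left in `out`.
  int alternating_search(const std::vector<std::unordered_set<int>> &g, int u,
                         int v, bool detect_meet, std::vector<int> &out) {
    int token = ++cur_stamp_;
    std::vector<int> qa, qb;
    size_t ha = 0, hb = 0;
    qa.push_back(u); stamp_[u] = token; side_[u] = 0;
    qb.push_back(v); stamp_[v] = token; side_[v] = 1;
    for (;;) {
      if (ha >= qa.size()) { out = qa; return 0; }
      {
        int x = qa[ha++];
        for (int y : g[x]) {
          if (stamp_[y] == token) {
            if (detect_meet && side_[y] == 1) return -1;
            continue;
          }
          stamp_[y] = token; side_[y] = 0; qa.push_back(y);
        }
      }
      if (hb >= qb.size()) { out = qb; return 1; }
      {
        int x = qb[hb++];
        for (int y : g[x]) {
          if (stamp_[y] == token) {
            if (detect_meet && side_[y] == 0) return -1;
            continue;
          }
          stamp_[y] = token; side_[y] = 1; qb.push_back(y);
        }
      }
    }
  }

  void forest_edge_deleted(int u, int v) {
    std::vector<int> part;
    int side = alternating_search(fadj, u, v, false, part);
    int anchor = side == 0 ? u : v;
    (void)anchor;
    // membership in `part` <=> stamp matches and side_ equals `side`
    int token = cur_stamp_;
    // replacement-edge search over the smaller forest part
    for (int x : part) {
      for (int y : adj[x]) {
        if (stamp_[y] != token || side_[y] != (char)side) {
          // y lies in the other part of the (old) component
          fadj[x].insert(y);
          fadj[y].insert(x);
          return;
        }
      }
    }
    split_off(part, comp[u]);
  }

  void graph_edge_deleted(int u, int v) {
    std::vector<int> part;
    int side = alternating_search(adj, u, v, true, part);
    if (side < 0) return; // still connected
    split_off(part, comp[u] >= 0 ? comp[u] : comp[v]);
  }
};

#endif
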