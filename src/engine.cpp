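#include <Rcpp.h>
#include <random>
#include <map>
#include <deque>
#include "display.h"

using namespace Rcpp;

// Top-down agreement-supertree construction over a profile of fully and
// singularly labeled rooted trees.  The engine owns the display graph and
// the exposure bookkeeping; deletions are destructive and performed once,
// so an engine instance is single-use for a full build (stepped decompose
// calls share the same state and must follow the top-down order).

namespace {

struct TreeData {
  int n;
  std::vector<int> parent;              // node -> node, -1 for root
  std::vector<int> taxon;               // node -> taxon id
  std::vector<int> child_start;         // CSR over nodes, child order kept
  std::vector<int> child_list;          // children as taxon ids
  std::vector<int> tax2node;            // taxon -> node or -1
  std::vector<char> seen;               // per node: position reached it
  int root;
};

struct BlockStore {
  // Union-find over blocks; each live root holds its child entries.
  std::vector<int> uf;
  std::vector<std::vector<std::pair<int,int>>> entries; // (tree, child taxon)
  int find(int x) {
    while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
    return x;
  }
  int create() {
    int id = (int)uf.size();
    uf.push_back(id);
    entries.emplace_back();
    return id;
  }
  // merge b into a (both roots)
  void link(int a, int b) {
    if (entries[a].size() < entries[b].size()) std::swap(a, b);
    uf[b] = a;
    auto &ea = entries[a];
    for (auto &p : entries[b]) ea.push_back(p);
    entries[b].clear();
    entries[b].shrink_to_fit();
  }
};

struct DecompOut {
  std::vector<int> exposed;                    // S before the while loop
  std::vector<std::vector<int>> blocks0;       // initial child partition
  std::vector<int> bad_seq;                    // bad labels, elimination order
  std::vector<std::vector<int>> merged_seq;    // merged block after each step
  std::vector<int> S;                          // final nice exposed subset
  std::vector<std::vector<int>> final_blocks;
  std::vector<std::vector<int>> successors;    // k-vectors, -1 = empty
  int while_iters;
};

class Engine {
public:
  int k, ntax;
  std::vector<TreeData> trees;
  std::vector<int> unseen_count;  // taxon -> #trees not yet reached
  std::vector<char> deleted;      // taxon already removed from the graph
  std::vector<char> in_some_tree; // sanity
  DisplayGraph dg;
  bool validate;
  std::string bad_order;          // "scan" or "random"
  std::mt19937 rng;
  bool build_used;
  // stats
  long long positions_processed, decompose_calls, bad_eliminations;

  Engine(const List &treelist, int ntaxa, const std::string &backend,
         bool validate_, const std::string &bad_order_, int seed)
      : k(treelist.size()), ntax(ntaxa),
        unseen_count(ntaxa, 0), deleted(ntaxa, 0), in_some_tree(ntaxa, 0),
        dg(ntaxa, collect_edges(treelist, ntaxa), backend == "forest"),
        validate(validate_), bad_order(bad_order_), rng(seed),
        build_used(false), positions_processed(0), decompose_calls(0),
        bad_eliminations(0) {
    if (backend != "forest" && backend != "bfs")
      stop("unknown connectivity backend: %s", backend.c_str());
    trees.resize(k);
    for (int i = 0; i < k; ++i) {
      List tr = treelist[i];
      IntegerVector par = tr["parent"];
      IntegerVector tax = tr["taxon"];
      TreeData &td = trees[i];
      td.n = par.size();
      td.parent.resize(td.n);
      td.taxon.resize(td.n);
      td.tax2node.assign(ntax, -1);
      td.seen.assign(td.n, 0);
      td.root = -1;
      std::vector<int> nkids(td.n, 0);
      for (int v = 0; v < td.n; ++v) {
        td.parent[v] = par[v] - 1; // 0 root sentinel -> -1
        if (td.parent[v] < 0) {
          if (td.root >= 0) stop("tree %d has two roots", i + 1);
          td.root = v;
        } else {
          nkids[td.parent[v]] += 1;
        }
        int t = tax[v] - 1;
        if (t < 0 || t >= ntax) stop("taxon id out of range");
        if (td.tax2node[t] >= 0) stop("taxon labels two nodes in one tree");
        td.taxon[v] = t;
        td.tax2node[t] = v;
        in_some_tree[t] = 1;
        unseen_count[t] += 1;
      }
      if (td.root < 0) stop("tree %d has no root", i + 1);
      td.child_start.assign(td.n + 1, 0);
      for (int v = 0; v < td.n; ++v) td.child_start[v + 1] = nkids[v];
      for (int v = 0; v < td.n; ++v) td.child_start[v + 1] += td.child_start[v];
      td.child_list.assign(td.n > 0 ? td.child_start[td.n] : 0, -1);
      std::vector<int> fill(td.n, 0);
      // node index order preserves the written child order (preorder ids)
      for (int v = 0; v < td.n; ++v) {
        int p = td.parent[v];
        if (p >= 0) td.child_list[td.child_start[p] + fill[p]++] = td.taxon[v];
      }
    }
  }

  static std::vector<std::pair<int,int>> collect_edges(const List &treelist,
                                                       int ntax) {
    std::vector<std::pair<int,int>> edges;
    for (int i = 0; i < treelist.size(); ++i) {
      List tr = treelist[i];
      IntegerVector par = tr["parent"];
      IntegerVector tax = tr["taxon"];
      for (int v = 0; v < par.size(); ++v) {
        if (par[v] > 0) {
          int a = tax[par[v] - 1] - 1, b = tax[v] - 1;
          if (a < 0 || b < 0 || a >= ntax || b >= ntax)
            stop("taxon id out of range");
          edges.emplace_back(std::min(a, b), std::max(a, b));
        }
      }
    }
    std::sort(edges.begin(), edges.end());
    edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
    return edges;
  }

  // children of taxon t in tree i, in input order
  inline std::pair<const int*, const int*> children(int i, int t) const {
    const TreeData &td = trees[i];
    int v = td.tax2node[t];
    if (v < 0) return {nullptr, nullptr};
    return {td.child_list.data() + td.child_start[v],
            td.child_list.data() + td.child_start[v + 1]};
  }

  std::vector<int> initial_position() const {
    std::vector<int> pos(k, -1);
    for (int i = 0; i < k; ++i) pos[i] = trees[i].taxon[trees[i].root];
    return pos;
  }

  // --- validation helpers (used only with validate = TRUE) ---------------

  // taxa of the subtree of tree i rooted at taxon t
  void subtree_taxa(int i, int t, std::vector<char> &mark) const {
    const TreeData &td = trees[i];
    std::vector<int> stack{td.tax2node[t]};
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      mark[td.taxon[v]] = 1;
      for (int c = td.child_start[v]; c < td.child_start[v + 1]; ++c)
        stack.push_back(td.tax2node[td.child_list[c]]);
    }
  }

  void check_valid_position(const std::vector<int> &pos) const {
    std::vector<char> xp(ntax, 0);
    for (int i = 0; i < k; ++i)
      if (pos[i] >= 0) subtree_taxa(i, pos[i], xp);
    for (int i = 0; i < k; ++i) {
      const TreeData &td = trees[i];
      // nodes of tree i whose taxon is in X_P(pi)
      int lca = -1;
      bool any = false;
      for (int v = 0; v < td.n; ++v) {
        if (!xp[td.taxon[v]]) continue;
        any = true;
        if (lca < 0) { lca = v; continue; }
        // naive pairwise LCA by upward walks
        std::vector<char> onpath(td.n, 0);
        for (int x = lca; x >= 0; x = td.parent[x]) onpath[x] = 1;
        int y = v;
        while (!onpath[y]) y = td.parent[y];
        lca = y;
      }
      if (!any) {
        if (pos[i] >= 0)
          stop("invalid position: tree %d should be empty", i + 1);
      } else {
        if (pos[i] < 0 || td.tax2node[pos[i]] != lca)
          stop("invalid position: tree %d root is not the LCA", i + 1);
      }
    }
  }

  // --- Decompose ----------------------------------------------------------

  DecompOut decompose(const std::vector<int> &pos, bool trace) {
    ++decompose_calls;
    if ((int)pos.size() != k) stop("position has wrong length");
    if (validate) check_valid_position(pos);

    // exposure bookkeeping: remove i from the unseen list of pos[i]
    for (int i = 0; i < k; ++i) {
      if (pos[i] < 0) continue;
      TreeData &td = trees[i];
      int v = td.tax2node[pos[i]];
      if (v < 0) stop("position label absent from tree");
      if (!td.seen[v]) {
        td.seen[v] = 1;
        unseen_count[pos[i]] -= 1;
      }
    }

    // occ: distinct position labels in order of first tree index
    std::vector<int> occ_tax;
    std::vector<std::vector<int>> occ_idx;
    {
      std::map<int,int> where;
      for (int i = 0; i < k; ++i) {
        if (pos[i] < 0) continue;
        auto it = where.find(pos[i]);
        if (it == where.end()) {
          where[pos[i]] = (int)occ_tax.size();
          occ_tax.push_back(pos[i]);
          occ_idx.push_back({i});
        } else {
          occ_idx[it->second].push_back(i);
        }
      }
    }

    DecompOut out;
    out.while_iters = 0;

    // S = exposed labels
    std::vector<char> inS(ntax, 0);
    std::vector<int> S;
    for (int t : occ_tax)
      if (unseen_count[t] == 0) { inS[t] = 1; S.push_back(t); }
    out.exposed = S;
    std::sort(out.exposed.begin(), out.exposed.end());

    // delete new exposed labels from the display graph (old ones skipped)
    for (int t : S) {
      if (!deleted[t]) {
        dg.delete_vertex(t);
        deleted[t] = 1;
      }
    }

    // initial blocks: group children of all position labels by component
    BlockStore bs;
    std::unordered_map<int,int> comp2blk;
    for (int i = 0; i < k; ++i) {
      if (pos[i] < 0) continue;
      auto ch = children(i, pos[i]);
      for (const int *p = ch.first; p != ch.second; ++p) {
        int c = *p;
        if (deleted[c])
          stop("internal error: child label already deleted");
        int gc = dg.comp[c];
        auto it = comp2blk.find(gc);
        int b;
        if (it == comp2blk.end()) {
          b = bs.create();
          comp2blk[gc] = b;
        } else b = it->second;
        bs.entries[b].push_back({i, c});
      }
    }
    if (trace) out.blocks0 = snapshot_blocks(bs);

    // while loop: eliminate bad labels, virtually merging blocks
    std::vector<int> blk_stamp, blk_cnt;
    std::unordered_map<int,int> bad_block; // taxon removed from S -> block
    for (;;) {
      // find bad labels: scan tree index ascending, then child order
      std::vector<int> bads;
      for (int i = 0; i < k && (bads.empty() || bad_order == "random"); ++i) {
        int a = pos[i];
        if (a < 0 || !inS[a]) continue;
        blk_stamp.assign(bs.uf.size(), 0);
        blk_cnt.assign(bs.uf.size(), 0);
        auto ch = children(i, a);
        for (const int *p = ch.first; p != ch.second; ++p) {
          int b = bs.find(block_of_child(bs, comp2blk, *p));
          if (blk_stamp[b] == 0) { blk_stamp[b] = 1; blk_cnt[b] = 1; }
          else if (++blk_cnt[b] >= 2) {
            if (std::find(bads.begin(), bads.end(), a) == bads.end())
              bads.push_back(a);
            if (bad_order != "random") break;
            break; // a is established bad in this tree; no need to scan on
          }
        }
      }
      if (bads.empty()) break;
      int bad;
      if (bad_order == "random") {
        std::uniform_int_distribution<int> pick(0, (int)bads.size() - 1);
        bad = bads[pick(rng)];
      } else bad = bads[0];
      ++out.while_iters;
      ++bad_eliminations;
      if (out.while_iters > k)
        stop("internal error: while loop exceeded k iterations");
      // merge all blocks holding a child of `bad`, over every tree where
      // the position sits at `bad`
      int target = -1;
      for (int i = 0; i < k; ++i) {
        if (pos[i] != bad) continue;
        auto ch = children(i, bad);
        for (const int *p = ch.first; p != ch.second; ++p) {
          int b = bs.find(block_of_child(bs, comp2blk, *p));
          if (target < 0) target = b;
          else if (b != bs.find(target)) bs.link(bs.find(target), b);
        }
      }
      inS[bad] = 0;
      S.erase(std::remove(S.begin(), S.end(), bad), S.end());
      if (target >= 0) bad_block[bad] = bs.find(target);
      out.bad_seq.push_back(bad);
      if (trace) {
        std::vector<int> merged;
        if (target >= 0)
          for (auto &e : bs.entries[bs.find(target)]) merged.push_back(e.second);
        std::sort(merged.begin(), merged.end());
        merged.erase(std::unique(merged.begin(), merged.end()), merged.end());
        out.merged_seq.push_back(merged);
      }
    }

    out.S = S;
    std::sort(out.S.begin(), out.S.end());

    if (S.empty()) return out; // disagreement is decided by the caller

    // live block roots, ordered by smallest child taxon for reproducibility
    std::vector<int> roots;
    for (size_t b = 0; b < bs.uf.size(); ++b)
      if (bs.find((int)b) == (int)b && !bs.entries[b].empty())
        roots.push_back((int)b);
    std::vector<int> min_tax(bs.uf.size(), ntax);
    for (int b : roots)
      for (auto &e : bs.entries[b])
        min_tax[b] = std::min(min_tax[b], e.second);
    std::sort(roots.begin(), roots.end(),
              [&](int a, int b) { return min_tax[a] < min_tax[b]; });

    if (trace) {
      for (int b : roots) {
        std::vector<int> bl;
        for (auto &e : bs.entries[b]) bl.push_back(e.second);
        std::sort(bl.begin(), bl.end());
        bl.erase(std::unique(bl.begin(), bl.end()), bl.end());
        out.final_blocks.push_back(bl);
      }
    }

    // successor positions (one per block)
    std::unordered_map<int,int> root_index;
    for (size_t j = 0; j < roots.size(); ++j) root_index[roots[j]] = (int)j;
    out.successors.assign(roots.size(), std::vector<int>(k, -1));
    for (size_t j = 0; j < roots.size(); ++j) {
      for (auto &e : bs.entries[roots[j]]) {
        int i = e.first, c = e.second;
        int a = pos[i];
        if (inS[a]) {
          if (out.successors[j][i] >= 0)
            stop("internal error: two children of an exposed label in one block");
          out.successors[j][i] = c;
        }
      }
    }
    for (int i = 0; i < k; ++i) {
      int a = pos[i];
      if (a < 0 || inS[a]) continue;
      int b;
      if (deleted[a]) {
        auto it = bad_block.find(a);
        if (it == bad_block.end())
          stop("internal error: deleted non-S label with no virtual block");
        b = bs.find(it->second);
      } else {
        auto it = comp2blk.find(dg.comp[a]);
        if (it == comp2blk.end())
          stop("internal error: component of a non-exposed label holds no child");
        b = bs.find(it->second);
      }
      auto it = root_index.find(b);
      if (it == root_index.end())
        stop("internal error: block of a carried label is not live");
      // N2: a's children (if any) must all sit in this same block
      if (validate) {
        auto ch = children(i, a);
        for (const int *p = ch.first; p != ch.second; ++p)
          if (bs.find(block_of_child(bs, comp2blk, *p)) != b)
            stop("N2 violated: children of a non-exposed label split");
      }
      out.successors[it->second][i] = a;
    }

    if (validate) check_disjoint_cover(pos, out);
    return out;
  }

  void check_disjoint_cover(const std::vector<int> &pos,
                            const DecompOut &out) const {
    std::vector<char> xp(ntax, 0);
    for (int i = 0; i < k; ++i)
      if (pos[i] >= 0) subtree_taxa(i, pos[i], xp);
    std::vector<int> cover(ntax, 0);
    for (int t : out.S) cover[t] += 1;
    for (const auto &sp : out.successors) {
      std::vector<char> sx(ntax, 0);
      for (int i = 0; i < k; ++i)
        if (sp[i] >= 0) subtree_taxa(i, sp[i], sx);
      for (int t = 0; t < ntax; ++t) cover[t] += sx[t];
    }
    for (int t = 0; t < ntax; ++t)
      if ((int)xp[t] != cover[t])
        stop("disjoint cover violated at taxon %d", t + 1);
  }

  static std::vector<std::vector<int>> snapshot_blocks(BlockStore &bs) {
    std::vector<std::vector<int>> res;
    for (size_t b = 0; b < bs.uf.size(); ++b) {
      if (bs.find((int)b) != (int)b || bs.entries[b].empty()) continue;
      std::vector<int> bl;
      for (auto &e : bs.entries[b]) bl.push_back(e.second);
      std::sort(bl.begin(), bl.end());
      bl.erase(std::unique(bl.begin(), bl.end()), bl.end());
      res.push_back(bl);
    }
    std::sort(res.begin(), res.end());
    return res;
  }

  // children stay alive for the whole call (no deletions happen after the
  // new exposed labels are removed), so the component id recorded at block
  // construction is still current; merges are tracked by the union-find
  int block_of_child(BlockStore &bs,
                     const std::unordered_map<int,int> &comp2blk,
                     int c) const {
    auto it = comp2blk.find(dg.comp[c]);
    if (it == comp2blk.end())
      throw std::runtime_error("internal error: child has no block");
    return bs.find(it->second);
  }
};

static List stats_list(const Engine *e) {
  return List::create(
      _["positions_processed"] = (double)e->positions_processed,
      _["decompose_calls"] = (double)e->decompose_calls,
      _["bad_eliminations"] = (double)e->bad_eliminations,
      _["edge_deletions"] = (double)e->dg.n_edge_del,
      _["vertex_deletions"] = (double)e->dg.n_vertex_del,
      _["max_component_moves"] =
          e->dg.move_count.empty()
              ? 0
              : *std::max_element(e->dg.move_count.begin(),
                                  e->dg.move_count.end()));
}

} // namespace

// Rcpp plumbing ------------------------------------------------------------

static Engine *get_engine(SEXP ptr) {
  XPtr<Engine> p(ptr);
  if (!p) stop("invalid engine pointer");
  return p.get();
}

// [[Rcpp::export]]
SEXP ae_create(List trees, int ntax, std::string backend, bool validate,
               std::string bad_order, int seed) {
  Engine *e = new Engine(trees, ntax, backend, validate, bad_order, seed);
  XPtr<Engine> p(e, true);
  return p;
}

static IntegerVector pos_to_r(const std::vector<int> &pos) {
  IntegerVector r(pos.size());
  for (size_t i = 0; i < pos.size(); ++i)
    r[i] = pos[i] < 0 ? NA_INTEGER : pos[i] + 1;
  return r;
}

static std::vector<int> pos_from_r(IntegerVector pos) {
  std::vector<int> p(pos.size());
  for (int i = 0; i < pos.size(); ++i)
    p[i] = pos[i] == NA_INTEGER ? -1 : pos[i] - 1;
  return p;
}

static List taxsets_to_r(const std::vector<std::vector<int>> &v) {
  List r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    IntegerVector x(v[i].size());
    for (size_t j = 0; j < v[i].size(); ++j) x[j] = v[i][j] + 1;
    r[i] = x;
  }
  return r;
}

// [[Rcpp::export]]
IntegerVector ae_initial_position(SEXP ptr) {
  return pos_to_r(get_engine(ptr)->initial_position());
}

// [[Rcpp::export]]
List ae_decompose(SEXP ptr, IntegerVector position) {
  Engine *e = get_engine(ptr);
  DecompOut d = e->decompose(pos_from_r(position), true);
  List succ(d.successors.size());
  for (size_t i = 0; i < d.successors.size(); ++i)
    succ[i] = pos_to_r(d.successors[i]);
  IntegerVector S(d.S.size()), S0(d.exposed.size()), bad(d.bad_seq.size());
  for (size_t i = 0; i < d.S.size(); ++i) S[i] = d.S[i] + 1;
  for (size_t i = 0; i < d.exposed.size(); ++i) S0[i] = d.exposed[i] + 1;
  for (size_t i = 0; i < d.bad_seq.size(); ++i) bad[i] = d.bad_seq[i] + 1;
  return List::create(
      _["exposed"] = S0, _["blocks_initial"] = taxsets_to_r(d.blocks0),
      _["bad_labels"] = bad, _["merged_blocks"] = taxsets_to_r(d.merged_seq),
      _["S"] = S, _["blocks_final"] = taxsets_to_r(d.final_blocks),
      _["successors"] = succ, _["while_iters"] = d.while_iters);
}

// [[Rcpp::export]]
List ae_build(SEXP ptr, std::string queue_order) {
  Engine *e = get_engine(ptr);
  if (e->build_used) stop("engine already used for a build; create a fresh one");
  e->build_used = true;
  bool lifo = queue_order == "lifo";

  struct QItem { std::vector<int> pos; int pred; };
  std::deque<QItem> queue;
  queue.push_back({e->initial_position(), -1});

  std::vector<int> node_parent;
  std::vector<std::vector<int>> node_taxa;
  long long guard = 0;

  while (!queue.empty()) {
    QItem it;
    if (lifo) { it = queue.back(); queue.pop_back(); }
    else { it = queue.front(); queue.pop_front(); }
    ++e->positions_processed;
    if (++guard > 2LL * e->ntax + 2)
      stop("internal error: more positions than twice the taxon count");
    DecompOut d = e->decompose(it.pos, false);
    if (d.S.empty()) {
      return List::create(_["status"] = "DISAGREES",
                          _["conflict_position"] = pos_to_r(it.pos),
                          _["stats"] = stats_list(e));
    }
    int nid = (int)node_parent.size();
    node_parent.push_back(it.pred);
    node_taxa.push_back(d.S);
    for (auto &sp : d.successors) queue.push_back({sp, nid});
  }

  if ((long long)node_parent.size() > (long long)e->ntax)
    stop("internal error: output has more nodes than taxa");

  IntegerVector par(node_parent.size());
  for (size_t i = 0; i < node_parent.size(); ++i)
    par[i] = node_parent[i] + 1; // 0 = root sentinel
  return List::create(_["status"] = "AGREES", _["parent"] = par,
                      _["taxa"] = taxsets_to_r(node_taxa),
                      _["stats"] = stats_list(e));
}

// [[Rcpp::export]]
List ae_stats(SEXP ptr) { return stats_list(get_engine(ptr)); }
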