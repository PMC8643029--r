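#include <Rcpp.h>
#include "display.h"

using namespace Rcpp;

// Stand-alone handle to a display graph, used by the R-level API and the
// connectivity test suite.  Vertices are 1-based taxon ids on the R side.

static DisplayGraph *get_dg(SEXP ptr) {
  XPtr<DisplayGraph> p(ptr);
  if (!p) stop("invalid display graph pointer");
  return p.get();
}

// [[Rcpp::export]]
SEXP dg_create(int nv, IntegerMatrix edges, bool forest) {
  std::vector<std::pair<int,int>> ev;
  for (int i = 0; i < edges.nrow(); ++i) {
    int a = edges(i, 0) - 1, b = edges(i, 1) - 1;
    if (a < 0 || b < 0 || a >= nv || b >= nv) stop("edge endpoint out of range");
    ev.emplace_back(std::min(a, b), std::max(a, b));
  }
  std::sort(ev.begin(), ev.end());
  ev.erase(std::unique(ev.begin(), ev.end()), ev.end());
  DisplayGraph *g = new DisplayGraph(nv, ev, forest);
  XPtr<DisplayGraph> p(g, true);
  return p;
}

// [[Rcpp::export]]
List dg_delete_exposed(SEXP ptr, IntegerVector labels) {
  DisplayGraph *g = get_dg(ptr);
  size_t log_from = g->split_log.size();
  for (int i = 0; i < labels.size(); ++i) {
    int v = labels[i] - 1;
    if (v < 0 || v >= g->nv) stop("label out of range");
    if (!g->alive[v])
      stop("delete_exposed: label %d already deleted", labels[i]);
    g->delete_vertex(v);
  }
  List splits(g->split_log.size() - log_from);
  for (size_t j = log_from; j < g->split_log.size(); ++j) {
    const SplitEvent &ev = g->split_log[j];
    IntegerVector moved(ev.moved.size());
    for (size_t m = 0; m < ev.moved.size(); ++m) moved[m] = ev.moved[m] + 1;
    splits[j - log_from] =
        List::create(_["from"] = ev.from_comp + 1, _["to"] = ev.new_comp + 1,
                     _["moved"] = moved);
  }
  return splits;
}

// [[Rcpp::export]]
IntegerVector dg_components(SEXP ptr) {
  DisplayGraph *g = get_dg(ptr);
  IntegerVector comp(g->nv);
  for (int v = 0; v < g->nv; ++v)
    comp[v] = g->alive[v] ? g->comp[v] + 1 : NA_INTEGER;
  return comp;
}

// [[Rcpp::export]]
int dg_component_of(SEXP ptr, int v) {
  DisplayGraph *g = get_dg(ptr);
  if (v < 1 || v > g->nv) stop("label out of range");
  if (!g->alive[v - 1]) stop("component_of: label %d is deleted", v);
  return g->comp[v - 1] + 1;
}

// [[Rcpp::export]]
IntegerVector dg_move_counts(SEXP ptr) {
  DisplayGraph *g = get_dg(ptr);
  IntegerVector mc(g->nv);
  for (int v = 0; v < g->nv; ++v) mc[v] = g->move_count[v];
  return mc;
}

// [[Rcpp::export]]
List dg_stats(SEXP ptr) {
  DisplayGraph *g = get_dg(ptr);
  int nalive = 0;
  for (int v = 0; v < g->nv; ++v) nalive += g->alive[v] ? 1 : 0;
  return List::create(_["n_vertices"] = g->nv, _["n_alive"] = nalive,
                      _["edge_deletions"] = (double)g->n_edge_del,
                      _["vertex_deletions"] = (double)g->n_vertex_del);
}
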