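#include <Rcpp.h>
using namespace Rcpp;

// Multispecies-coalescent genealogy sampling within an ultrametric species
// tree (branch lengths in coalescent units). Lineages entering a
// species-tree branch coalesce at rate k(k-1)/2 per unit time, pairs chosen
// uniformly; survivors are pooled at the parent node and everything merges
// above the root. Uses R's RNG so draws are reproducible under set.seed().

struct LinSet {
  std::vector<int> id;     // gene-tree node id (1-based)
  std::vector<double> h;   // height (time before present) of the node
};

static void coal_interval(LinSet &s, double t0, double t1, int &next_id,
                          std::vector<int> &par, std::vector<int> &chl,
                          std::vector<double> &len) {
  double t = t0;
  while (s.id.size() >= 2) {
    int k = (int)s.id.size();
    double rate = 0.5 * k * (k - 1);
    t += R::rexp(1.0 / rate);
    if (t >= t1) break;
    int i = (int)(unif_rand() * k);
    int j = (int)(unif_rand() * (k - 1));
    if (j >= i) ++j;
    int node = ++next_id;
    par.push_back(node); chl.push_back(s.id[i]); len.push_back(t - s.h[i]);
    par.push_back(node); chl.push_back(s.id[j]); len.push_back(t - s.h[j]);
    // replace i with the merged lineage, drop j
    s.id[i] = node; s.h[i] = t;
    s.id[j] = s.id.back(); s.h[j] = s.h.back();
    s.id.pop_back(); s.h.pop_back();
  }
}

// One genealogy. `order` lists internal species-tree nodes with every child
// before its parent (root last); `children` maps node id -> child ids;
// `tip_lineages` maps species-tree tip -> gene-tip ids present at that tip
// (possibly empty after dropout). Returns an ape-style edge matrix with
// gene tips 1..nl and the root numbered nl+1.
// [[Rcpp::export(name = ".msc_draw_edges")]]
List msc_draw_edges(IntegerVector order, List children,
                    NumericVector height, List tip_lineages) {
  int n_sp_nodes = height.size();
  int ntip_sp = tip_lineages.size();
  std::vector<LinSet> sets(n_sp_nodes + 1);
  int nl = 0;
  for (int i = 0; i < ntip_sp; ++i) {
    IntegerVector ids = tip_lineages[i];
    for (int j = 0; j < ids.size(); ++j) {
      sets[i + 1].id.push_back(ids[j]);
      sets[i + 1].h.push_back(0.0);
      ++nl;
    }
  }
  if (nl < 2) stop("need at least 2 lineages");
  std::vector<int> par, chl;
  std::vector<double> len;
  par.reserve(2 * nl); chl.reserve(2 * nl); len.reserve(2 * nl);
  int next_id = nl;
  int root_sp = order[order.size() - 1];
  for (int oi = 0; oi < order.size(); ++oi) {
    int v = order[oi];
    IntegerVector ch = children[v - 1];
    for (int ci = 0; ci < ch.size(); ++ci) {
      int u = ch[ci];
      coal_interval(sets[u], height[u - 1], height[v - 1], next_id,
                    par, chl, len);
      LinSet &su = sets[u], &sv = sets[v];
      sv.id.insert(sv.id.end(), su.id.begin(), su.id.end());
      sv.h.insert(sv.h.end(), su.h.begin(), su.h.end());
      su.id.clear(); su.h.clear();
    }
  }
  coal_interval(sets[root_sp], height[root_sp - 1], R_PosInf, next_id,
                par, chl, len);
  // relabel internal ids so the root (created last) becomes nl + 1
  int ne = (int)par.size();
  IntegerMatrix edge(ne, 2);
  NumericVector elen(ne);
  for (int e = 0; e < ne; ++e) {
    int p = par[e], c = chl[e];
    edge(e, 0) = 3 * nl - p;
    edge(e, 1) = c > nl ? 3 * nl - c : c;
    elen[e] = len[e];
  }
  return List::create(_["edge"] = edge, _["edge.length"] = elen,
                      _["nl"] = nl);
}
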