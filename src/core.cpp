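#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Max-tree of upper level sets {I >= t} built by immersion (t = 255 .. 0),
// union-find with per-root canonical tree node. Bright-on-dark polarity only.
// Nodes record (level, area, parent); same-level absorptions are marked as
// aliases so each (component, level) pair is emitted at most once.

struct MaxTree {
  std::vector<int> level, parent, area;
  std::vector<bool> alias;
  int add(int lev) {
    level.push_back(lev); parent.push_back(-1); area.push_back(0);
    alias.push_back(false);
    return (int)level.size() - 1;
  }
};

static int uf_find(std::vector<int>& uf, int x) {
  int r = x;
  while (uf[r] != r) r = uf[r];
  while (uf[x] != r) { int nx = uf[x]; uf[x] = r; x = nx; }
  return r;
}

// [[Rcpp::export]]
List cpp_mser(IntegerMatrix img, int delta, double max_variation,
              int min_area, int max_area, double min_diversity,
              bool debug = false) {
  const int h = img.nrow(), w = img.ncol(), n = h * w;
  std::vector<std::vector<int> > buckets(256);
  for (int p = 0; p < n; ++p) {
    int v = img[p];
    if (v < 0) v = 0; if (v > 255) v = 255;
    buckets[v].push_back(p);
  }
  std::vector<int> uf(n, -1);            // -1: pixel not yet immersed
  std::vector<int> root_node(n, -1);     // canonical node of a uf root
  std::vector<int> pix_node(n, -1);      // node a pixel was added under
  MaxTree t;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};

  for (int lev = 255; lev >= 0; --lev) {
    for (size_t bi = 0; bi < buckets[lev].size(); ++bi) {
      int p = buckets[lev][bi];
      uf[p] = p;
      int np = t.add(lev); t.area[np] = 1;
      root_node[p] = np; pix_node[p] = np;
      int r = p, c = p / h, rr = p % h;
      for (int k = 0; k < 4; ++k) {
        int r2 = rr + dr[k], c2 = c + dc[k];
        if (r2 < 0 || r2 >= h || c2 < 0 || c2 >= w) continue;
        int q = c2 * h + r2;
        if (uf[q] < 0) continue;
        int ra = uf_find(uf, r), rb = uf_find(uf, q);
        if (ra == rb) continue;
        int na = root_node[ra], nb = root_node[rb];
        // union by size of components
        int rnew;
        if (t.area[na] >= t.area[nb]) { uf[rb] = ra; rnew = ra; }
        else { uf[ra] = rb; rnew = rb; }
        int nnew;
        bool a_at = (t.level[na] == lev), b_at = (t.level[nb] == lev);
        if (a_at && b_at) {
          nnew = (t.area[na] >= t.area[nb]) ? na : nb;
          int other = (nnew == na) ? nb : na;
          t.area[nnew] += t.area[other];
          t.parent[other] = nnew;
          t.alias[other] = true;
        } else if (a_at || b_at) {
          nnew = a_at ? na : nb;
          int other = a_at ? nb : na;
          t.area[nnew] += t.area[other];
          t.parent[other] = nnew;
        } else {
          nnew = t.add(lev);
          t.area[nnew] = t.area[na] + t.area[nb];
          t.parent[na] = nnew; t.parent[nb] = nnew;
        }
        root_node[rnew] = nnew;
        r = rnew;
      }
    }
  }

  int nn = (int)t.level.size();
  // stability variation: compare with the component delta levels up
  std::vector<double> var(nn, 0.0);
  std::vector<bool> cand(nn, false);
  for (int i = 0; i < nn; ++i) {
    if (t.alias[i]) continue;
    int cur = i, tgt = t.level[i] - delta;
    while (t.parent[cur] != -1 && t.level[t.parent[cur]] >= tgt)
      cur = t.parent[cur];
    var[i] = (double)(t.area[cur] - t.area[i]) / (double)t.area[i];
    cand[i] = (var[i] < max_variation &&
               t.area[i] >= min_area && t.area[i] <= max_area);
  }
  // min-diversity pruning along branches (keep the more stable of near-equal
  // nested pairs), ascending area so children are visited first
  std::vector<int> order;
  for (int i = 0; i < nn; ++i) if (cand[i]) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return t.area[a] < t.area[b] ||
                                       (t.area[a] == t.area[b] && a < b); });
  for (size_t oi = 0; oi < order.size(); ++oi) {
    int i = order[oi];
    while (cand[i]) {
      int a = t.parent[i];
      while (a != -1 && !cand[a]) a = t.parent[a];
      if (a == -1) break;
      double div = (double)(t.area[a] - t.area[i]) / (double)t.area[a];
      if (div >= min_diversity) break;
      if (var[i] <= var[a]) cand[a] = false;   // recompare i upward
      else cand[i] = false;
    }
  }
  // collapse to <= 2 levels. Build the selected forest (nearest selected
  // ancestor links); per selected root keep the root as lower and, as uppers,
  // its descendants after recursively decomposing any node that splits into
  // two or more disjoint selected sub-descendants (touching-nucleus clumps
  // decompose; a nucleus over its bright core does not). Other selected
  // nodes are absorbed into their nearest kept ancestor.
  std::vector<int> selpar(nn, -1);
  std::vector<std::vector<int> > selkids(nn);
  std::vector<int> roots;
  for (int i = 0; i < nn; ++i) {
    if (!cand[i]) continue;
    int a = t.parent[i];
    while (a != -1 && !cand[a]) a = t.parent[a];
    selpar[i] = a;
    if (a == -1) roots.push_back(i); else selkids[a].push_back(i);
  }
  if (debug) {
    std::vector<int> dl, da, dp;
    std::vector<double> dv;
    for (int i = 0; i < nn; ++i) {
      if (!cand[i]) continue;
      dl.push_back(t.level[i]); da.push_back(t.area[i]);
      dv.push_back(var[i]); dp.push_back(selpar[i]);
    }
    return List::create(_["level"] = dl, _["area"] = da, _["var"] = dv,
                        _["selpar"] = dp);
  }
  std::vector<int> kind(nn, 0);  // 0 drop, 1 single, 2 lower, 3 upper
  std::vector<int> selp(nn, -1); // upper -> its lower
  // iterative "pick": expand nodes with >= 2 selected children
  for (size_t ri = 0; ri < roots.size(); ++ri) {
    int r = roots[ri];
    if (selkids[r].empty()) { kind[r] = 1; continue; }
    kind[r] = 2;
    std::vector<int> frontier = selkids[r], uppers;
    while (!frontier.empty()) {
      int x = frontier.back(); frontier.pop_back();
      // walk single-child chains: a node over its own refinement is one
      // object; only a genuine branch point splits it
      int y = x;
      while (selkids[y].size() == 1) y = selkids[y][0];
      if (selkids[y].size() >= 2) {
        for (size_t kj = 0; kj < selkids[y].size(); ++kj)
          frontier.push_back(selkids[y][kj]);
      } else {
        uppers.push_back(x);   // keep the top of the chain (largest extent)
      }
    }
    for (size_t kj = 0; kj < uppers.size(); ++kj) {
      kind[uppers[kj]] = 3;
      selp[uppers[kj]] = r;
    }
  }

  std::vector<int> keep;
  for (int i = 0; i < nn; ++i) if (kind[i] >= 1) keep.push_back(i);
  std::vector<int> out_id(nn, -1);
  // lowers and singles first, then uppers, deterministic by node index
  int nid = 0;
  for (size_t k = 0; k < keep.size(); ++k)
    if (kind[keep[k]] != 3) out_id[keep[k]] = nid++;
  for (size_t k = 0; k < keep.size(); ++k)
    if (kind[keep[k]] == 3) out_id[keep[k]] = nid++;

  std::vector<std::vector<int> > pix(nid);
  for (int p = 0; p < n; ++p) {
    int cur = pix_node[p];
    while (cur != -1) {
      if (out_id[cur] >= 0) pix[out_id[cur]].push_back(p + 1);
      cur = t.parent[cur];
    }
  }
  CharacterVector lev_out(nid);
  IntegerVector par_out(nid);
  List px(nid);
  for (size_t k = 0; k < keep.size(); ++k) {
    int i = keep[k], id = out_id[i];
    lev_out[id] = (kind[i] == 1) ? "single" : (kind[i] == 2 ? "lower" : "upper");
    par_out[id] = (kind[i] == 3) ? out_id[selp[i]] + 1 : NA_INTEGER;
    std::sort(pix[id].begin(), pix[id].end());
    px[id] = IntegerVector(pix[id].begin(), pix[id].end());
  }
  return List::create(_["pixels"] = px, _["level"] = lev_out,
                      _["parent"] = par_out);
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<int> stack;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nd = (connectivity == 8) ? 8 : 4;
  for (int c = 0; c < w; ++c) for (int r = 0; r < h; ++r) {
    if (!mask(r, c) || lab(r, c) != 0) continue;
    ++next;
    stack.clear(); stack.push_back(c * h + r);
    lab(r, c) = next;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int pr = p % h, pc = p / h;
      for (int k = 0; k < nd; ++k) {
        int r2 = pr + dr8[k], c2 = pc + dc8[k];
        if (r2 < 0 || r2 >= h || c2 < 0 || c2 >= w) continue;
        if (mask(r2, c2) && lab(r2, c2) == 0) {
          lab(r2, c2) = next;
          stack.push_back(c2 * h + r2);
        }
      }
    }
  }
  return lab;
}
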