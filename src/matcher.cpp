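#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Backtracking subgraph-isomorphism matcher (VF2-style search tree) whose
// per-vertex semantic test is membership in a precomputed candidate set
// (either label-only compatibility or the locality compatibility map).
// Non-induced semantics: every query edge must map onto a target edge;
// query non-edges impose no constraint.
//
// States counts the assignments (v -> u) that pass all feasibility checks,
// i.e. the nodes of the explored search tree below the root.

namespace {

struct Matcher {
  int nq, ng;
  std::vector<std::vector<int> > qa, ga, cand;
  std::vector<int> mapq, order;
  std::vector<char> usedT, matchedQ;
  bool fixedOrder, firstOnly;
  long long maxMatches, states;
  std::vector<std::vector<int> > out;

  bool hasEdge(int a, int b) const {
    return std::binary_search(ga[a].begin(), ga[a].end(), b);
  }

  int chooseNext(int depth) const {
    int best = -1;
    long long bestAvail = -1;
    for (int v = 0; v < nq; ++v) {
      if (matchedQ[v]) continue;
      if (depth > 0) {
        bool adjMatched = false;
        for (size_t k = 0; k < qa[v].size(); ++k)
          if (matchedQ[qa[v][k]]) { adjMatched = true; break; }
        if (!adjMatched) continue;
      }
      long long avail = 0;
      for (size_t k = 0; k < cand[v].size(); ++k)
        if (!usedT[cand[v][k]]) ++avail;
      if (best < 0 || avail < bestAvail) { best = v; bestAvail = avail; }
    }
    return best;  // -1 only for disconnected queries (rejected upstream)
  }

  bool search(int depth) {
    if (depth == nq) {
      out.push_back(mapq);
      return firstOnly || (long long)out.size() >= maxMatches;
    }
    int v = fixedOrder ? order[depth] : chooseNext(depth);
    if (v < 0) stop("query graph is disconnected");
    for (size_t k = 0; k < cand[v].size(); ++k) {
      int u = cand[v][k];
      if (usedT[u]) continue;
      bool ok = true;
      for (size_t j = 0; j < qa[v].size(); ++j) {
        int w = qa[v][j];
        if (mapq[w] >= 0 && !hasEdge(mapq[w], u)) { ok = false; break; }
      }
      if (!ok) continue;
      ++states;
      mapq[v] = u;
      usedT[u] = 1;
      matchedQ[v] = 1;
      bool done = search(depth + 1);
      mapq[v] = -1;
      usedT[u] = 0;
      matchedQ[v] = 0;
      if (done) return true;
    }
    return false;
  }
};

void fillAdj(List src, std::vector<std::vector<int> >& dst) {
  int n = src.size();
  dst.resize(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = src[i];
    dst[i].assign(nb.begin(), nb.end());
    std::sort(dst[i].begin(), dst[i].end());
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_match(List qadj, List gadj, List candList, bool firstOnly,
               double maxMatches, IntegerVector order) {
  Matcher M;
  fillAdj(qadj, M.qa);
  fillAdj(gadj, M.ga);
  M.nq = M.qa.size();
  M.ng = M.ga.size();
  M.cand.resize(M.nq);
  for (int v = 0; v < M.nq; ++v) {
    IntegerVector cv = candList[v];
    M.cand[v].assign(cv.begin(), cv.end());
    std::sort(M.cand[v].begin(), M.cand[v].end());
  }
  M.mapq.assign(M.nq, -1);
  M.usedT.assign(M.ng, 0);
  M.matchedQ.assign(M.nq, 0);
  M.fixedOrder = order.size() > 0;
  if (M.fixedOrder) {
    if ((int)order.size() != M.nq) stop("vertex order must cover the query");
    M.order.assign(order.begin(), order.end());
  }
  M.firstOnly = firstOnly;
  M.maxMatches = (maxMatches <= 0 || !R_finite(maxMatches))
                     ? -1
                     : (long long)maxMatches;
  if (M.maxMatches < 0) M.maxMatches = (long long)1 << 62;
  M.states = 0;
  if (M.nq > 0) M.search(0);
  List matches(M.out.size());
  for (size_t i = 0; i < M.out.size(); ++i)
    matches[i] = IntegerVector(M.out[i].begin(), M.out[i].end());
  return List::create(_["matches"] = matches,
                      _["states"] = (double)M.states);
}
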