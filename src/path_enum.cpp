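#include <Rcpp.h>
#include <map>
#include <set>
#include <string>
#include <vector>
using namespace Rcpp;

// Bounded-length simple-path enumeration over a node-labeled undirected
// graph. A feature key is the sequence of vertex labels along a simple path,
// joined by a single space (labels come from whitespace-delimited transaction
// files, so the separator cannot occur inside a label). Occurrences are
// directed traversals: an undirected path is visited once from each endpoint.
//
// Bitset packing: bit v lives in byte v >> 3 at position v & 7, matching
// R's packBits()/rawToBits() layout.

namespace {

struct FeatRec {
  int count = 0;
  std::vector<unsigned char> start;  // packed start-vertex bitset
};

struct Enumerator {
  int n, lp, nbytes;
  std::vector<std::string> labels;
  std::vector<std::vector<int> > adj;
  std::vector<char> visited;

  Enumerator(CharacterVector labs, List adjList, int lp_) : lp(lp_) {
    n = labs.size();
    nbytes = (n + 7) / 8;
    labels.reserve(n);
    for (int i = 0; i < n; ++i) labels.push_back(as<std::string>(labs[i]));
    adj.resize(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector nb = adjList[i];
      adj[i].assign(nb.begin(), nb.end());
    }
    visited.assign(n, 0);
  }

  bool extendable(int last, int depth) const {
    if (depth >= lp) return false;
    for (size_t k = 0; k < adj[last].size(); ++k)
      if (!visited[adj[last][k]]) return true;
    return false;
  }
};

// full enumeration: every prefix is an occurrence
void dfsAll(Enumerator& E, int start, int last, int depth, std::string& key,
            std::map<std::string, FeatRec>& feats) {
  FeatRec& rec = feats[key];
  rec.count += 1;
  if (rec.start.empty()) rec.start.assign(E.nbytes, 0);
  rec.start[start >> 3] |= (unsigned char)(1u << (start & 7));
  if (depth >= E.lp) return;
  for (size_t k = 0; k < E.adj[last].size(); ++k) {
    int u = E.adj[last][k];
    if (E.visited[u]) continue;
    E.visited[u] = 1;
    size_t keep = key.size();
    key += ' ';
    key += E.labels[u];
    dfsAll(E, start, u, depth + 1, key, feats);
    key.resize(keep);
    E.visited[u] = 0;
  }
}

// terminal-only enumeration: record occurrences that cannot be extended
// (depth limit reached or dead end); used for query feature extraction
void dfsTerminal(Enumerator& E, int start, int last, int depth,
                 std::string& key, std::map<std::string, int>& fq,
                 std::set<std::string>& fvqv) {
  if (!E.extendable(last, depth)) {
    fq[key] += 1;
    fvqv.insert(key);
    return;
  }
  for (size_t k = 0; k < E.adj[last].size(); ++k) {
    int u = E.adj[last][k];
    if (E.visited[u]) continue;
    E.visited[u] = 1;
    size_t keep = key.size();
    key += ' ';
    key += E.labels[u];
    dfsTerminal(E, start, u, depth + 1, key, fq, fvqv);
    key.resize(keep);
    E.visited[u] = 0;
  }
}

void dfsList(Enumerator& E, int start, int last, int depth, std::string& key,
             std::vector<std::string>& keys, std::vector<int>& term) {
  keys.push_back(key);
  term.push_back(E.extendable(last, depth) ? 0 : 1);
  if (depth >= E.lp) return;
  for (size_t k = 0; k < E.adj[last].size(); ++k) {
    int u = E.adj[last][k];
    if (E.visited[u]) continue;
    E.visited[u] = 1;
    size_t keep = key.size();
    key += ' ';
    key += E.labels[u];
    dfsList(E, start, u, depth + 1, key, keys, term);
    key.resize(keep);
    E.visited[u] = 0;
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_enumerate_features(CharacterVector labels, List adjList, int lp) {
  Enumerator E(labels, adjList, lp);
  std::map<std::string, FeatRec> feats;
  std::string key;
  for (int v = 0; v < E.n; ++v) {
    E.visited[v] = 1;
    key = E.labels[v];
    dfsAll(E, v, v, 1, key, feats);
    E.visited[v] = 0;
  }
  int nf = feats.size();
  CharacterVector fnames(nf);
  IntegerVector counts(nf);
  List starts(nf);
  int i = 0;
  for (std::map<std::string, FeatRec>::iterator it = feats.begin();
       it != feats.end(); ++it, ++i) {
    fnames[i] = it->first;
    counts[i] = it->second.count;
    RawVector rv(E.nbytes);
    std::copy(it->second.start.begin(), it->second.start.end(), rv.begin());
    starts[i] = rv;
  }
  return List::create(_["features"] = fnames, _["counts"] = counts,
                      _["starts"] = starts);
}

// [[Rcpp::export]]
List cpp_query_features(CharacterVector labels, List adjList, int lp) {
  Enumerator E(labels, adjList, lp);
  std::map<std::string, int> fq;
  std::vector<std::set<std::string> > fvq(E.n);
  std::string key;
  for (int v = 0; v < E.n; ++v) {
    E.visited[v] = 1;
    key = E.labels[v];
    dfsTerminal(E, v, v, 1, key, fq, fvq[v]);
    E.visited[v] = 0;
  }
  int nf = fq.size();
  CharacterVector fnames(nf);
  IntegerVector counts(nf);
  int i = 0;
  for (std::map<std::string, int>::iterator it = fq.begin(); it != fq.end();
       ++it, ++i) {
    fnames[i] = it->first;
    counts[i] = it->second;
  }
  List fvqOut(E.n);
  for (int v = 0; v < E.n; ++v) {
    CharacterVector fs(fvq[v].size());
    int j = 0;
    for (std::set<std::string>::iterator it = fvq[v].begin();
         it != fvq[v].end(); ++it, ++j)
      fs[j] = *it;
    fvqOut[v] = fs;
  }
  return List::create(_["features"] = fnames, _["counts"] = counts,
                      _["fvq"] = fvqOut);
}

// [[Rcpp::export]]
List cpp_start_paths(CharacterVector labels, List adjList, int lp, int v) {
  Enumerator E(labels, adjList, lp);
  if (v < 0 || v >= E.n) stop("start vertex out of range");
  std::vector<std::string> keys;
  std::vector<int> term;
  std::string key = E.labels[v];
  E.visited[v] = 1;
  dfsList(E, v, v, 1, key, keys, term);
  E.visited[v] = 0;
  return List::create(_["feature"] = wrap(keys),
                      _["terminal"] = LogicalVector(term.begin(), term.end()));
}
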