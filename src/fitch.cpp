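#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Fitch small-parsimony score over a (possibly multifurcating) tree.
//
// `edge` is the two-column edge matrix of an ape "phylo" object in postorder
// (every edge below a node precedes the edge above it), `tip_states` holds one
// row per tip (tip i = node id i) of bitmask-encoded states
// (A=1, C=2, G=4, T=8; missing/ambiguous = union of bits), one column per site
// pattern, and `weights` gives the multiplicity of each pattern.
//
// [[Rcpp::export]]
double fitch_score_cpp(IntegerMatrix edge, IntegerMatrix tip_states,
                       NumericVector weights) {
  const int nsite = tip_states.ncol();
  const int ntip = tip_states.nrow();
  if (weights.size() != nsite) stop("weights length must match site count");
  int maxnode = 0;
  for (int i = 0; i < edge.nrow(); ++i) {
    if (edge(i, 0) > maxnode) maxnode = edge(i, 0);
    if (edge(i, 1) > maxnode) maxnode = edge(i, 1);
  }
  std::vector<int> S((size_t)maxnode * nsite, 0);
  std::vector<char> seen((size_t)maxnode + 1, 0);
  for (int t = 0; t < ntip; ++t) {
    int* row = &S[(size_t)t * nsite];
    for (int s = 0; s < nsite; ++s) {
      int v = tip_states(t, s);
      if (v < 1 || v > 15) stop("tip states must be bitmasks in 1..15");
      row[s] = v;
    }
    seen[t + 1] = 1;
  }
  double score = 0.0;
  for (int i = 0; i < edge.nrow(); ++i) {
    const int p = edge(i, 0), c = edge(i, 1);
    if (!seen[c]) stop("edge matrix is not in postorder");
    int* Sp = &S[(size_t)(p - 1) * nsite];
    const int* Sc = &S[(size_t)(c - 1) * nsite];
    if (!seen[p]) {
      std::memcpy(Sp, Sc, sizeof(int) * nsite);
      seen[p] = 1;
    } else {
      for (int s = 0; s < nsite; ++s) {
        const int inter = Sp[s] & Sc[s];
        if (inter) {
          Sp[s] = inter;
        } else {
          Sp[s] |= Sc[s];
          score += weights[s];
        }
      }
    }
  }
  return score;
}

// Score many trees (a list of postorder edge matrices) against one state
// matrix; used by the exhaustive-search oracle.
//
// [[Rcpp::export]]
NumericVector fitch_score_many_cpp(List edges, IntegerMatrix tip_states,
                                   NumericVector weights) {
  const int n = edges.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerMatrix e = edges[i];
    out[i] = fitch_score_cpp(e, tip_states, weights);
  }
  return out;
}
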