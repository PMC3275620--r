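#include <Rcpp.h>
using namespace Rcpp;

// Per-locus minimum change counts for binary characters on a rooted tree,
// computed as unit-cost Sankoff dynamic programming over two states. Exact
// for multifurcating nodes as well as binary ones.
//
// edge: (parent, child) rows in postorder (every child's subtree precedes the
//       edge to its parent); 1-based node ids, tips 1..nTip.
// tipCodes: nTip x nLoci, rows ordered by tip id; 1 = band absent, 2 = band
//       present, 3 = missing (fully ambiguous).
// [[Rcpp::export(name = ".fitchStepsC")]]
IntegerVector fitch_steps_c(IntegerMatrix edge, IntegerMatrix tipCodes,
                            int nNode) {
  const int nTip = tipCodes.nrow();
  const int nLoci = tipCodes.ncol();
  const int nTotal = nTip + nNode;
  const int BIG = 1 << 28;

  std::vector<int> c0((size_t)nTotal * nLoci, 0);
  std::vector<int> c1((size_t)nTotal * nLoci, 0);

  for (int t = 0; t < nTip; ++t) {
    const size_t off = (size_t)t * nLoci;
    for (int l = 0; l < nLoci; ++l) {
      const int code = tipCodes(t, l);
      if (code == 1) {          // absent observed
        c1[off + l] = BIG;
      } else if (code == 2) {   // present observed
        c0[off + l] = BIG;
      } else if (code != 3) {
        stop("invalid tip state code (must be 1, 2 or 3)");
      }
    }
  }

  const int nEdge = edge.nrow();
  for (int e = 0; e < nEdge; ++e) {
    const int p = edge(e, 0) - 1;
    const int c = edge(e, 1) - 1;
    if (p < 0 || p >= nTotal || c < 0 || c >= nTotal)
      stop("edge matrix refers to a node id out of range");
    const size_t po = (size_t)p * nLoci;
    const size_t co = (size_t)c * nLoci;
    for (int l = 0; l < nLoci; ++l) {
      const int a0 = c0[co + l];
      const int a1 = c1[co + l];
      const int m0 = a0 < a1 + 1 ? a0 : a1 + 1;
      const int m1 = a1 < a0 + 1 ? a1 : a0 + 1;
      c0[po + l] += m0 > BIG ? BIG : m0;
      c1[po + l] += m1 > BIG ? BIG : m1;
    }
  }

  const int root = edge(nEdge - 1, 0) - 1;
  const size_t ro = (size_t)root * nLoci;
  IntegerVector steps(nLoci);
  for (int l = 0; l < nLoci; ++l) {
    int s = std::min(c0[ro + l], c1[ro + l]);
    steps[l] = s >= BIG ? 0 : s;
  }
  return steps;
}
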