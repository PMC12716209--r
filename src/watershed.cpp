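#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// Seeded watershed by priority flooding (Meyer). Pixels are flooded in order
// of increasing elevation, starting from the seed pixels; each unlabeled
// in-mask 4-neighbour inherits the label of its first claimant, so every
// boundary pixel ends up in exactly one region. FIFO tie-breaking on equal
// elevation makes the result deterministic for a given seed image.
//
// elev:  elevation surface (flood fills low values first)
// seeds: integer matrix, 0 = unseeded, k > 0 = seed for label k
// mask:  logical matrix; pixels outside the mask are never labeled
// [[Rcpp::export(name = ".ws_flood")]]
IntegerMatrix ws_flood(NumericMatrix elev, IntegerMatrix seeds,
                       LogicalMatrix mask) {
  const int nr = elev.nrow(), nc = elev.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("elevation, seeds and mask must share the same shape");

  IntegerMatrix lab(nr, nc);

  struct Node {
    double h;
    long long ord;
    int i, j, l;
  };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.h != b.h) return a.h > b.h;   // min-heap on elevation
      return a.ord > b.ord;               // FIFO among equal elevations
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long long ord = 0;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0 && mask(i, j)) {
        lab(i, j) = seeds(i, j);
        pq.push({elev(i, j), ord++, i, j, seeds(i, j)});
      }

  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Node n = pq.top();
    pq.pop();
    for (int d = 0; d < 4; ++d) {
      const int ii = n.i + di[d], jj = n.j + dj[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!mask(ii, jj) || lab(ii, jj) > 0) continue;
      lab(ii, jj) = n.l;
      pq.push({std::max(elev(ii, jj), n.h), ord++, ii, jj, n.l});
    }
  }
  return lab;
}
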