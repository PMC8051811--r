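#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Neighbour offsets; first 4 are the 4-connected ones.
static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Connected-component labelling of a binary mask.
// Labels are assigned in row-major order of first encounter, so the result
// is deterministic and already sequential (1..K).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol(), nn = connectivity;
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + DR[k], c2 = cc + DC[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

struct WsNode {
  double height;   // distance-transform value: flood high values first
  long order;      // insertion counter: FIFO tie-break for determinism
  int idx;
};

struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.height != b.height) return a.height < b.height;  // max-heap on height
    return a.order > b.order;                              // FIFO on ties
  }
};

// Marker-based watershed by priority flooding of the negative distance
// transform restricted to the foreground mask: equivalently, flood from the
// markers in order of decreasing distance-transform height. Every foreground
// pixel receives the label of exactly one marker; background stays 0.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& dist, const IntegerMatrix& markers,
                            const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = dist.nrow(), nc = dist.ncol(), nn = connectivity;
  if (markers.nrow() != nr || markers.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("dist, markers and mask must have identical dimensions");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int m = markers(r, c);
      if (m > 0) {
        if (!mask(r, c)) stop("marker outside the foreground mask");
        lab(r, c) = m;
        pq.push({dist(r, c), order++, r + c * nr});
      }
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int rr = nd.idx % nr, cc = nd.idx / nr;
    int lb = lab(rr, cc);
    for (int k = 0; k < nn; ++k) {
      int r2 = rr + DR[k], c2 = cc + DC[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) && lab(r2, c2) == 0) {
        lab(r2, c2) = lb;
        pq.push({dist(r2, c2), order++, r2 + c2 * nr});
      }
    }
  }
  return lab;
}
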