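#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Neighbour searches used by the proximity stage. Both routines prune by
// sorting the reference set on x and scanning outward from the query's
// insertion point, stopping once |dx| exceeds the current bound; results are
// bit-identical to an exhaustive scan because the same squared-distance
// expression is evaluated for every admissible candidate.

struct XOrder {
  const double *x;
  bool operator()(int a, int b) const { return x[a] < x[b]; }
};

static std::vector<int> order_by_x(const NumericVector &x) {
  std::vector<int> idx(x.size());
  for (int i = 0; i < (int)idx.size(); ++i) idx[i] = i;
  XOrder cmp; cmp.x = REAL(x);
  std::stable_sort(idx.begin(), idx.end(), cmp);
  return idx;
}

// For each query point, the distance to (and index of) its nearest point in
// the reference set, ties broken toward the lower reference index.
// self_index: 1-based index of the reference record identical to each query
// (0 when none), excluded from the search.
// [[Rcpp::export]]
List cpp_nn_cross(NumericVector ax, NumericVector ay,
                  NumericVector bx, NumericVector by,
                  IntegerVector self_index) {
  const int na = ax.size(), nb = bx.size();
  NumericVector dist(na);
  IntegerVector which(na);
  std::vector<int> ord = order_by_x(bx);
  std::vector<double> sx(nb);
  for (int k = 0; k < nb; ++k) sx[k] = bx[ord[k]];
  for (int i = 0; i < na; ++i) {
    const double qx = ax[i], qy = ay[i];
    const int excl = self_index.size() ? self_index[i] - 1 : -1;
    double best = R_PosInf;
    int besti = NA_INTEGER;
    // insertion point of qx in the sorted reference
    int pos = (int)(std::lower_bound(sx.begin(), sx.end(), qx) - sx.begin());
    int lo = pos - 1, hi = pos;
    while (lo >= 0 || hi < nb) {
      // advance on the side whose next candidate is closer in x; stop when
      // neither side can still beat (or tie) the current bound
      double dlo = (lo >= 0) ? (qx - sx[lo]) : R_PosInf;
      double dhi = (hi < nb) ? (sx[hi] - qx) : R_PosInf;
      bool take_hi = dhi <= dlo;
      double dx = take_hi ? dhi : dlo;
      if (dx * dx > best) break;
      int k = take_hi ? hi : lo;
      int j = ord[k];
      if (j != excl) {
        double ddx = bx[j] - qx;
        double ddy = by[j] - qy;
        // keep the squares in named temporaries: forbids fused multiply-add
        // contraction, so distances match a plain R computation bit for bit
        double sqx = ddx * ddx;
        double sqy = ddy * ddy;
        double d2 = sqx + sqy;
        if (d2 < best || (d2 == best && besti != NA_INTEGER && j + 1 < besti)) {
          best = d2;
          besti = j + 1;
        }
      }
      if (take_hi) ++hi; else --lo;
    }
    dist[i] = (besti == NA_INTEGER) ? R_PosInf : std::sqrt(best);
    which[i] = besti;
  }
  return List::create(_["dist"] = dist, _["index"] = which);
}

// All cross distances <= rmax with their 1-based query (A) indices.
// exclude_same: drop pairs with equal position in both vectors (self pairs
// when A and B are the same table).
// [[Rcpp::export]]
List cpp_pairs_within_idx(NumericVector ax, NumericVector ay,
                          NumericVector bx, NumericVector by,
                          double rmax, bool exclude_same) {
  const int na = ax.size(), nb = bx.size();
  const double r2 = rmax * rmax;
  std::vector<int> ord = order_by_x(bx);
  std::vector<double> sx(nb);
  for (int k = 0; k < nb; ++k) sx[k] = bx[ord[k]];
  std::vector<double> out;
  std::vector<int> qi;
  for (int i = 0; i < na; ++i) {
    const double qx = ax[i], qy = ay[i];
    int lo = (int)(std::lower_bound(sx.begin(), sx.end(), qx - rmax) - sx.begin());
    for (int k = lo; k < nb && sx[k] <= qx + rmax; ++k) {
      int j = ord[k];
      if (exclude_same && j == i) continue;
      double dx = bx[j] - qx, dy = by[j] - qy;
      double sqx = dx * dx;
      double sqy = dy * dy;
      double d2 = sqx + sqy;
      if (d2 <= r2) {
        out.push_back(std::sqrt(d2));
        qi.push_back(i + 1);
      }
    }
  }
  return List::create(_["dist"] = wrap(out), _["query"] = wrap(qi));
}
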