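#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Nearest-neighbour queries via a sorted sweep on x: binary-search the query
// abscissa in the reference set, then expand outward on both sides, pruning
// once the x-gap alone exceeds the best distance found so far. Exact (no
// tolerance); typically near O(log n + k) per query for scattered points.

namespace {

struct SortedRefs {
  std::vector<double> x, y;
  std::vector<int> idx;  // original 0-based index of each sorted entry
};

SortedRefs sort_refs(const NumericVector& qx, const NumericVector& qy) {
  int n = qx.size();
  SortedRefs s;
  s.idx.resize(n);
  for (int i = 0; i < n; ++i) s.idx[i] = i;
  std::sort(s.idx.begin(), s.idx.end(),
            [&](int a, int b) { return qx[a] < qx[b]; });
  s.x.resize(n);
  s.y.resize(n);
  for (int i = 0; i < n; ++i) {
    s.x[i] = qx[s.idx[i]];
    s.y[i] = qy[s.idx[i]];
  }
  return s;
}

// squared NN distance from (px, py) to refs, skipping original index `skip`
// (pass -1 to consider all references)
double nn2_one(double px, double py, const SortedRefs& s, int skip) {
  int n = s.x.size();
  int r = std::lower_bound(s.x.begin(), s.x.end(), px) - s.x.begin();
  int l = r - 1;
  double best = R_PosInf;
  while (l >= 0 || r < n) {
    double dxl = (l >= 0) ? px - s.x[l] : R_PosInf;
    double dxr = (r < n) ? s.x[r] - px : R_PosInf;
    if (dxl <= dxr) {
      if (dxl * dxl >= best) {
        if (dxr * dxr >= best) break;
        // left side exhausted by pruning; only right can improve
        l = -1;
        continue;
      }
      if (s.idx[l] != skip) {
        double dy = py - s.y[l];
        double d2 = dxl * dxl + dy * dy;
        if (d2 < best) best = d2;
      }
      --l;
    } else {
      if (dxr * dxr >= best) {
        if (dxl * dxl >= best) break;
        r = n;
        continue;
      }
      if (s.idx[r] != skip) {
        double dy = py - s.y[r];
        double d2 = dxr * dxr + dy * dy;
        if (d2 < best) best = d2;
      }
      ++r;
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
NumericVector nncross_cpp(NumericVector px, NumericVector py,
                          NumericVector qx, NumericVector qy) {
  int np = px.size();
  if (qx.size() == 0) stop("reference set is empty");
  SortedRefs s = sort_refs(qx, qy);
  NumericVector out(np);
  for (int i = 0; i < np; ++i)
    out[i] = std::sqrt(nn2_one(px[i], py[i], s, -1));
  return out;
}

// [[Rcpp::export]]
NumericVector nnself_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 2) stop("need at least 2 points for nearest-other distances");
  SortedRefs s = sort_refs(x, y);
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = std::sqrt(nn2_one(x[i], y[i], s, i));
  return out;
}
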