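#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Noise-tolerance local maxima detection.
// Contract (identical to the pure-R reference implementation):
//  * candidates: pixels strictly above the global minimum whose value is
//    >= all 8 neighbors (outside the image counts as -Inf);
//  * equal-valued 8-connected plateaus collapse to one representative, the
//    pixel nearest the plateau centroid, ties row-major; a plateau only
//    qualifies if every pixel in it is a candidate;
//  * representatives processed in descending value (ties row-major); each is
//    accepted iff the 8-connected flood region of pixels with value
//    > v - tolerance reachable from it contains no higher pixel and no
//    already-accepted maximum.

struct Rep { int i, j; double v; };

// [[Rcpp::export]]
IntegerMatrix find_maxima_cpp(NumericMatrix img, double tolerance) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  if (n == 0) return IntegerMatrix(0, 2);

  double gmin = img[0];
  for (int k = 1; k < n; ++k) if (img[k] < gmin) gmin = img[k];

  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  // candidate mask
  std::vector<char> cand(n, 0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      if (v <= gmin) continue;
      bool ok = true;
      for (int k = 0; k < 8; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (img(ii, jj) > v) { ok = false; break; }
      }
      if (ok) cand[i + (size_t)j * nr] = 1;
    }
  }

  // plateau grouping over candidate pixels
  std::vector<char> seen(n, 0);
  std::vector<Rep> reps;
  std::vector<int> stack, comp;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      int p0 = i0 + j0 * nr;
      if (seen[p0] || !cand[p0]) continue;
      double v = img[p0];
      comp.clear();
      stack.clear();
      stack.push_back(p0);
      seen[p0] = 1;
      bool all_cand = true;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        comp.push_back(p);
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < 8; ++k) {
          int ii = pi + di[k], jj = pj + dj[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          int q = ii + jj * nr;
          if (!seen[q] && img[q] == v) {
            seen[q] = 1;
            if (!cand[q]) all_cand = false;
            stack.push_back(q);
          }
        }
      }
      if (!all_cand) continue;
      // squared distance to the centroid, scaled by m^2 so it is exact
      // integer arithmetic (representable in double): (m*pi - Si)^2 + ...
      double m = (double)comp.size(), Si = 0.0, Sj = 0.0;
      for (int p : comp) { Si += p % nr; Sj += p / nr; }
      int best = -1;
      double bestd = 0.0;
      for (int p : comp) {
        int pi = p % nr, pj = p / nr;
        double d2 = (m * pi - Si) * (m * pi - Si) +
                    (m * pj - Sj) * (m * pj - Sj);
        if (best < 0 || d2 < bestd ||
            (d2 == bestd &&
             (pi < best % nr || (pi == best % nr && pj < best / nr)))) {
          best = p; bestd = d2;
        }
      }
      reps.push_back({best % nr, best / nr, v});
    }
  }

  std::sort(reps.begin(), reps.end(), [](const Rep &a, const Rep &b) {
    if (a.v != b.v) return a.v > b.v;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });

  std::vector<char> accepted(n, 0);
  std::vector<int> visited(n, -1);  // stamp per flood
  std::vector<std::pair<int, int> > out;
  std::vector<int> flood;
  for (size_t r = 0; r < reps.size(); ++r) {
    double v = reps[r].v;
    double thr = v - tolerance;
    int p0 = reps[r].i + reps[r].j * nr;
    flood.clear();
    flood.push_back(p0);
    visited[p0] = (int)r;
    bool ok = true;
    size_t qi = 0;
    while (qi < flood.size()) {
      int p = flood[qi++];
      if (img[p] > v || accepted[p]) { ok = false; break; }
      int pi = p % nr, pj = p / nr;
      for (int k = 0; k < 8; ++k) {
        int ii = pi + di[k], jj = pj + dj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int q = ii + jj * nr;
        if (visited[q] != (int)r && img[q] > thr) {
          visited[q] = (int)r;
          flood.push_back(q);
        }
      }
    }
    if (ok) {
      accepted[p0] = 1;
      out.push_back(std::make_pair(reps[r].i + 1, reps[r].j + 1));
    }
  }

  IntegerMatrix res(out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    res(k, 0) = out[k].first;
    res(k, 1) = out[k].second;
  }
  colnames(res) = CharacterVector::create("row", "col");
  return res;
}
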