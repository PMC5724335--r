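#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Quality-guided 2D phase unwrapping by region growing.
//
// Starting from the highest-quality pixel of each connected component of the
// mask, pixels are admitted in decreasing quality order (priority queue of
// the solved region's frontier); each admitted pixel is unwrapped relative
// to its already-solved neighbour of highest quality by adding the 2*pi
// multiple that brings the difference into (-pi, pi].  The solution is
// determined up to one 2*pi*k offset per connected component, which the
// caller fixes by temporal seeding.
//
// wrapped, quality: matrices; mask: logical matrix. Returns a list with the
// unwrapped matrix (NA outside mask) and integer component labels.

struct Cand {
  double q;
  int idx;
  bool operator<(const Cand& o) const { return q < o.q; }
};

// [[Rcpp::export(name = ".unwrap2d_cpp")]]
List unwrap2d_cpp(NumericMatrix wrapped, NumericMatrix quality,
                  LogicalMatrix mask) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  const double TWO_PI = 2.0 * M_PI;
  NumericMatrix out(nr, nc);
  IntegerMatrix comp(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::fill(comp.begin(), comp.end(), 0);
  std::vector<char> solved(nr * nc, 0), queued(nr * nc, 0);

  const int dr[4] = {1, -1, 0, 0};
  const int dc[4] = {0, 0, 1, -1};
  int n_comp = 0;

  for (int start = 0; start < nr * nc; ++start) {
    int sr = start % nr, sc = start / nr;
    if (!mask(sr, sc) || solved[start]) continue;

    // find the highest-quality unsolved pixel of this component via a
    // flood fill, then grow from it
    std::vector<int> members;
    std::vector<char> seen(nr * nc, 0);
    std::queue<int> bfs;
    bfs.push(start);
    seen[start] = 1;
    int best = start;
    while (!bfs.empty()) {
      int p = bfs.front(); bfs.pop();
      members.push_back(p);
      int pr = p % nr, pc = p / nr;
      if (quality(pr, pc) > quality(best % nr, best / nr)) best = p;
      for (int k = 0; k < 4; ++k) {
        int r2 = pr + dr[k], c2 = pc + dc[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int p2 = r2 + nr * c2;
        if (mask(r2, c2) && !seen[p2] && !solved[p2]) {
          seen[p2] = 1;
          bfs.push(p2);
        }
      }
    }

    ++n_comp;
    std::priority_queue<Cand> pq;
    out(best % nr, best / nr) = wrapped(best % nr, best / nr);
    solved[best] = 1;
    comp(best % nr, best / nr) = n_comp;
    {
      int pr = best % nr, pc = best / nr;
      for (int k = 0; k < 4; ++k) {
        int r2 = pr + dr[k], c2 = pc + dc[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int p2 = r2 + nr * c2;
        if (mask(r2, c2) && !solved[p2] && !queued[p2]) {
          pq.push({quality(r2, c2), p2});
          queued[p2] = 1;
        }
      }
    }
    while (!pq.empty()) {
      Cand c = pq.top(); pq.pop();
      int pr = c.idx % nr, pc = c.idx / nr;
      if (solved[c.idx]) continue;
      // unwrap against the solved neighbour of highest quality
      double best_q = -1.0, ref = NA_REAL;
      for (int k = 0; k < 4; ++k) {
        int r2 = pr + dr[k], c2 = pc + dc[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (solved[r2 + nr * c2] && quality(r2, c2) > best_q) {
          best_q = quality(r2, c2);
          ref = out(r2, c2);
        }
      }
      double w = wrapped(pr, pc);
      out(pr, pc) = w + TWO_PI * std::round((ref - w) / TWO_PI);
      solved[c.idx] = 1;
      comp(pr, pc) = n_comp;
      for (int k = 0; k < 4; ++k) {
        int r2 = pr + dr[k], c2 = pc + dc[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int p2 = r2 + nr * c2;
        if (mask(r2, c2) && !solved[p2] && !queued[p2]) {
          pq.push({quality(r2, c2), p2});
          queued[p2] = 1;
        }
      }
    }
  }
  return List::create(_["unwrapped"] = out, _["components"] = comp,
                      _["n_components"] = n_comp);
}
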