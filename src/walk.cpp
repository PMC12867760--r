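#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Seeded random walk of n_mice agents on an nx-by-ny grid, one step per
// second. At second t mouse m moves with probability p_move_light[m] or
// p_move_dark[m] according to is_light[t]; a move is either social (with
// per-mouse probability p_social[m]: one Chebyshev-reducing step toward the
// nearest conspecific, ties over conspecifics broken uniformly) or a
// uniform draw from the 8-neighborhood, clipped to the board. Updates are
// synchronous from the positions at t-1, mice processed in index order, so
// runs are reproducible from R's RNG stream alone.
// [[Rcpp::export]]
List walk_cohort_cpp(int n_sec, int nx, int ny,
                     LogicalVector is_light,
                     NumericVector p_move_light, NumericVector p_move_dark,
                     NumericVector p_social,
                     IntegerVector x0, IntegerVector y0) {
  const int n_mice = x0.size();
  IntegerMatrix X(n_sec, n_mice), Y(n_sec, n_mice);
  for (int m = 0; m < n_mice; ++m) { X(0, m) = x0[m]; Y(0, m) = y0[m]; }
  const int ddx[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int ddy[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int t = 1; t < n_sec; ++t) {
    for (int m = 0; m < n_mice; ++m) {
      int cx = X(t - 1, m), cy = Y(t - 1, m);
      int nxp = cx, nyp = cy;
      double pm = is_light[t] ? p_move_light[m] : p_move_dark[m];
      if (unif_rand() < pm) {
        bool stepped = false;
        if (n_mice > 1 && unif_rand() < p_social[m]) {
          // nearest conspecific by Chebyshev distance, reservoir tie-break
          int best = INT_MAX, nbest = 0, tx = cx, ty = cy;
          for (int o = 0; o < n_mice; ++o) {
            if (o == m) continue;
            int dx = X(t - 1, o) - cx, dy = Y(t - 1, o) - cy;
            int d = std::max(dx < 0 ? -dx : dx, dy < 0 ? -dy : dy);
            if (d < best) {
              best = d; nbest = 1; tx = X(t - 1, o); ty = Y(t - 1, o);
            } else if (d == best) {
              ++nbest;
              if (unif_rand() < 1.0 / nbest) { tx = X(t - 1, o); ty = Y(t - 1, o); }
            }
          }
          if (best > 0) {  // same-cell target: fall through to uniform step
            nxp = cx + (tx > cx) - (tx < cx);
            nyp = cy + (ty > cy) - (ty < cy);
            stepped = true;
          }
        }
        if (!stepped) {
          int k = (int)(unif_rand() * 8.0);
          if (k > 7) k = 7;
          nxp = cx + ddx[k]; nyp = cy + ddy[k];
        }
        if (nxp < 1) nxp = 1; else if (nxp > nx) nxp = nx;
        if (nyp < 1) nyp = 1; else if (nyp > ny) nyp = ny;
      }
      X(t, m) = nxp; Y(t, m) = nyp;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y);
}
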