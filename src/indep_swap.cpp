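#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard (independent) swap randomization of a count matrix.
//
// A swappable 2x2 submatrix has presence pattern [x,0;0,y] or [0,x;y,0]
// (x, y > 0); swapping moves the counts to the opposite diagonal, which
// preserves the per-row and per-column *occupancy* (presence) totals exactly
// while carrying the count values with the move.
//
// mode "successes": perform n successful swaps (capped at maxAttempts
// candidate draws); mode "attempts": draw n candidate submatrices and swap
// whenever one is swappable (the burn-in / between-draw convention).
//
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".cppCheckerboardSwap")]]
List cppCheckerboardSwap(NumericMatrix m, int n, bool countSuccesses,
                         double maxAttempts) {
  NumericMatrix out = clone(m);
  int nr = out.nrow(), nc = out.ncol();
  if (nr < 2 || nc < 2)
    return List::create(_["matrix"] = out, _["swaps"] = 0,
                        _["attempts"] = 0, _["exhausted"] = (n > 0));
  double attempts = 0;
  int swaps = 0;
  while (true) {
    if (countSuccesses) {
      if (swaps >= n) break;
      if (attempts >= maxAttempts) break;
    } else if (attempts >= n) {
      break;
    }
    attempts += 1;
    int i = (int)(unif_rand() * nr), j = (int)(unif_rand() * (nr - 1));
    if (j >= i) j++;
    int k = (int)(unif_rand() * nc), l = (int)(unif_rand() * (nc - 1));
    if (l >= k) l++;
    double a = out(i, k), b = out(i, l), c = out(j, k), d = out(j, l);
    if (a > 0 && d > 0 && b == 0 && c == 0) {
      out(i, l) = a; out(i, k) = 0;
      out(j, k) = d; out(j, l) = 0;
      swaps++;
    } else if (b > 0 && c > 0 && a == 0 && d == 0) {
      out(i, k) = b; out(i, l) = 0;
      out(j, l) = c; out(j, k) = 0;
      swaps++;
    }
  }
  bool exhausted = countSuccesses && swaps < n;
  return List::create(_["matrix"] = out, _["swaps"] = swaps,
                      _["attempts"] = attempts, _["exhausted"] = exhausted);
}
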