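#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh, three-state) over a precomputed
// position score matrix S (n x m): S(i-1, j-1) scores pairing row unit i
// with column unit j. A gap run of length k costs gap_open +
// (k - 1) * gap_extend. State X places gaps in the first ("a") profile
// while consuming column units; state Y the converse. Transitions between
// the two gap states re-open (a new run starts).
//
// Tie-breaks are fixed: match/mismatch over gap-in-a over gap-in-b, both
// when choosing the final state and at every traceback step, so the
// returned path is a deterministic function of the inputs.
//
// Returns the optimal score and the move sequence from start to end:
// 1 = diagonal, 2 = gap in a (consume b), 3 = gap in b (consume a).

static const double NEG = -1e300;

// [[Rcpp::export]]
List affine_dp_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    X(0, j) = gap_open + (j - 1) * gap_extend;
    M(0, j) = Y(0, j) = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    Y(i, 0) = gap_open + (i - 1) * gap_extend;
    M(i, 0) = X(i, 0) = NEG;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > d) d = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > d) d = Y(i - 1, j - 1);
      M(i, j) = d + S(i - 1, j - 1);

      double x = M(i, j - 1) + gap_open;
      if (X(i, j - 1) + gap_extend > x) x = X(i, j - 1) + gap_extend;
      if (Y(i, j - 1) + gap_open > x) x = Y(i, j - 1) + gap_open;
      X(i, j) = x;

      double y = M(i - 1, j) + gap_open;
      if (X(i - 1, j) + gap_open > y) y = X(i - 1, j) + gap_open;
      if (Y(i - 1, j) + gap_extend > y) y = Y(i - 1, j) + gap_extend;
      Y(i, j) = y;
    }
  }

  // Final state: prefer M, then X (gap in a), then Y.
  int state = 0;  // 0 = M, 1 = X, 2 = Y
  double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }
  const double score = best;

  std::vector<int> rev;
  rev.reserve(n + m);
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      rev.push_back(1);
      double target = M(i, j) - S(i - 1, j - 1);
      if (std::abs(M(i - 1, j - 1) - target) < eps) state = 0;
      else if (std::abs(X(i - 1, j - 1) - target) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      rev.push_back(2);
      if (j == 1 && i == 0) { --j; continue; }  // leading gap row
      double v = X(i, j);
      if (std::abs(M(i, j - 1) + gap_open - v) < eps) state = 0;
      else if (std::abs(X(i, j - 1) + gap_extend - v) < eps) state = 1;
      else state = 2;
      --j;
    } else {
      rev.push_back(3);
      if (i == 1 && j == 0) { --i; continue; }
      double v = Y(i, j);
      if (std::abs(M(i - 1, j) + gap_open - v) < eps) state = 0;
      else if (std::abs(X(i - 1, j) + gap_open - v) < eps) state = 1;
      else state = 2;
      --i;
    }
  }
  std::reverse(rev.begin(), rev.end());
  return List::create(Named("score") = score,
                      Named("moves") = IntegerVector(rev.begin(), rev.end()));
}
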