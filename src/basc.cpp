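#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Optimal monotone step-function approximations of a sorted vector.
//
// For a sorted vector u[1..N] and every discontinuity count j in
// {1, ..., N-2}, find the breakpoint positions b_1 < ... < b_j (a
// breakpoint b separates ranks b and b+1) minimizing the total squared
// deviation of u from the step function whose levels are the interval
// means. Ties in total cost are broken by the lexicographically smallest
// breakpoint tuple, which the suffix DP + greedy forward reconstruction
// below guarantees.
//
// Returns a list with, for each j from N-2 down to 1, the breakpoint
// vector and the total squared error.
// [[Rcpp::export]]
List bascDP(NumericVector u) {
  const int N = u.size();
  if (N < 3) stop("need at least 3 values");

  std::vector<double> s1(N + 1, 0.0), s2(N + 1, 0.0);
  for (int i = 1; i <= N; ++i) {
    s1[i] = s1[i - 1] + u[i - 1];
    s2[i] = s2[i - 1] + u[i - 1] * u[i - 1];
  }
  // squared deviation of ranks a..b (1-based, inclusive) from their mean
  auto cost = [&](int a, int b) {
    double len = b - a + 1;
    double sum = s1[b] - s1[a - 1];
    double ss = s2[b] - s2[a - 1];
    double c = ss - sum * sum / len;
    return c > 0 ? c : 0.0;
  };

  const int maxSeg = N - 1;  // most segments used: j = N-2 discontinuities
  // D[k][i]: minimal cost of covering ranks i..N with k segments
  std::vector<std::vector<double>> D(maxSeg + 1,
                                     std::vector<double>(N + 2, 0.0));
  for (int i = 1; i <= N; ++i) D[1][i] = cost(i, N);
  for (int k = 2; k <= maxSeg; ++k) {
    for (int i = 1; i <= N - k + 1; ++i) {
      double best = R_PosInf;
      for (int b = i; b <= N - k + 1; ++b) {
        double c = cost(i, b) + D[k - 1][b + 1];
        if (c < best) best = c;
      }
      D[k][i] = best;
    }
  }

  List breaks(N - 2);
  NumericVector sse(N - 2);
  for (int K = maxSeg; K >= 2; --K) {  // K segments = K-1 discontinuities
    IntegerVector bp(K - 1);
    int i = 1;
    for (int seg = K, idx = 0; seg >= 2; --seg, ++idx) {
      // smallest first breakpoint consistent with the optimum
      for (int b = i; b <= N - seg + 1; ++b) {
        if (cost(i, b) + D[seg - 1][b + 1] == D[seg][i]) {
          bp[idx] = b;
          i = b + 1;
          break;
        }
      }
    }
    breaks[maxSeg - K] = bp;       // j = N-2 first, down to j = 1
    sse[maxSeg - K] = D[K][1];
  }
  return List::create(Named("breakpoints") = breaks, Named("sse") = sse);
}
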