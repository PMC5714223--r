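#include <Rcpp.h>
using namespace Rcpp;

// Maximum expected accuracy structure: Nussinov-style DP maximising
//   sum over pairs (i,j) in S of 2*P(i,j) + sum over unpaired i of q(i)
// over non-crossing structures with pair span > min_sep. Ties are broken
// toward the unpaired branch (fewer pairs), then toward the smallest
// partner index, which yields a deterministic structure.

// [[Rcpp::export(name = ".mea_dp_cpp")]]
List mea_dp_cpp(NumericMatrix P, NumericVector q, int min_sep) {
  const int n = q.size();
  if (n == 0)
    return List::create(_["pairs"] = IntegerMatrix(0, 2),
                        _["objective"] = 0.0);
  std::vector<double> M((size_t)n * n, 0.0);
  // choice: -1 = i unpaired, k >= 0 = pair (i,k)
  std::vector<int> CH((size_t)n * n, -1);
#define IX(i, j) ((size_t)(i) * n + (j))
  for (int span = 0; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double best = q[i] + (i + 1 <= j ? M[IX(i + 1, j)] : 0.0);
      int ch = -1;
      for (int k = i + min_sep + 1; k <= j; ++k) {
        if (P(i, k) <= 0.0) continue;
        double v = 2.0 * P(i, k) + (i + 1 <= k - 1 ? M[IX(i + 1, k - 1)] : 0.0)
                   + (k + 1 <= j ? M[IX(k + 1, j)] : 0.0);
        if (v > best) { best = v; ch = k; }
      }
      M[IX(i, j)] = best;
      CH[IX(i, j)] = ch;
    }
  }

  // iterative traceback
  std::vector<std::pair<int, int> > pairs;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i > j) continue;
    int ch = CH[IX(i, j)];
    if (ch < 0) {
      stack.push_back(std::make_pair(i + 1, j));
    } else {
      pairs.push_back(std::make_pair(i + 1, ch + 1)); // 1-based
      stack.push_back(std::make_pair(i + 1, ch - 1));
      stack.push_back(std::make_pair(ch + 1, j));
    }
  }
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  double obj = M[IX(0, n - 1)];
#undef IX
  return List::create(_["pairs"] = pm, _["objective"] = obj);
}

// Monotone maximum-sum decoding of a positional score matrix S (a
// Needleman-Wunsch DP with gap score 0). Returns the matched index pairs
// (1-based) and the total matched score. Ties prefer the diagonal, then
// the gap in the second sequence, making the traceback deterministic.

// [[Rcpp::export(name = ".nw_decode_cpp")]]
List nw_decode_cpp(NumericMatrix S) {
  const int n1 = S.nrow(), n2 = S.ncol();
  std::vector<double> D((size_t)(n1 + 1) * (n2 + 1), 0.0);
  std::vector<signed char> T((size_t)(n1 + 1) * (n2 + 1), 0);
#define IX(i, k) ((size_t)(i) * (n2 + 1) + (k))
  for (int i = 1; i <= n1; ++i) {
    for (int k = 1; k <= n2; ++k) {
      double diag = D[IX(i - 1, k - 1)] + S(i - 1, k - 1);
      double up = D[IX(i - 1, k)];
      double left = D[IX(i, k - 1)];
      double best = diag; signed char t = 0;
      if (up > best) { best = up; t = 1; }
      if (left > best) { best = left; t = 2; }
      D[IX(i, k)] = best;
      T[IX(i, k)] = t;
    }
  }
  std::vector<std::pair<int, int> > matches;
  int i = n1, k = n2;
  while (i > 0 && k > 0) {
    signed char t = T[IX(i, k)];
    if (t == 0) { matches.push_back(std::make_pair(i, k)); --i; --k; }
    else if (t == 1) --i;
    else --k;
  }
  std::reverse(matches.begin(), matches.end());
  IntegerMatrix mm(matches.size(), 2);
  for (size_t r = 0; r < matches.size(); ++r) {
    mm(r, 0) = matches[r].first;
    mm(r, 1) = matches[r].second;
  }
  double sc = D[IX(n1, n2)];
#undef IX
  return List::create(_["matches"] = mm, _["score"] = sc);
}
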