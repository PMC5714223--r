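#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// McCaskill-style inside-outside partition function over non-crossing
// canonical structures for one sequence, with a multiplicative per-pair
// extrinsic factor. The structure weight is the product over loops of the
// model factors:
//   hairpin closed by (i,j) with u unpaired  -> hairpinF[u]
//   two-loop between (i,j) and (k,l): stack (u1=u2=0, stack 6x6 by pair
//   type), bulge (one side 0) bulgeF[u], internal internalF[u], with
//   u = u1+u2 <= max_internal
//   multibranch: m_init per loop, m_branch per inner branch,
//   m_unpaired per unpaired loop nucleotide; exterior loop factor 1
// and the product over pairs (i,j) of pairwt(x_i,x_j) * extmult(i,j).
//
// Pair-type index for the stack table: AU=0, UA=1, GC=2, CG=3, GU=4, UG=5.

static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0; // AU
  if (a == 3 && b == 0) return 1; // UA
  if (a == 2 && b == 1) return 2; // GC
  if (a == 1 && b == 2) return 3; // CG
  if (a == 2 && b == 3) return 4; // GU
  if (a == 3 && b == 2) return 5; // UG
  return -1;
}

// [[Rcpp::export(name = ".partition_pairprobs_cpp")]]
NumericMatrix partition_pairprobs_cpp(IntegerVector xenc,
                                      NumericMatrix pairwt,
                                      NumericMatrix stack,
                                      NumericVector hairpinF,
                                      NumericVector bulgeF,
                                      NumericVector internalF,
                                      double m_init, double m_branch,
                                      double m_unpaired,
                                      int min_hairpin, int max_internal,
                                      Nullable<NumericMatrix> extmult_) {
  const int n = xenc.size();
  bool has_ext = extmult_.isNotNull();
  NumericMatrix extmult;
  if (has_ext) {
    extmult = NumericMatrix(extmult_);
    if (extmult.nrow() != n || extmult.ncol() != n)
      stop("extrinsic multiplier has wrong dimensions");
  }

  // pair weight including extrinsic multiplier, 0 for non-canonical /
  // below-minimum spans
  std::vector<double> W(n * n, 0.0);
  std::vector<int> PT(n * n, -1);
#define IX(i, j) ((i) * n + (j))
  for (int i = 0; i < n; ++i)
    for (int j = i + min_hairpin + 1; j < n; ++j) {
      int pt = pair_type(xenc[i], xenc[j]);
      if (pt < 0) continue;
      double w = pairwt(xenc[i], xenc[j]);
      if (has_ext) w *= extmult(i, j);
      W[IX(i, j)] = w;
      PT[IX(i, j)] = pt;
    }

  std::vector<double> Qb(n * n, 0.0), QM(n * n, 0.0), QM1(n * n, 0.0);
  std::vector<double> upow(n + 2);
  upow[0] = 1.0;
  for (int u = 1; u <= n + 1; ++u) upow[u] = upow[u - 1] * m_unpaired;

  for (int span = min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // Qb(i,j)
      if (W[IX(i, j)] > 0.0) {
        int u = j - i - 1;
        double val = (u >= min_hairpin && u < hairpinF.size())
                         ? hairpinF[u] : 0.0;
        // two-loops
        int kmax = std::min(i + 1 + max_internal, j - min_hairpin - 2);
        for (int k = i + 1; k <= kmax; ++k) {
          int u1 = k - i - 1;
          int lmin = std::max(k + min_hairpin + 1, j - 1 - (max_internal - u1));
          for (int l = lmin; l <= j - 1; ++l) {
            double qb = Qb[IX(k, l)];
            if (qb <= 0.0) continue;
            int u2 = j - l - 1;
            double f;
            if (u1 == 0 && u2 == 0)
              f = stack(PT[IX(i, j)], PT[IX(k, l)]);
            else if (u1 == 0 || u2 == 0)
              f = bulgeF[u1 + u2];
            else
              f = internalF[u1 + u2];
            val += f * qb;
          }
        }
        // multibranch: >= 2 inner branches
        for (int h = i + 2; h <= j - 2; ++h) {
          double qm = QM[IX(i + 1, h - 1)];
          if (qm <= 0.0) continue;
          double qm1 = QM1[IX(h, j - 1)];
          if (qm1 <= 0.0) continue;
          val += m_init * qm * qm1;
        }
        Qb[IX(i, j)] = W[IX(i, j)] * val;
      }
      // QM1(i,j): one branch starting exactly at i, trailing unpaired
      {
        double s = 0.0;
        for (int l = i + min_hairpin + 1; l <= j; ++l) {
          double qb = Qb[IX(i, l)];
          if (qb > 0.0) s += qb * m_branch * upow[j - l];
        }
        QM1[IX(i, j)] = s;
      }
      // QM(i,j): >= 1 branch, multiloop unpaired factors
      {
        double s = 0.0;
        for (int k = i; k <= j; ++k) {
          double qm1 = QM1[IX(k, j)];
          if (qm1 <= 0.0) continue;
          double left = upow[k - i];
          if (k > i) left += QM[IX(i, k - 1)];
          s += left * qm1;
        }
        QM[IX(i, j)] = s;
      }
    }
  }
  // short spans: QM/QM1 remain 0 (no room for a branch), fine.

  // exterior prefixes / suffixes
  std::vector<double> Qleft(n + 1), Qright(n + 1);
  // Qleft[j] = partition of x[0..j-1] (Qleft[0] = 1)
  Qleft[0] = 1.0;
  for (int j = 1; j <= n; ++j) {
    double s = Qleft[j - 1]; // x[j-1] unpaired
    for (int i = 1; i <= j; ++i) {
      double qb = Qb[IX(i - 1, j - 1)];
      if (qb > 0.0) s += Qleft[i - 1] * qb;
    }
    Qleft[j] = s;
  }
  // Qright[i] = partition of x[i..n-1] (Qright[n] = 1)
  Qright[n] = 1.0;
  for (int i = n - 1; i >= 0; --i) {
    double s = Qright[i + 1];
    for (int j = i; j < n; ++j) {
      double qb = Qb[IX(i, j)];
      if (qb > 0.0) s += qb * Qright[j + 1];
    }
    Qright[i] = s;
  }
  double Qtot = Qleft[n];
  if (!(Qtot >= 1.0) || !std::isfinite(Qtot))
    stop("partition function degenerate (open chain lost)");

  // outside: O(i,j) with P(i,j) = Qb(i,j) * O(i,j) / Qtot
  std::vector<double> O(n * n, 0.0);
  // helper closures for multiloop fills
  auto Eu = [&](int a, int b) -> double { // all-unpaired fill
    return (b < a) ? 1.0 : upow[b - a + 1];
  };
  auto QMv = [&](int a, int b) -> double {
    return (b < a) ? 0.0 : QM[IX(a, b)];
  };

  for (int span = n - 1; span >= min_hairpin + 1; --span) {
    for (int k = 0; k + span < n; ++k) {
      int l = k + span;
      if (Qb[IX(k, l)] <= 0.0) continue;
      double o = Qleft[k] * Qright[l + 1];
      // enclosed by (i,j) through a two-loop
      int imin = std::max(0, k - 1 - max_internal);
      for (int i = imin; i <= k - 1; ++i) {
        int u1 = k - i - 1;
        int jmax = std::min(n - 1, l + 1 + (max_internal - u1));
        for (int j = l + 1; j <= jmax; ++j) {
          if (W[IX(i, j)] <= 0.0 || O[IX(i, j)] <= 0.0) continue;
          int u2 = j - l - 1;
          double f;
          if (u1 == 0 && u2 == 0)
            f = stack(PT[IX(i, j)], PT[IX(k, l)]);
          else if (u1 == 0 || u2 == 0)
            f = bulgeF[u1 + u2];
          else
            f = internalF[u1 + u2];
          o += O[IX(i, j)] * W[IX(i, j)] * f;
        }
      }
      // as a branch of a multiloop closed by (i,j); at least one other
      // branch must exist: split on whether the left fill carries one
      for (int i = 0; i <= k - 1; ++i) {
        for (int j = l + 1; j < n; ++j) {
          if (W[IX(i, j)] <= 0.0) continue;
          double oij = O[IX(i, j)];
          if (oij <= 0.0) continue;
          double lQM = QMv(i + 1, k - 1), lE = Eu(i + 1, k - 1);
          double rQM = QMv(l + 1, j - 1), rE = Eu(l + 1, j - 1);
          double fills = lQM * (rQM + rE) + lE * rQM;
          if (fills <= 0.0) continue;
          o += oij * W[IX(i, j)] * m_init * m_branch * fills;
        }
      }
      O[IX(k, l)] = o;
    }
  }

  NumericMatrix P(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = Qb[IX(i, j)] * O[IX(i, j)] / Qtot;
      if (v < 0.0) v = 0.0;
      if (v > 1.0) v = 1.0;
      P(i, j) = v;
    }
#undef IX
  return P;
}
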