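#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Three-state pair HMM (0 = ALN, 1 = INS1, 2 = INS2) forward-backward.
// Sequences arrive 0-based encoded over A,C,G,U = 0..3. tau is the 3x3
// transition matrix (row = from), pairEmit the 4x4 ALN emission table,
// insEmit the length-4 single-residue emission table (shared by the two
// insert states). rho, when present, multiplies the ALN terms of both
// recursions as a structural prior; absent rho is the all-ones prior.
//
// Numeric stability: the tables are rescaled per anti-diagonal
// (i + k = const). Cells on one anti-diagonal are reached by paths of
// comparable length, so their dynamic range stays bounded; per-row
// scaling would anchor the scale to the all-gap edge cells and flush
// the near-diagonal mass to zero for long sequences. Cumulative log
// scale factors per anti-diagonal are carried alongside and posteriors
// are assembled in log space. No underflow up to N ~ 1000.

static inline double get_rho(const NumericMatrix &rho, bool has_rho,
                             int i, int k) {
  // i,k are 1-based residue indices
  return has_rho ? rho(i - 1, k - 1) : 1.0;
}

// [[Rcpp::export(name = ".hmm_posteriors_cpp")]]
List hmm_posteriors_cpp(IntegerVector x, IntegerVector y,
                        NumericMatrix tau, NumericMatrix pairEmit,
                        NumericVector insEmit,
                        Nullable<NumericMatrix> rho_) {
  const int n1 = x.size(), n2 = y.size();
  bool has_rho = rho_.isNotNull();
  NumericMatrix rho;
  if (has_rho) {
    rho = NumericMatrix(rho_);
    if (rho.nrow() != n1 || rho.ncol() != n2)
      stop("match-score prior has wrong dimensions");
  }

  const int R = n1 + 1, C = n2 + 1, D = n1 + n2;
  std::vector<double> aA(R * C, 0.0), a1(R * C, 0.0), a2(R * C, 0.0);
  std::vector<double> bA(R * C, 0.0), b1(R * C, 0.0), b2(R * C, 0.0);
  std::vector<double> clA(D + 1, 0.0), clB(D + 1, 0.0);
#define IX(i, k) ((i) * C + (k))

  // forward, by anti-diagonal d = i + k. Stored entries on diagonal d
  // carry the factor exp(-clA[d]); reads from d-1 are on the working
  // scale, reads from d-2 are adjusted by exp(clA[d-2] - clA[d-1]).
  aA[IX(0, 0)] = 1.0;
  for (int d = 1; d <= D; ++d) {
    double f2 = (d >= 2) ? std::exp(clA[d - 2] - clA[d - 1]) : 1.0;
    int ilo = std::max(0, d - n2), ihi = std::min(n1, d);
    double m = 0.0;
    for (int i = ilo; i <= ihi; ++i) {
      int k = d - i;
      double vA = 0.0, v1 = 0.0, v2 = 0.0;
      if (i >= 1 && k >= 1) {
        double prev = tau(0, 0) * aA[IX(i - 1, k - 1)] +
                      tau(1, 0) * a1[IX(i - 1, k - 1)] +
                      tau(2, 0) * a2[IX(i - 1, k - 1)];
        vA = pairEmit(x[i - 1], y[k - 1]) * get_rho(rho, has_rho, i, k) *
             prev * f2;
      }
      if (i >= 1) {
        double prev = tau(0, 1) * aA[IX(i - 1, k)] +
                      tau(1, 1) * a1[IX(i - 1, k)] +
                      tau(2, 1) * a2[IX(i - 1, k)];
        v1 = insEmit[x[i - 1]] * prev;
      }
      if (k >= 1) {
        double prev = tau(0, 2) * aA[IX(i, k - 1)] +
                      tau(1, 2) * a1[IX(i, k - 1)] +
                      tau(2, 2) * a2[IX(i, k - 1)];
        v2 = insEmit[y[k - 1]] * prev;
      }
      aA[IX(i, k)] = vA; a1[IX(i, k)] = v1; a2[IX(i, k)] = v2;
      m = std::max(m, std::max(vA, std::max(v1, v2)));
    }
    if (m > 0.0) {
      for (int i = ilo; i <= ihi; ++i) {
        int k = d - i;
        aA[IX(i, k)] /= m; a1[IX(i, k)] /= m; a2[IX(i, k)] /= m;
      }
      clA[d] = clA[d - 1] + std::log(m);
    } else {
      clA[d] = clA[d - 1];
    }
  }

  double tail = aA[IX(n1, n2)] + a1[IX(n1, n2)] + a2[IX(n1, n2)];
  if (!(tail > 0.0) || !std::isfinite(tail))
    stop("pair HMM has zero total path weight (degenerate parameters)");
  double logZ = std::log(tail) + clA[D];

  // backward, anti-diagonals from D down; reads from d+1 are on the
  // working scale, reads from d+2 adjusted by exp(clB[d+2] - clB[d+1])
  bA[IX(n1, n2)] = b1[IX(n1, n2)] = b2[IX(n1, n2)] = 1.0;
  for (int d = D - 1; d >= 0; --d) {
    double f2 = (d + 2 <= D) ? std::exp(clB[d + 2] - clB[d + 1]) : 1.0;
    int ilo = std::max(0, d - n2), ihi = std::min(n1, d);
    double m = 0.0;
    for (int i = ilo; i <= ihi; ++i) {
      int k = d - i;
      double tA = 0.0, t1 = 0.0, t2 = 0.0;
      if (i + 1 <= n1 && k + 1 <= n2)
        tA = pairEmit(x[i], y[k]) * get_rho(rho, has_rho, i + 1, k + 1) *
             bA[IX(i + 1, k + 1)] * f2;
      if (i + 1 <= n1) t1 = insEmit[x[i]] * b1[IX(i + 1, k)];
      if (k + 1 <= n2) t2 = insEmit[y[k]] * b2[IX(i, k + 1)];
      double vA = tau(0, 0) * tA + tau(0, 1) * t1 + tau(0, 2) * t2;
      double v1 = tau(1, 0) * tA + tau(1, 1) * t1 + tau(1, 2) * t2;
      double v2 = tau(2, 0) * tA + tau(2, 1) * t1 + tau(2, 2) * t2;
      bA[IX(i, k)] = vA; b1[IX(i, k)] = v1; b2[IX(i, k)] = v2;
      m = std::max(m, std::max(vA, std::max(v1, v2)));
    }
    if (m > 0.0) {
      for (int i = ilo; i <= ihi; ++i) {
        int k = d - i;
        bA[IX(i, k)] /= m; b1[IX(i, k)] /= m; b2[IX(i, k)] /= m;
      }
      clB[d] = clB[d + 1] + std::log(m);
    } else {
      clB[d] = clB[d + 1];
    }
  }

  NumericMatrix co(n1, n2), al(n1, n2);
  for (int i = 1; i <= n1; ++i) {
    for (int k = 1; k <= n2; ++k) {
      double lsc = clA[i + k] + clB[i + k] - logZ;
      double pA = aA[IX(i, k)] * bA[IX(i, k)];
      double p1 = a1[IX(i, k)] * b1[IX(i, k)];
      double p2 = a2[IX(i, k)] * b2[IX(i, k)];
      double tot = pA + p1 + p2;
      double vco = tot > 0.0 ? std::exp(std::log(tot) + lsc) : 0.0;
      double val = pA > 0.0 ? std::exp(std::log(pA) + lsc) : 0.0;
      if (vco < 0.0) vco = 0.0;
      if (vco > 1.0) vco = 1.0;
      if (val < 0.0) val = 0.0;
      if (val > 1.0) val = 1.0;
      co(i - 1, k - 1) = vco;
      al(i - 1, k - 1) = val;
    }
  }
#undef IX
  return List::create(_["coincidence"] = co, _["aligned"] = al,
                      _["logZ"] = logZ);
}
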