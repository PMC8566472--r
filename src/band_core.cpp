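#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact binomial arithmetic. C(alpha, j) with the convention C(alpha, j) = 0
// for 0 <= alpha < j. Values up to C(10000, 10) ~ 2.7e33 exceed the 53-bit
// integer range of a double, so tables and count differences are kept in
// 128-bit integers whenever C(n, j) fits, and only the final count is
// rounded to double. For larger arguments we fall back to R's double-
// precision choose().

typedef __int128 int128;

static bool binom_fits_128(const double alpha, const double j) {
  // 2^126 guard leaves headroom for sums of four table entries
  return Rf_lchoose(alpha, j) < 126.0 * M_LN2;
}

static int128 binom128(const long long alpha, const long long j) {
  if (alpha < j) return 0;
  int128 r = 1;
  for (long long i = 1; i <= j; ++i) {
    r = r * (int128)(alpha - j + i);
    r = r / (int128)i;  // always divides exactly
  }
  return r;
}

static double binom_dbl(const double alpha, const double j) {
  if (alpha < j) return 0.0;
  if (binom_fits_128(alpha, j))
    return (double)binom128((long long)alpha, (long long)j);
  return Rf_choose(alpha, j);
}

// [[Rcpp::export]]
NumericVector cpp_binom(NumericVector alpha, double j) {
  if (j < 0) stop("'j' must be a non-negative integer");
  const R_xlen_t m = alpha.size();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    if (alpha[i] < 0) stop("'alpha' must be non-negative");
    out[i] = binom_dbl(alpha[i], j);
  }
  return out;
}

// Table of C(alpha, j) for alpha = 0..n, exact in int128 when possible.
struct BinomTable {
  bool exact;
  std::vector<int128> ti;
  std::vector<double> td;
  BinomTable(int n, int j) {
    exact = binom_fits_128((double)n, (double)j);
    if (exact) {
      ti.resize(n + 1);
      for (int a = 0; a <= n; ++a) ti[a] = binom128(a, j);
    } else {
      td.resize(n + 1);
      for (int a = 0; a <= n; ++a) td[a] = binom_dbl(a, j);
    }
  }
};

// N^(j)_k for a single point with first-occurrence rank l and multiplicity e
// (e = 0 for out-of-sample values) against a reference column of size n:
// C(n,j) - C(l-1,j) - C(n-l-e+1,j).
static inline double count_single(const BinomTable &bt, int n, int l, int e) {
  if (bt.exact)
    return (double)(bt.ti[n] - bt.ti[l - 1] - bt.ti[n - l - e + 1]);
  return bt.td[n] - bt.td[l - 1] - bt.td[n - l - e + 1];
}

// N^(j)_k for a pair via inclusion-exclusion; (lm, em) belong to the smaller
// of the two coordinate values, lM to the larger. When the values coincide
// the last term is dropped (single-point formula).
static inline double count_pair(const BinomTable &bt, int n, int lm, int em,
                                int lM, bool tied) {
  if (bt.exact) {
    int128 r = bt.ti[n] - bt.ti[lM - 1] - bt.ti[n - lm - em + 1];
    if (!tied) r += bt.ti[lM - lm - em];
    return (double)r;
  }
  double r = bt.td[n] - bt.td[lM - 1] - bt.td[n - lm - em + 1];
  if (!tied) r += bt.td[lM - lm - em];
  return r;
}

// [[Rcpp::export]]
NumericMatrix cpp_count_single(IntegerMatrix L, IntegerMatrix E, int n, int j) {
  const int q = L.nrow(), d = L.ncol();
  BinomTable bt(n, j);
  NumericMatrix out(q, d);
  for (int k = 0; k < d; ++k)
    for (int i = 0; i < q; ++i)
      out(i, k) = count_single(bt, n, L(i, k), E(i, k));
  return out;
}

enum CoefId { SM = 0, JAC, SIMP, FORBES, DICE, ANDER, OCHIAI, RR };

// Binary similarity coefficient from a contingency table (a,b,c,dd) with
// total tot = a+b+c+dd. Zero denominators only arise with a = 0 (possible
// for out-of-sample queries); the coefficient is then defined as 0, the
// a -> 0 limit of each formula.
static inline double coef_value(const int coef, const double a, const double b,
                                const double c, const double dd, const double tot) {
  switch (coef) {
  case SM:     return (a + dd) / tot;
  case JAC:    { const double den = a + b + c;
                 return den > 0 ? a / den : 0.0; }
  case SIMP:   { const double den = std::min(a + b, a + c);
                 return den > 0 ? a / den : 0.0; }
  case FORBES: { const double den = (a + b) * (a + c);
                 return den > 0 ? a * tot / den : 0.0; }
  case DICE:   { const double den = 2.0 * a + b + c;
                 return den > 0 ? 2.0 * a / den : 0.0; }
  case ANDER:  { const double den = a + 2.0 * (b + c);
                 return den > 0 ? a / den : 0.0; }
  case OCHIAI: { const double den = (a + b) * (a + c);
                 return den > 0 ? a / std::sqrt(den) : 0.0; }
  case RR:     return a / tot;
  }
  return NA_REAL;
}

// Aggregated band similarity between two rows described by per-coordinate
// (value, l, eta) triples against a common reference sample of size n.
// aggregation 0 = coordinate-wise average (option b), 1 = pooled tables
// (option a: sum the d tables entrywise, then apply the coefficient).
static double pair_similarity(const std::vector<BinomTable> &tables,
                              const NumericMatrix &V1, const IntegerMatrix &L1,
                              const IntegerMatrix &E1, const int i1,
                              const NumericMatrix &V2, const IntegerMatrix &L2,
                              const IntegerMatrix &E2, const int i2,
                              const int n, const int J, const int coef,
                              const int aggregation) {
  const int d = V1.ncol();
  double acc = 0.0;
  for (int j = 2; j <= J; ++j) {
    const BinomTable &bt = tables[j - 2];
    const double cnj = bt.exact ? (double)bt.ti[n] : bt.td[n];
    double pa = 0, pb = 0, pc = 0, pd = 0, coord_acc = 0;
    for (int k = 0; k < d; ++k) {
      const double v1 = V1(i1, k), v2 = V2(i2, k);
      const int l1 = L1(i1, k), e1 = E1(i1, k);
      const int l2 = L2(i2, k), e2 = E2(i2, k);
      const double N1 = count_single(bt, n, l1, e1);
      const double N2 = count_single(bt, n, l2, e2);
      double Np;
      if (v1 == v2) {
        Np = count_pair(bt, n, l1, e1, l1, true);
      } else if (v1 < v2) {
        Np = count_pair(bt, n, l1, e1, l2, false);
      } else {
        Np = count_pair(bt, n, l2, e2, l1, false);
      }
      const double a = Np, b = N1 - Np, c = N2 - Np, dd = cnj - N1 - N2 + Np;
      if (b < 0 || c < 0 || dd < -0.5)
        stop("inconsistent band counts (internal error)");
      if (aggregation == 0) {
        coord_acc += coef_value(coef, a, b, c, dd, cnj);
      } else {
        pa += a; pb += b; pc += c; pd += dd;
      }
    }
    if (aggregation == 0)
      acc += coord_acc / (double)d;
    else
      acc += coef_value(coef, pa, pb, pc, pd, pa + pb + pc + pd);
  }
  return acc / (double)(J - 1);
}

// [[Rcpp::export]]
NumericMatrix cpp_band_similarity(NumericMatrix V, IntegerMatrix L,
                                  IntegerMatrix E, int J, int coef,
                                  int aggregation) {
  const int n = V.nrow();
  std::vector<BinomTable> tables;
  for (int j = 2; j <= J; ++j) tables.emplace_back(n, j);
  NumericMatrix out(n, n);
  for (int i1 = 0; i1 < n; ++i1)
    for (int i2 = i1; i2 < n; ++i2) {
      const double s = pair_similarity(tables, V, L, E, i1, V, L, E, i2,
                                       n, J, coef, aggregation);
      out(i1, i2) = s;
      out(i2, i1) = s;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_cross_band_similarity(NumericMatrix Vq, IntegerMatrix Lq,
                                        IntegerMatrix Eq, NumericMatrix Vt,
                                        IntegerMatrix Lt, IntegerMatrix Et,
                                        int n, int J, int coef,
                                        int aggregation) {
  const int q = Vq.nrow(), m = Vt.nrow();
  std::vector<BinomTable> tables;
  for (int j = 2; j <= J; ++j) tables.emplace_back(n, j);
  NumericMatrix out(q, m);
  for (int i1 = 0; i1 < q; ++i1)
    for (int i2 = 0; i2 < m; ++i2)
      out(i1, i2) = pair_similarity(tables, Vq, Lq, Eq, i1, Vt, Lt, Et, i2,
                                    n, J, coef, aggregation);
  return out;
}
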