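#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Alignments are passed as integer matrices (sequences x columns) with
// 0 = gap and 1..20 = amino acids in alphabetical one-letter order
// (A C D E F G H I K L M N P Q R S T V W Y).  `cols` holds 1-based
// indices of the eligible columns; every kernel returns a symmetric
// matrix over those columns with NA on the diagonal and for pairs with
// no valid (mutually ungapped) sequences.

static inline void pairCountsAt(const IntegerMatrix& A, int ci, int cj,
                                int* jc, int* nx, int* ny, int& nv) {
  std::fill(jc, jc + 400, 0);
  std::fill(nx, nx + 20, 0);
  std::fill(ny, ny + 20, 0);
  nv = 0;
  const int n = A.nrow();
  for (int s = 0; s < n; ++s) {
    const int x = A(s, ci), y = A(s, cj);
    if (x > 0 && y > 0) {
      ++jc[(x - 1) * 20 + (y - 1)];
      ++nx[x - 1];
      ++ny[y - 1];
      ++nv;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix omesKernel(IntegerMatrix A, IntegerVector cols) {
  const int m = cols.size();
  NumericMatrix out(m, m);
  std::fill(out.begin(), out.end(), NA_REAL);
  int jc[400], nx[20], ny[20], nv;
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      pairCountsAt(A, cols[a] - 1, cols[b] - 1, jc, nx, ny, nv);
      if (nv == 0) continue;
      // sum over residue-pair cells with positive marginals: (obs-exp)^2/Nv
      double score = 0.0;
      for (int x = 0; x < 20; ++x) {
        if (nx[x] == 0) continue;
        for (int y = 0; y < 20; ++y) {
          if (ny[y] == 0) continue;
          const double ex = (double)nx[x] * ny[y] / nv;
          const double d = jc[x * 20 + y] - ex;
          score += d * d / nv;
        }
      }
      out(a, b) = out(b, a) = score;
    }
  }
  return out;
}

// Returns mutual information I (nats), joint entropy H, and NMI = I/H
// (0 when H = 0) for every eligible column pair.
// [[Rcpp::export]]
List nmiKernel(IntegerMatrix A, IntegerVector cols) {
  const int m = cols.size();
  NumericMatrix I(m, m), H(m, m), NMI(m, m);
  std::fill(I.begin(), I.end(), NA_REAL);
  std::fill(H.begin(), H.end(), NA_REAL);
  std::fill(NMI.begin(), NMI.end(), NA_REAL);
  int jc[400], nx[20], ny[20], nv;
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      pairCountsAt(A, cols[a] - 1, cols[b] - 1, jc, nx, ny, nv);
      if (nv == 0) continue;
      double mi = 0.0, hj = 0.0;
      for (int x = 0; x < 20; ++x) {
        if (nx[x] == 0) continue;
        for (int y = 0; y < 20; ++y) {
          const int c = jc[x * 20 + y];
          if (c == 0) continue;
          const double pxy = (double)c / nv;
          mi += pxy * std::log(pxy * nv * (double)nv / ((double)nx[x] * ny[y]));
          hj -= pxy * std::log(pxy);
        }
      }
      I(a, b) = I(b, a) = mi;
      H(a, b) = H(b, a) = hj;
      const double r = hj > 0.0 ? mi / hj : 0.0;
      NMI(a, b) = NMI(b, a) = r;
    }
  }
  return List::create(_["I"] = I, _["H"] = H, _["NMI"] = NMI);
}

// McBASC: correlation of McLachlan similarity profiles over all ordered
// sequence pairs (k,l), k != l.  Pairs involving a gap score 0 (the
// McLachlan matrix has no gap entry).  Columns with zero similarity
// variance contribute r = 0.
// [[Rcpp::export]]
NumericMatrix mcbascKernel(IntegerMatrix A, IntegerVector cols,
                           NumericMatrix M) {
  const int n = A.nrow(), m = cols.size();
  const R_xlen_t np = (R_xlen_t)n * n - n;
  std::vector<double> V((size_t)m * np);
  std::vector<bool> zero(m, false);
  for (int a = 0; a < m; ++a) {
    double* v = &V[(size_t)a * np];
    const int c = cols[a] - 1;
    R_xlen_t t = 0;
    double sum = 0.0;
    for (int k = 0; k < n; ++k) {
      const int xk = A(k, c);
      for (int l = 0; l < n; ++l) {
        if (k == l) continue;
        const int xl = A(l, c);
        const double s = (xk > 0 && xl > 0) ? M(xk - 1, xl - 1) : 0.0;
        v[t++] = s;
        sum += s;
      }
    }
    const double mean = sum / np;
    double ss = 0.0;
    for (R_xlen_t i = 0; i < np; ++i) {
      v[i] -= mean;
      ss += v[i] * v[i];
    }
    if (ss <= 0.0) {
      zero[a] = true;
    } else {
      const double inv = 1.0 / std::sqrt(ss);
      for (R_xlen_t i = 0; i < np; ++i) v[i] *= inv;
    }
  }
  NumericMatrix out(m, m);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int a = 0; a < m; ++a) {
    const double* va = &V[(size_t)a * np];
    for (int b = a + 1; b < m; ++b) {
      if (zero[a] || zero[b]) {
        out(a, b) = out(b, a) = 0.0;
        continue;
      }
      const double* vb = &V[(size_t)b * np];
      double dot = 0.0;
      for (R_xlen_t i = 0; i < np; ++i) dot += va[i] * vb[i];
      out(a, b) = out(b, a) = dot;
    }
  }
  return out;
}

// One ELSC direction: perturb at column ci (keep sequences carrying its
// modal residue), evaluate at column cj.  -ln prod_y C(N_y,n_y)/C(N_y,m_y)
// with m_y the largest-remainder "ideal" counts summing to the
// subalignment size.  Ties broken toward the alphabetically first residue.
static double elscDir(const IntegerMatrix& A, int ci, int cj) {
  const int n = A.nrow();
  std::vector<int> valid;
  valid.reserve(n);
  int cnti[20] = {0};
  for (int s = 0; s < n; ++s) {
    if (A(s, ci) > 0 && A(s, cj) > 0) {
      valid.push_back(s);
      ++cnti[A(s, ci) - 1];
    }
  }
  const int Nall = (int)valid.size();
  if (Nall == 0) return NA_REAL;
  int modal = 0;
  for (int x = 1; x < 20; ++x)
    if (cnti[x] > cnti[modal]) modal = x;
  int Ny[20] = {0}, ny[20] = {0};
  int nsub = 0;
  for (int s : valid) {
    const int y = A(s, cj) - 1;
    ++Ny[y];
    if (A(s, ci) - 1 == modal) {
      ++ny[y];
      ++nsub;
    }
  }
  // ideal counts m_y: floor(nsub*Ny/Nall), remainder by largest fraction
  int my[20];
  double frac[20];
  int assigned = 0;
  for (int y = 0; y < 20; ++y) {
    const double ideal = (double)nsub * Ny[y] / Nall;
    my[y] = (int)std::floor(ideal);
    frac[y] = ideal - my[y];
    assigned += my[y];
  }
  int rem = nsub - assigned;
  while (rem > 0) {
    int best = -1;
    for (int y = 0; y < 20; ++y)
      if (frac[y] > 0 && (best < 0 || frac[y] > frac[best])) best = y;
    my[best] += 1;
    frac[best] = 0.0;
    --rem;
  }
  double score = 0.0;
  for (int y = 0; y < 20; ++y) {
    if (Ny[y] == 0) continue;
    score += R::lchoose(Ny[y], my[y]) - R::lchoose(Ny[y], ny[y]);
  }
  return score;
}

// [[Rcpp::export]]
NumericMatrix elscKernel(IntegerMatrix A, IntegerVector cols) {
  const int m = cols.size();
  NumericMatrix out(m, m);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      const double d1 = elscDir(A, cols[a] - 1, cols[b] - 1);
      const double d2 = elscDir(A, cols[b] - 1, cols[a] - 1);
      if (ISNA(d1) || ISNA(d2)) continue;
      out(a, b) = out(b, a) = 0.5 * (d1 + d2);
    }
  }
  return out;
}

// log continuous-binomial density of (possibly fractional) count k out
// of n at background rate p, via lgamma
static inline double lbinomDens(double k, double n, double p) {
  return R::lgammafn(n + 1.0) - R::lgammafn(k + 1.0) -
         R::lgammafn(n - k + 1.0) + k * std::log(p) +
         (n - k) * std::log(1.0 - p);
}

// One SCA direction: perturb at ci (modal-residue subalignment of size
// M), measure the statistical-energy shift at cj.  Energies are
// log-binomial probabilities of the residue frequency relative to the
// background frequencies q, both evaluated at depth M so that identical
// sub/full frequencies give exactly zero shift.  Residue classes absent
// from the background are excluded.  kT* = 1.
static double scaDir(const IntegerMatrix& A, int ci, int cj,
                     const NumericVector& q) {
  const int n = A.nrow();
  int cnti[20] = {0};
  std::vector<int> valid;
  valid.reserve(n);
  for (int s = 0; s < n; ++s) {
    if (A(s, ci) > 0 && A(s, cj) > 0) {
      valid.push_back(s);
      ++cnti[A(s, ci) - 1];
    }
  }
  const int N = (int)valid.size();
  if (N == 0) return NA_REAL;
  int modal = 0;
  for (int x = 1; x < 20; ++x)
    if (cnti[x] > cnti[modal]) modal = x;
  int fx[20] = {0}, gx[20] = {0};
  int M = 0;
  for (int s : valid) {
    const int x = A(s, cj) - 1;
    ++fx[x];
    if (A(s, ci) - 1 == modal) {
      ++gx[x];
      ++M;
    }
  }
  if (M == 0) return NA_REAL;
  double ss = 0.0;
  for (int x = 0; x < 20; ++x) {
    if (q[x] <= 0.0 || q[x] >= 1.0) continue;
    const double f = (double)fx[x] / N;
    const double d = lbinomDens((double)gx[x], M, q[x]) -
                     lbinomDens(f * M, M, q[x]);
    ss += d * d;
  }
  return std::sqrt(ss);
}

// [[Rcpp::export]]
NumericMatrix scaKernel(IntegerMatrix A, IntegerVector cols,
                        NumericVector bg) {
  const int m = cols.size();
  NumericMatrix out(m, m);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      const double d1 = scaDir(A, cols[a] - 1, cols[b] - 1, bg);
      const double d2 = scaDir(A, cols[b] - 1, cols[a] - 1, bg);
      if (ISNA(d1) || ISNA(d2)) continue;
      out(a, b) = out(b, a) = 0.5 * (d1 + d2);
    }
  }
  return out;
}
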