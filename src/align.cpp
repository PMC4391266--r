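#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap conventions throughout: a gap of length k costs open + k * extend
// (BLAST-style), so the first gapped column already pays open + extend.

static const double NEG = -1e30;

// raw-pointer SW kernel against a precomputed subject profile:
// prof is K x n row-major (prof[c * n + j] = sm[c, b[j]]), so the inner
// loop reads contiguous memory.
static double sw_score_prof(const int *a, int m, const double *prof,
                            int n, double gap_open, double gap_extend) {
  std::vector<double> H(n + 1, 0.0), E(n + 1, NEG);
  const double gox = gap_open + gap_extend;
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    double diag = 0.0;       // H[i-1][j-1]
    double F = NEG;          // gap in b (vertical)
    const double *row = prof + (size_t) a[i - 1] * n;
    double *Hp = H.data(), *Ep = E.data();
    for (int j = 1; j <= n; ++j) {
      double e = Ep[j] - gap_extend, e2 = Hp[j] - gox;
      e = e > e2 ? e : e2;
      Ep[j] = e;
      double f2 = Hp[j - 1] - gox;
      F -= gap_extend;
      if (f2 > F) F = f2;
      double h = diag + row[j - 1];
      if (e > h) h = e;
      if (F > h) h = F;
      if (h < 0.0) h = 0.0;
      diag = Hp[j];
      Hp[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

static std::vector<double> make_profile(const int *b, int n,
                                        const double *sm, int K) {
  std::vector<double> prof((size_t) K * n);
  for (int c = 0; c < K; ++c)
    for (int j = 0; j < n; ++j)
      prof[(size_t) c * n + j] = sm[c + (size_t) b[j] * K];
  return prof;
}

// Smith-Waterman optimal local score, linear memory, score only.
// a, b: 0-based indices into the substitution matrix.
// [[Rcpp::export]]
double cpp_sw_score(IntegerVector a, IntegerVector b, NumericMatrix sm,
                    double gap_open, double gap_extend) {
  std::vector<double> prof = make_profile(b.begin(), b.size(),
                                          sm.begin(), sm.nrow());
  return sw_score_prof(a.begin(), a.size(), prof.data(), b.size(),
                       gap_open, gap_extend);
}

// Full Smith-Waterman with traceback: returns score, number of identical
// aligned residue pairs, and number of aligned columns (gaps included).
// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, NumericMatrix sm,
                  double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E(i, j) = std::max(E(i, j - 1) - gap_extend,
                         H(i, j - 1) - gap_open - gap_extend);
      F(i, j) = std::max(F(i - 1, j) - gap_extend,
                         H(i - 1, j) - gap_open - gap_extend);
      double h = H(i - 1, j - 1) + sm(a[i - 1], b[j - 1]);
      h = std::max(h, E(i, j));
      h = std::max(h, F(i, j));
      h = std::max(h, 0.0);
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback from (bi, bj) until H == 0
  int i = bi, j = bj, ident = 0, cols = 0;
  while (i > 0 && j > 0 && H(i, j) > 0) {
    if (H(i, j) == H(i - 1, j - 1) + sm(a[i - 1], b[j - 1])) {
      if (a[i - 1] == b[j - 1]) ++ident;
      ++cols; --i; --j;
    } else if (H(i, j) == E(i, j)) {
      while (j > 0 && E(i, j) == E(i, j - 1) - gap_extend) { ++cols; --j; }
      ++cols; --j;
    } else {
      while (i > 0 && F(i, j) == F(i - 1, j) - gap_extend) { ++cols; --i; }
      ++cols; --i;
    }
  }
  return List::create(_["score"] = best, _["identical"] = ident,
                      _["columns"] = cols);
}

// All unordered pairs i<j among a list of integer-coded sequences;
// returns a numeric vector of SW scores in pair order (1,2),(1,3),...
// [[Rcpp::export]]
NumericVector cpp_sw_all_pairs(List seqs, NumericMatrix sm,
                               double gap_open, double gap_extend) {
  const int n = seqs.size();
  const int K = sm.nrow();
  const double *smp = sm.begin();
  std::vector<std::vector<int> > ss(n);
  std::vector<std::vector<double> > profs(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::vector<int> >(seqs[i]);
    profs[i] = make_profile(ss[i].data(), (int) ss[i].size(), smp, K);
  }
  NumericVector out((double) n * (n - 1) / 2);
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; ++i) {
    const int *ai = ss[i].data();
    const int mi = (int) ss[i].size();
    for (int j = i + 1; j < n; ++j) {
      out[k++] = sw_score_prof(ai, mi, profs[j].data(),
                               (int) ss[j].size(), gap_open, gap_extend);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Global (Needleman-Wunsch/Gotoh) alignment of two profiles with affine
// gaps; end gaps are penalized like internal gaps. Profiles are K x L
// residue-frequency matrices (gap mass allowed; gap rows score 0 via sm).
// Column score s(i,j) = pA[,i]' S pB[,j] (sum-of-pairs expectation).
// Returns 1-based source-column indices per output column (0 = gap).
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix pa, NumericMatrix pb, NumericMatrix sm,
                       double gap_open, double gap_extend) {
  const int K = pa.nrow(), La = pa.ncol(), Lb = pb.ncol();
  // SA = S' * pa : K x La, so s(i,j) = sum_k pb(k,j) * SA(k,i)
  NumericMatrix SA(K, La);
  for (int i = 0; i < La; ++i)
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int l = 0; l < K; ++l) acc += sm(l, k) * pa(l, i);
      SA(k, i) = acc;
    }
  NumericMatrix H(La + 1, Lb + 1), E(La + 1, Lb + 1), F(La + 1, Lb + 1);
  H(0, 0) = 0.0; E(0, 0) = NEG; F(0, 0) = NEG;
  for (int j = 1; j <= Lb; ++j) {
    E(0, j) = -gap_open - gap_extend * j;
    H(0, j) = E(0, j);
    F(0, j) = NEG;
  }
  for (int i = 1; i <= La; ++i) {
    F(i, 0) = -gap_open - gap_extend * i;
    H(i, 0) = F(i, 0);
    E(i, 0) = NEG;
  }
  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += pb(k, j - 1) * SA(k, i - 1);
      E(i, j) = std::max(E(i, j - 1) - gap_extend,
                         H(i, j - 1) - gap_open - gap_extend);
      F(i, j) = std::max(F(i - 1, j) - gap_extend,
                         H(i - 1, j) - gap_open - gap_extend);
      double h = H(i - 1, j - 1) + s;
      h = std::max(h, E(i, j));
      H(i, j) = std::max(h, F(i, j));
    }
  }
  // traceback (prefer diagonal, then E, then F, for determinism)
  std::vector<int> ia, ib;
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += pb(k, j - 1) * SA(k, i - 1);
      if (H(i, j) == H(i - 1, j - 1) + s) {
        ia.push_back(i); ib.push_back(j); --i; --j; continue;
      }
    }
    if (j > 0 && H(i, j) == E(i, j)) {
      while (j > 1 && E(i, j) == E(i, j - 1) - gap_extend) {
        ia.push_back(0); ib.push_back(j); --j;
      }
      ia.push_back(0); ib.push_back(j); --j; continue;
    }
    if (i > 0) {
      while (i > 1 && F(i, j) == F(i - 1, j) - gap_extend) {
        ia.push_back(i); ib.push_back(0); --i;
      }
      ia.push_back(i); ib.push_back(0); --i; continue;
    }
    // j > 0, leading gap in A
    ia.push_back(0); ib.push_back(j); --j;
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());
  return List::create(_["ia"] = wrap(ia), _["ib"] = wrap(ib),
                      _["score"] = H(La, Lb));
}
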