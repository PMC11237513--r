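#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels.  Sequences arrive as 0-based
// integer codes into the substitution matrix; a gap of length L costs
// gap_open + gap_extend * L (NCBI convention: the first gap residue pays
// both the opening and one extension).
//
// Three DP states per cell: M (a_i aligned to b_j), IX (gap in subject,
// consuming query), IY (gap in query, consuming subject).  Traceback ties
// prefer diagonal (M), then up (IX), then left (IY) -- determinism over
// biological nuance.

static const double NEG_INF = -1e30;

// state codes for traceback pointers
enum { PTR_NONE = 0, PTR_M = 1, PTR_IX = 2, PTR_IY = 3, PTR_START = 4 };

static inline int idx(int i, int j, int m) { return i * (m + 1) + j; }

// pick predecessor with priority M > IX > IY (> START for local M-state)
static inline int argmax3(double vm, double vx, double vy, double &best) {
  best = vm; int p = PTR_M;
  if (vx > best) { best = vx; p = PTR_IX; }
  if (vy > best) { best = vy; p = PTR_IY; }
  return p;
}

// [[Rcpp::export(name = ".align_local")]]
List align_local(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double gi = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> M((n + 1) * (m + 1), NEG_INF),
      IX((n + 1) * (m + 1), NEG_INF), IY((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> pM((n + 1) * (m + 1), PTR_NONE),
      pX((n + 1) * (m + 1), PTR_NONE), pY((n + 1) * (m + 1), PTR_NONE);

  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = idx(i, j, m), cd = idx(i - 1, j - 1, m),
                cu = idx(i - 1, j, m), cl = idx(i, j - 1, m);
      // M: start a fresh alignment (score 0) or extend any state
      double prev; int p = argmax3(M[cd], IX[cd], IY[cd], prev);
      if (prev < 0.0) { prev = 0.0; p = PTR_START; }
      M[c] = prev + sub(a[i - 1], b[j - 1]);
      pM[c] = (unsigned char)p;
      // IX: gap in subject (move up); a gap following an opposite-strand
      // gap (IY) opens anew
      double vx; int px = argmax3(M[cu] - gi, IX[cu] - ge, IY[cu] - gi, vx);
      IX[c] = vx; pX[c] = (unsigned char)px;
      // IY: gap in query (move left)
      double vy; int py = argmax3(M[cl] - gi, IX[cl] - gi, IY[cl] - ge, vy);
      IY[c] = vy; pY[c] = (unsigned char)py;
      // local optimum always ends on an aligned pair
      if (M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }
  if (bi < 0)
    return List::create(_["score"] = 0.0, _["empty"] = true);

  // traceback from the best M cell
  int i = bi, j = bj, state = PTR_M;
  long n_ident = 0, n_cols = 0;
  int qe = bi, se = bj, qs = bi, ss = bj;
  while (true) {
    const int c = idx(i, j, m);
    if (state == PTR_M) {
      ++n_cols;
      if (a[i - 1] == b[j - 1]) ++n_ident;
      qs = i; ss = j;
      int p = pM[c];
      --i; --j;
      if (p == PTR_START) break;
      state = p;
    } else if (state == PTR_IX) {
      ++n_cols;
      state = pX[c];
      --i;
    } else { // PTR_IY
      ++n_cols;
      state = pY[c];
      --j;
    }
  }
  return List::create(_["score"] = best, _["empty"] = false,
                      _["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se,
                      _["n_ident"] = (double)n_ident,
                      _["n_cols"] = (double)n_cols);
}

// [[Rcpp::export(name = ".align_global")]]
List align_global(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double gi = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> M((n + 1) * (m + 1), NEG_INF),
      IX((n + 1) * (m + 1), NEG_INF), IY((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> pM((n + 1) * (m + 1), PTR_NONE),
      pX((n + 1) * (m + 1), PTR_NONE), pY((n + 1) * (m + 1), PTR_NONE);

  M[idx(0, 0, m)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    IX[idx(i, 0, m)] = -(gap_open + ge * i);
    pX[idx(i, 0, m)] = (i == 1) ? PTR_M : PTR_IX;
  }
  for (int j = 1; j <= m; ++j) {
    IY[idx(0, j, m)] = -(gap_open + ge * j);
    pY[idx(0, j, m)] = (j == 1) ? PTR_M : PTR_IY;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = idx(i, j, m), cd = idx(i - 1, j - 1, m),
                cu = idx(i - 1, j, m), cl = idx(i, j - 1, m);
      double prev; int p = argmax3(M[cd], IX[cd], IY[cd], prev);
      M[c] = prev + sub(a[i - 1], b[j - 1]);
      pM[c] = (unsigned char)p;
      double vx; int px = argmax3(M[cu] - gi, IX[cu] - ge, IY[cu] - gi, vx);
      IX[c] = vx; pX[c] = (unsigned char)px;
      double vy; int py = argmax3(M[cl] - gi, IX[cl] - gi, IY[cl] - ge, vy);
      IY[c] = vy; pY[c] = (unsigned char)py;
    }
  }
  const int c0 = idx(n, m, m);
  double score; int state = argmax3(M[c0], IX[c0], IY[c0], score);

  int i = n, j = m;
  long n_ident = 0, n_cols = 0;
  while (i > 0 || j > 0) {
    const int c = idx(i, j, m);
    if (state == PTR_M) {
      ++n_cols;
      if (a[i - 1] == b[j - 1]) ++n_ident;
      state = pM[c];
      --i; --j;
    } else if (state == PTR_IX) {
      ++n_cols;
      state = pX[c];
      --i;
    } else {
      ++n_cols;
      state = pY[c];
      --j;
    }
  }
  return List::create(_["score"] = score, _["n_ident"] = (double)n_ident,
                      _["n_cols"] = (double)n_cols);
}
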