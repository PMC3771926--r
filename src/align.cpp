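#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap dynamic programming kernels operating on a precomputed
// position-vs-position score matrix S (rows = positions of A, cols =
// positions of B). Working on scores rather than residues lets the same
// kernel serve residue-residue, profile-profile and PSSM-sequence
// alignment. A gap of length L costs open + L * ext (the SSEARCH/Biostrings
// convention).

static const double NEG = -1e30;

// Needleman-Wunsch (global) with affine gaps and optional free end gaps.
// Returns a 2 x n integer path matrix: row 1 = 1-based index into A's
// positions (0 = gap), row 2 = same for B. Ties prefer diagonal, then a
// gap in B (consume A), then a gap in A; this makes the traceback
// deterministic.
// [[Rcpp::export]]
IntegerMatrix nw_affine_path(NumericMatrix S, double open, double ext,
                             bool free_ends = true) {
  const int n = S.nrow(), m = S.ncol();
  const size_t W = (size_t)(m + 1);
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };

  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // predecessor state (0 = M, 1 = X, 2 = Y) for each state's optimum
  std::vector<unsigned char> pM((n + 1) * W, 0), pX((n + 1) * W, 0),
      pY((n + 1) * W, 0);

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = free_ends ? 0.0 : -(open + ext * i);
    pX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = free_ends ? 0.0 : -(open + ext * j);
    pY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal move
      double bm = M[at(i - 1, j - 1)];
      unsigned char sm = 0;
      if (X[at(i - 1, j - 1)] > bm) { bm = X[at(i - 1, j - 1)]; sm = 1; }
      if (Y[at(i - 1, j - 1)] > bm) { bm = Y[at(i - 1, j - 1)]; sm = 2; }
      M[at(i, j)] = bm + S(i - 1, j - 1);
      pM[at(i, j)] = sm;
      // X: consume A (gap in B)
      double ox = M[at(i - 1, j)] - open - ext;
      double ex = X[at(i - 1, j)] - ext;
      if (ox >= ex) { X[at(i, j)] = ox; pX[at(i, j)] = 0; }
      else          { X[at(i, j)] = ex; pX[at(i, j)] = 1; }
      // Y: consume B (gap in A)
      double oy = M[at(i, j - 1)] - open - ext;
      double ey = Y[at(i, j - 1)] - ext;
      if (oy >= ey) { Y[at(i, j)] = oy; pY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = ey; pY[at(i, j)] = 2; }
    }
  }

  // locate the end cell
  int ei = n, ej = m;
  unsigned char es = 0;
  {
    double best = M[at(n, m)];
    es = 0;
    if (X[at(n, m)] > best) { best = X[at(n, m)]; es = 1; }
    if (Y[at(n, m)] > best) { best = Y[at(n, m)]; es = 2; }
    if (free_ends) {
      for (int i = 0; i <= n; ++i) {
        for (int s = 0; s < 3; ++s) {
          double v = (s == 0 ? M : (s == 1 ? X : Y))[at(i, m)];
          if (v > best) { best = v; ei = i; ej = m; es = (unsigned char)s; }
        }
      }
      for (int j = 0; j <= m; ++j) {
        for (int s = 0; s < 3; ++s) {
          double v = (s == 0 ? M : (s == 1 ? X : Y))[at(n, j)];
          if (v > best) { best = v; ei = n; ej = j; es = (unsigned char)s; }
        }
      }
    }
  }

  std::vector<int> ra, rb;  // reversed path
  // free trailing gaps beyond the chosen end cell
  for (int j = m; j > ej; --j) { ra.push_back(0); rb.push_back(j); }
  for (int i = n; i > ei; --i) { ra.push_back(i); rb.push_back(0); }

  int i = ei, j = ej;
  unsigned char s = es;
  while (i > 0 || j > 0) {
    if (s == 0) {
      if (i == 0 && j == 0) break;
      ra.push_back(i); rb.push_back(j);
      s = pM[at(i, j)]; --i; --j;
    } else if (s == 1) {
      ra.push_back(i); rb.push_back(0);
      s = pX[at(i, j)]; --i;
    } else {
      ra.push_back(0); rb.push_back(j);
      s = pY[at(i, j)]; --j;
    }
  }

  const int L = (int)ra.size();
  IntegerMatrix path(2, L);
  for (int k = 0; k < L; ++k) {
    path(0, k) = ra[L - 1 - k];
    path(1, k) = rb[L - 1 - k];
  }
  return path;
}

// Smith-Waterman (local) with affine gaps on a score matrix. Returns
// c(score, a_start, a_end, b_start, b_end), 1-based inclusive spans; all
// zero when no positive-scoring alignment exists. Ties between equal
// maxima resolve to the lowest a index, then the lowest b index.
// [[Rcpp::export]]
NumericVector sw_affine_best(NumericMatrix S, double open, double ext) {
  const int n = S.nrow(), m = S.ncol();
  const size_t W = (size_t)(m + 1);
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };

  std::vector<double> M((n + 1) * W, 0.0), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // predecessor state for traceback; 3 in pM marks a fresh local start
  std::vector<unsigned char> pM((n + 1) * W, 3), pX((n + 1) * W, 0),
      pY((n + 1) * W, 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double bm = M[at(i - 1, j - 1)];
      unsigned char sm = 0;
      if (X[at(i - 1, j - 1)] > bm) { bm = X[at(i - 1, j - 1)]; sm = 1; }
      if (Y[at(i - 1, j - 1)] > bm) { bm = Y[at(i - 1, j - 1)]; sm = 2; }
      double v = bm + S(i - 1, j - 1);
      if (v <= 0.0) { M[at(i, j)] = 0.0; pM[at(i, j)] = 3; }
      else          { M[at(i, j)] = v;   pM[at(i, j)] = sm; }

      double ox = M[at(i - 1, j)] - open - ext;
      double ex = X[at(i - 1, j)] - ext;
      if (ox >= ex) { X[at(i, j)] = ox; pX[at(i, j)] = 0; }
      else          { X[at(i, j)] = ex; pX[at(i, j)] = 1; }
      double oy = M[at(i, j - 1)] - open - ext;
      double ey = Y[at(i, j - 1)] - ext;
      if (oy >= ey) { Y[at(i, j)] = oy; pY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = ey; pY[at(i, j)] = 2; }

      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }

  NumericVector out(5);
  if (best <= 0.0) return out;
  out[0] = best;
  // traceback from the best M cell to the local start
  int i = bi, j = bj;
  unsigned char s = 0;
  int ai = bi, aj = bj;
  while (true) {
    if (s == 0) {
      if (pM[at(i, j)] == 3) { ai = i; aj = j; break; }
      s = pM[at(i, j)]; --i; --j;
      ai = i + 1; aj = j + 1;
    } else if (s == 1) {
      s = pX[at(i, j)]; --i;
    } else {
      s = pY[at(i, j)]; --j;
    }
  }
  out[1] = ai; out[2] = bi; out[3] = aj; out[4] = bj;
  return out;
}
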