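#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap alignment over a precomputed position score matrix.
// S[i,j] is the score for pairing position i of `a` with position j of `b`
// (rows may come from a substitution matrix or from a PSSM, which is what
// lets one core serve both sequence-sequence and profile-sequence search).
// Gap cost convention: a gap of length L costs gap_open + (L-1)*gap_extend,
// with gap_open/gap_extend passed as positive numbers (BLAST-style 11/1).
//
// Returns the optimal score plus traceback as two integer vectors of equal
// length: 1-based indices into a and b, 0 where the column is a gap.
// [[Rcpp::export]]
List align_core(NumericMatrix S, double gap_open, double gap_extend,
                bool local) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e18;

  // state matrices, (n+1) x (m+1), flattened
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG); // gap in b (consumes a)
  std::vector<double> Y((n + 1) * (m + 1), NEG); // gap in a (consumes b)
  // traceback pointers
  std::vector<signed char> pm((n + 1) * (m + 1), -1);
  std::vector<signed char> px((n + 1) * (m + 1), -1);
  std::vector<signed char> py((n + 1) * (m + 1), -1);

  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      X[at(i, 0)] = -(gap_open + (i - 1) * gap_extend);
      px[at(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Y[at(0, j)] = -(gap_open + (j - 1) * gap_extend);
      py[at(0, j)] = (j == 1) ? 0 : 1;
    }
  } else {
    for (int i = 1; i <= n; ++i) M[at(i, 0)] = 0.0;
    for (int j = 1; j <= m; ++j) M[at(0, j)] = 0.0;
    for (int i = 0; i <= n; ++i) pm[at(i, 0)] = 3;
    for (int j = 0; j <= m; ++j) pm[at(0, j)] = 3;
  }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // X: gap in b, consuming a_i
      double xm = M[at(i - 1, j)] - gap_open;
      double xx = X[at(i - 1, j)] - gap_extend;
      double xy = Y[at(i - 1, j)] - gap_open;
      double xv = xm; signed char xp = 0;
      if (xx > xv) { xv = xx; xp = 1; }
      if (xy > xv) { xv = xy; xp = 2; }
      X[at(i, j)] = xv; px[at(i, j)] = xp;

      // Y: gap in a, consuming b_j
      double ym = M[at(i, j - 1)] - gap_open;
      double yy = Y[at(i, j - 1)] - gap_extend;
      double yx = X[at(i, j - 1)] - gap_open;
      double yv = ym; signed char yp = 0;
      if (yy > yv) { yv = yy; yp = 1; }
      if (yx > yv) { yv = yx; yp = 2; }
      Y[at(i, j)] = yv; py[at(i, j)] = yp;

      // M: pair a_i with b_j
      double dm = M[at(i - 1, j - 1)];
      double dx = X[at(i - 1, j - 1)];
      double dy = Y[at(i - 1, j - 1)];
      double dv = dm; signed char dp = 0;
      if (dx > dv) { dv = dx; dp = 1; }
      if (dy > dv) { dv = dy; dp = 2; }
      double cell = dv + S(i - 1, j - 1);
      if (local && cell < 0.0) { cell = 0.0; dp = 3; }
      M[at(i, j)] = cell; pm[at(i, j)] = dp;

      if (local && cell > best) { best = cell; bi = i; bj = j; }
    }
  }

  int state; // 0 = M, 1 = X, 2 = Y
  if (local) {
    state = 0;
  } else {
    bi = n; bj = m;
    double bv = M[at(n, m)]; state = 0;
    if (X[at(n, m)] > bv) { bv = X[at(n, m)]; state = 1; }
    if (Y[at(n, m)] > bv) { bv = Y[at(n, m)]; state = 2; }
    best = bv;
  }

  std::vector<int> ai, bj_out;
  int i = bi, j = bj;
  if (!(local && best == 0.0)) {
    while (i > 0 || j > 0) {
      if (state == 0) {
        signed char p = pm[at(i, j)];
        if (p == 3) break; // local alignment start
        if (i == 0 && j == 0) break;
        ai.push_back(i); bj_out.push_back(j);
        --i; --j; state = p;
      } else if (state == 1) {
        signed char p = px[at(i, j)];
        ai.push_back(i); bj_out.push_back(0);
        --i; state = (p == 1) ? 1 : (p == 2 ? 2 : 0);
      } else {
        signed char p = py[at(i, j)];
        ai.push_back(0); bj_out.push_back(j);
        --j; state = (p == 1) ? 2 : (p == 2 ? 1 : 0);
      }
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj_out.begin(), bj_out.end());

  return List::create(_["score"] = best,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bj_out));
}
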