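#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment of a real score matrix.
//
// Three-state DP (match M / gap-in-template X / gap-in-query Y) with gap run
// cost open + (len-1)*extend. X<->Y transitions are allowed (a deletion may
// be followed directly by an insertion), each opening its own run. With
// ends_free = true, terminal gap runs in both sequences cost nothing and the
// empty alignment (score 0) is admissible; with ends_free = false the
// alignment is strictly global and terminal gaps are charged.
//
// Traceback is deterministic: among equal-scoring predecessors the diagonal
// (M) is preferred, then up (X), then left (Y).
// [[Rcpp::export(name = ".align_dp_cpp")]]
List align_dp(NumericMatrix S, double gap_open, double gap_extend,
              bool ends_free) {
  const int nq = S.nrow(), nt = S.ncol();
  if (nq < 1 || nt < 1) stop("empty score matrix");
  const double NEG = -1e18;

  NumericMatrix M(nq + 1, nt + 1), X(nq + 1, nt + 1), Y(nq + 1, nt + 1);
  IntegerMatrix pM(nq + 1, nt + 1), pX(nq + 1, nt + 1), pY(nq + 1, nt + 1);
  // predecessor codes: 0 = stop, 1 = M, 2 = X, 3 = Y

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG; pM(0, 0) = 0;
  for (int i = 1; i <= nq; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = ends_free ? 0.0 : gap_open + (i - 1) * gap_extend;
    pX(i, 0) = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= nt; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = ends_free ? 0.0 : gap_open + (j - 1) * gap_extend;
    pY(0, j) = (j == 1) ? 1 : 3;
  }

  for (int i = 1; i <= nq; ++i) {
    for (int j = 1; j <= nt; ++j) {
      // M: preference M > X > Y > fresh start (ends_free only)
      double best = M(i - 1, j - 1); int p = 1;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); p = 2; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); p = 3; }
      if (ends_free && 0.0 > best) { best = 0.0; p = 0; }
      M(i, j) = S(i - 1, j - 1) + best;
      pM(i, j) = p;

      double xm = M(i - 1, j) + gap_open;
      double xx = X(i - 1, j) + gap_extend;
      double xy = Y(i - 1, j) + gap_open;
      best = xm; p = 1;
      if (xx > best) { best = xx; p = 2; }
      if (xy > best) { best = xy; p = 3; }
      X(i, j) = best; pX(i, j) = p;

      double ym = M(i, j - 1) + gap_open;
      double yx = X(i, j - 1) + gap_open;
      double yy = Y(i, j - 1) + gap_extend;
      best = ym; p = 1;
      if (yx > best) { best = yx; p = 2; }
      if (yy > best) { best = yy; p = 3; }
      Y(i, j) = best; pY(i, j) = p;
    }
  }

  double score;
  int ci, cj, cstate; // traceback cursor; state 1 = M, 2 = X, 3 = Y
  if (ends_free) {
    score = 0.0; ci = 0; cj = 0; cstate = 0; // empty alignment admissible
    for (int i = 1; i <= nq; ++i)
      for (int j = 1; j <= nt; ++j)
        if (M(i, j) > score) { score = M(i, j); ci = i; cj = j; cstate = 1; }
  } else {
    score = M(nq, nt); cstate = 1;
    if (X(nq, nt) > score) { score = X(nq, nt); cstate = 2; }
    if (Y(nq, nt) > score) { score = Y(nq, nt); cstate = 3; }
    ci = nq; cj = nt;
  }

  std::vector<int> qi, ti;
  while (cstate != 0 && !(ci == 0 && cj == 0)) {
    if (cstate == 1) {
      qi.push_back(ci); ti.push_back(cj);
      int p = pM(ci, cj);
      --ci; --cj;
      cstate = p;
    } else if (cstate == 2) {
      int p = pX(ci, cj);
      --ci;
      cstate = p;
    } else {
      int p = pY(ci, cj);
      --cj;
      cstate = p;
    }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(ti.begin(), ti.end());

  IntegerMatrix pairs(qi.size(), 2);
  for (size_t k = 0; k < qi.size(); ++k) {
    pairs(k, 0) = qi[k];
    pairs(k, 1) = ti[k];
  }
  return List::create(_["pairs"] = pairs, _["score"] = score);
}
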