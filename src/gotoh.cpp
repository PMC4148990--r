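#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state DP) over integer-encoded
// sequences. Scores are integers on the caller's scale; a gap run of length L
// costs open + L * extend. End gaps are penalized (true global alignment).
//
// States: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a,
// consumes b). Ties are broken by state priority M > X > Y, both when picking
// the final state and each predecessor, giving a deterministic traceback that
// prefers diagonal moves, then gaps in b, then gaps in a.

static const long NEG = LONG_MIN / 4;

// [[Rcpp::export]]
List gotoh_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix submat,
                     int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    stop("both sequences must be non-empty");
  const long go = gap_open, ge = gap_extend;

  std::vector<long> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  // predecessor state per cell/state, packed as signed char
  std::vector<signed char> pM((n + 1) * (m + 1), -1),
      pX((n + 1) * (m + 1), -1), pY((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(go + (long)i * ge);
    pX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(go + (long)j * ge);
    pY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal
      long cands[3];
      cands[0] = M[at(i - 1, j - 1)];
      cands[1] = X[at(i - 1, j - 1)];
      cands[2] = Y[at(i - 1, j - 1)];
      int best = 0;
      for (int s = 1; s < 3; ++s)
        if (cands[s] > cands[best]) best = s;
      if (cands[best] > NEG) {
        M[at(i, j)] = cands[best] + submat(a[i - 1], b[j - 1]);
        pM[at(i, j)] = best;
      }
      // X: gap in b (consume a[i-1])
      cands[0] = M[at(i - 1, j)] - (go + ge);
      cands[1] = X[at(i - 1, j)] - ge;
      cands[2] = Y[at(i - 1, j)] - (go + ge);
      best = 0;
      for (int s = 1; s < 3; ++s)
        if (cands[s] > cands[best]) best = s;
      if (cands[best] > NEG / 2) {
        X[at(i, j)] = cands[best];
        pX[at(i, j)] = best;
      }
      // Y: gap in a (consume b[j-1])
      cands[0] = M[at(i, j - 1)] - (go + ge);
      cands[1] = X[at(i, j - 1)] - (go + ge);
      cands[2] = Y[at(i, j - 1)] - ge;
      best = 0;
      for (int s = 1; s < 3; ++s)
        if (cands[s] > cands[best]) best = s;
      if (cands[best] > NEG / 2) {
        Y[at(i, j)] = cands[best];
        pY[at(i, j)] = best;
      }
    }
  }

  long fin[3] = {M[at(n, m)], X[at(n, m)], Y[at(n, m)]};
  int state = 0;
  for (int s = 1; s < 3; ++s)
    if (fin[s] > fin[state]) state = s;
  const long score = fin[state];

  // traceback
  std::vector<int> ia, ib;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == 0) {
      prev = pM[at(i, j)];
      ia.push_back(i);
      ib.push_back(j);
      --i; --j;
    } else if (state == 1) {
      prev = pX[at(i, j)];
      ia.push_back(i);
      ib.push_back(0);
      --i;
    } else {
      prev = pY[at(i, j)];
      ia.push_back(0);
      ib.push_back(j);
      --j;
    }
    state = prev;
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());

  return List::create(_["score"] = (double)score,
                      _["ia"] = IntegerVector(ia.begin(), ia.end()),
                      _["ib"] = IntegerVector(ib.begin(), ib.end()));
}

// Score-only variant (no traceback matrices kept small is unnecessary at the
// lengths used here, but skipping predecessor bookkeeping is measurably
// faster for the all-vs-all protein stage).
// [[Rcpp::export]]
double gotoh_score_cpp(IntegerVector a, IntegerVector b, IntegerMatrix submat,
                       int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    stop("both sequences must be non-empty");
  const long go = gap_open, ge = gap_extend;
  std::vector<long> M(m + 1, NEG), X(m + 1, NEG), Y(m + 1, NEG);
  std::vector<long> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  M[0] = 0;
  for (int j = 1; j <= m; ++j) Y[j] = -(go + (long)j * ge);
  for (int i = 1; i <= n; ++i) {
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
    M[0] = NEG;
    Y[0] = NEG;
    X[0] = -(go + (long)i * ge);
    for (int j = 1; j <= m; ++j) {
      long d = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      M[j] = (d > NEG / 2) ? d + submat(a[i - 1], b[j - 1]) : NEG;
      X[j] = std::max(Mp[j] - (go + ge),
                      std::max(Xp[j] - ge, Yp[j] - (go + ge)));
      Y[j] = std::max(M[j - 1] - (go + ge),
                      std::max(X[j - 1] - (go + ge), Y[j - 1] - ge));
    }
  }
  return (double)std::max(M[m], std::max(X[m], Y[m]));
}
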