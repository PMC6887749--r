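#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
//
// Sequences arrive as 1-based integer codes into the substitution matrix;
// a gap run of length L costs gap_open + L * gap_ext (so a single-residue
// gap costs gap_open + gap_ext).  `local` switches Smith-Waterman semantics
// (zero floor on the match state, traceback from the best cell) vs global
// Needleman-Wunsch (traceback from the corner).

static const double NEG = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List gotoh_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                     double gap_open, double gap_ext, bool local) {
  const int n = a.size(), m = b.size();
  // state matrices: M (a_i~b_j), X (a_i~gap), Y (gap~b_j)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: which state each cell's max came from (0=M,1=X,2=Y,3=start)
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = local ? 0.0 : NEG;
    X(i, 0) = local ? NEG : -(gap_open + i * gap_ext);
    Y(i, 0) = NEG;
    tbX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = local ? 0.0 : NEG;
    Y(0, j) = local ? NEG : -(gap_open + j * gap_ext);
    X(0, j) = NEG;
    tbY(0, j) = 2;
  }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      // M state
      double vM = M(i - 1, j - 1), vX = X(i - 1, j - 1), vY = Y(i - 1, j - 1);
      double mx = vM; int who = 0;
      if (vX > mx) { mx = vX; who = 1; }
      if (vY > mx) { mx = vY; who = 2; }
      double mval = mx + s;
      if (local && mval < 0.0) { mval = 0.0; who = 3; }
      M(i, j) = mval; tbM(i, j) = who;
      // X state: a_i against gap
      double oM = M(i - 1, j) - gap_open - gap_ext;
      double oX = X(i - 1, j) - gap_ext;
      if (oM >= oX) { X(i, j) = oM; tbX(i, j) = 0; }
      else          { X(i, j) = oX; tbX(i, j) = 1; }
      // Y state: gap against b_j
      double pM = M(i, j - 1) - gap_open - gap_ext;
      double pY = Y(i, j - 1) - gap_ext;
      if (pM >= pY) { Y(i, j) = pM; tbY(i, j) = 0; }
      else          { Y(i, j) = pY; tbY(i, j) = 2; }
      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  int state; double score;
  int i, j;
  if (local) {
    score = best; i = bi; j = bj; state = 0;
    if (best <= 0.0) { // empty local alignment
      return List::create(_["score"] = 0.0,
                          _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0),
                          _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0);
    }
  } else {
    double fM = M(n, m), fX = X(n, m), fY = Y(n, m);
    score = fM; state = 0;
    if (fX > score) { score = fX; state = 1; }
    if (fY > score) { score = fY; state = 2; }
    i = n; j = m;
  }

  std::vector<int> ai, bi_v; // 0 encodes a gap
  while (true) {
    if (local && state == 0 && M(i, j) == 0.0) break; // local path start
    if (i == 0 && j == 0) break;
    if (state == 0) {
      int prev = tbM(i, j);
      ai.push_back(i); bi_v.push_back(j);
      --i; --j;
      state = (prev == 3) ? 0 : prev;
    } else if (state == 1) {
      int prev = tbX(i, j);
      ai.push_back(i); bi_v.push_back(0);
      --i; state = prev;
    } else {
      int prev = tbY(i, j);
      ai.push_back(0); bi_v.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi_v.begin(), bi_v.end());

  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  for (size_t k = 0; k < ai.size(); ++k) {
    if (ai[k] > 0) { if (!a_start) a_start = ai[k]; a_end = ai[k]; }
    if (bi_v[k] > 0) { if (!b_start) b_start = bi_v[k]; b_end = bi_v[k]; }
  }
  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai), _["b_idx"] = wrap(bi_v),
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}

// Profile-profile global alignment for progressive MSA.
// Profiles are integer matrices (rows = sequences, columns = alignment
// columns), entries 1-based codes into `sub`, 0 = gap.  Column-column score
// is the mean substitution score over all residue pairs; pairs involving a
// gap contribute 0.  Returns the merged column paths (0 = new gap).

// [[Rcpp::export]]
List profile_align_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix sub,
                       double gap_open, double gap_ext) {
  const int n = A.ncol(), m = B.ncol();
  const int ra = A.nrow(), rb = B.nrow();

  // precompute column-column scores
  NumericMatrix cs(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double tot = 0.0;
      for (int p = 0; p < ra; ++p) {
        const int ca = A(p, i);
        if (ca == 0) continue;
        for (int q = 0; q < rb; ++q) {
          const int cb = B(q, j);
          if (cb == 0) continue;
          tot += sub(ca - 1, cb - 1);
        }
      }
      cs(i, j) = tot / (double)(ra * rb);
    }
  }

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + i * gap_ext); tbX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + j * gap_ext); tbY(0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double vM = M(i - 1, j - 1), vX = X(i - 1, j - 1), vY = Y(i - 1, j - 1);
      double mx = vM; int who = 0;
      if (vX > mx) { mx = vX; who = 1; }
      if (vY > mx) { mx = vY; who = 2; }
      M(i, j) = mx + cs(i - 1, j - 1); tbM(i, j) = who;
      double oM = M(i - 1, j) - gap_open - gap_ext, oX = X(i - 1, j) - gap_ext;
      if (oM >= oX) { X(i, j) = oM; tbX(i, j) = 0; } else { X(i, j) = oX; tbX(i, j) = 1; }
      double pM = M(i, j - 1) - gap_open - gap_ext, pY = Y(i, j - 1) - gap_ext;
      if (pM >= pY) { Y(i, j) = pM; tbY(i, j) = 0; } else { Y(i, j) = pY; tbY(i, j) = 2; }
    }
  }
  double score = M(n, m); int state = 0;
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM(i, j);
      pa.push_back(i); pb.push_back(j); --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX(i, j);
      pa.push_back(i); pb.push_back(0); --i; state = prev;
    } else {
      int prev = tbY(i, j);
      pa.push_back(0); pb.push_back(j); --j; state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["path_a"] = wrap(pa), _["path_b"] = wrap(pb));
}
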