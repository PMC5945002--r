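#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming kernels for profile-HMM scoring and profile-profile
// alignment. Scores are natural-log odds; conversion to bits happens in R.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp((a < b ? a : b) - m));
}

// Forward log-odds under a single-hit uniform-fragment local architecture:
// entry/exit pair (k, l), k <= l, has prior 2 / (L (L + 1)); flanking
// residues are free (odds ratio one). em, ei: L x n log-odds emission
// matrices (position k, residue i). Transition vectors are natural logs of
// core probabilities, index k = transition out of position k (1-based k,
// stored 0-based; entries for k = L unused).
// [[Rcpp::export(name = ".fwd_logodds")]]
double fwd_logodds(NumericMatrix em, NumericMatrix ei,
                   NumericVector lmm, NumericVector lmi, NumericVector lmd,
                   NumericVector lim, NumericVector lii,
                   NumericVector ldm, NumericVector ldd) {
  const int L = em.nrow(), n = em.ncol();
  const double lentry = std::log(2.0) - std::log((double)L) - std::log((double)L + 1.0);
  std::vector<double> M(L + 1), I(L + 1), D(L + 1), Mp(L + 1), Ip(L + 1),
      Dp(L + 1);
  double total = NEG_INF;
  for (int k = 0; k <= L; ++k) M[k] = I[k] = D[k] = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    Mp = M; Ip = I; Dp = D;
    std::fill(M.begin(), M.end(), NEG_INF);
    std::fill(I.begin(), I.end(), NEG_INF);
    std::fill(D.begin(), D.end(), NEG_INF);
    for (int k = 1; k <= L; ++k) {
      double acc = lentry;  // fresh local entry at M_k emitting residue i
      if (k > 1) {
        acc = lse2(acc, Mp[k - 1] + lmm[k - 2]);
        acc = lse2(acc, Ip[k - 1] + lim[k - 2]);
        acc = lse2(acc, Dp[k - 1] + ldm[k - 2]);
      }
      M[k] = em(k - 1, i - 1) + acc;
      // D_k (k >= 2) from M/D at k-1 in the same row (D consumes no residue)
      if (k >= 2) {
        double dacc = lse2(M[k - 1] + lmd[k - 2], D[k - 1] + ldd[k - 2]);
        D[k] = dacc;
      }
      if (k < L) {
        double iacc = lse2(Mp[k] + lmi[k - 1], Ip[k] + lii[k - 1]);
        I[k] = ei(k - 1, i - 1) + iacc;
      }
      total = lse2(total, M[k]);  // local exit after M_k, free C flank
    }
  }
  return total;
}

// Viterbi under the same architecture. Returns max log-odds, the matched
// residue -> match column map (0 = not matched), and alignment span.
// [[Rcpp::export(name = ".vit_logodds")]]
List vit_logodds(NumericMatrix em, NumericMatrix ei,
                 NumericVector lmm, NumericVector lmi, NumericVector lmd,
                 NumericVector lim, NumericVector lii,
                 NumericVector ldm, NumericVector ldd) {
  const int L = em.nrow(), n = em.ncol();
  const double lentry = std::log(2.0) - std::log((double)L) - std::log((double)L + 1.0);
  // state codes in traceback: 0 entry, 1 M, 2 I, 3 D
  NumericMatrix M(n + 1, L + 1), I(n + 1, L + 1), D(n + 1, L + 1);
  IntegerMatrix tbM(n + 1, L + 1), tbI(n + 1, L + 1), tbD(n + 1, L + 1);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(I.begin(), I.end(), NEG_INF);
  std::fill(D.begin(), D.end(), NEG_INF);
  for (int i = 1; i <= n; ++i) {
    for (int k = 1; k <= L; ++k) {
      double best = lentry; int arg = 0;
      if (k > 1) {
        double v = M(i - 1, k - 1) + lmm[k - 2];
        if (v > best) { best = v; arg = 1; }
        v = D(i - 1, k - 1) + ldm[k - 2];  // D -> M emits this residue
        if (v > best) { best = v; arg = 3; }
        v = I(i - 1, k - 1) + lim[k - 2];
        if (v > best) { best = v; arg = 2; }
      }
      M(i, k) = em(k - 1, i - 1) + best; tbM(i, k) = arg;
      if (k >= 2) {
        double vm = M(i, k - 1) + lmd[k - 2];
        double vd = D(i, k - 1) + ldd[k - 2];
        if (vm >= vd) { D(i, k) = vm; tbD(i, k) = 1; } else { D(i, k) = vd; tbD(i, k) = 3; }
      }
      if (k < L) {
        double vm = M(i - 1, k) + lmi[k - 1];
        double vi = I(i - 1, k) + lii[k - 1];
        if (vm >= vi) { I(i, k) = ei(k - 1, i - 1) + vm; tbI(i, k) = 1; }
        else          { I(i, k) = ei(k - 1, i - 1) + vi; tbI(i, k) = 2; }
      }
    }
  }
  double best = NEG_INF; int bi = 0, bk = 0;
  for (int i = 1; i <= n; ++i)
    for (int k = 1; k <= L; ++k)
      if (M(i, k) > best) { best = M(i, k); bi = i; bk = k; }
  IntegerVector map(n);          // residue -> match column (0 if unmatched)
  IntegerVector stateOfRes(n);   // 0 flank, 1 M, 2 I
  int aliStart = 0, aliEnd = 0, nIns = 0, nDel = 0;
  if (bi > 0) {
    aliEnd = bi;
    int i = bi, k = bk, st = 1;  // current state being read
    while (true) {
      if (st == 1) {
        map[i - 1] = k; stateOfRes[i - 1] = 1;
        int prev = tbM(i, k);
        aliStart = i;
        --i; --k;
        if (prev == 0) break;
        st = prev;
      } else if (st == 2) {
        stateOfRes[i - 1] = 2; ++nIns;
        int prev = tbI(i, k);
        --i;
        st = prev;
      } else {  // delete, consumes a column not a residue
        ++nDel;
        int prev = tbD(i, k);
        --k;
        st = prev;
      }
    }
  }
  return List::create(_["score"] = best, _["map"] = map,
                      _["state"] = stateOfRes,
                      _["ali_start"] = aliStart, _["ali_end"] = aliEnd,
                      _["n_insert"] = nIns, _["n_delete"] = nDel);
}

// Global profile-profile alignment with affine gaps (Gotoh). pa, pb are
// 20 x ncol residue-frequency profiles (gap mass excluded so columns may sum
// to < 1); sub is the 20 x 20 substitution matrix. Returns logical advance
// vectors describing which profile consumes each merged column.
// [[Rcpp::export(name = ".profile_align")]]
List profile_align(NumericMatrix pa, NumericMatrix pb, NumericMatrix sub,
                   double gapOpen, double gapExt) {
  const int m = pa.ncol(), n = pb.ncol();
  NumericMatrix S(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  // column-pair scores
  NumericMatrix cs(m, n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int a = 0; a < 20; ++a) {
        if (pa(a, i) == 0.0) continue;
        double t = 0.0;
        for (int b = 0; b < 20; ++b) t += pb(b, j) * sub(a, b);
        s += pa(a, i) * t;
      }
      cs(i, j) = s;
    }
  // tb*: predecessor layer (0 S, 1 X, 2 Y) recorded during the fill
  IntegerMatrix tbS(m + 1, n + 1), tbX(m + 1, n + 1), tbY(m + 1, n + 1);
  S(0, 0) = 0; X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= m; ++i) {
    S(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = -gapOpen - gapExt * (i - 1);
    tbX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    S(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = -gapOpen - gapExt * (j - 1);
    tbY(0, j) = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j) {
      double ds = S(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      if (ds >= dx && ds >= dy) { S(i, j) = ds + cs(i - 1, j - 1); tbS(i, j) = 0; }
      else if (dx >= dy)        { S(i, j) = dx + cs(i - 1, j - 1); tbS(i, j) = 1; }
      else                      { S(i, j) = dy + cs(i - 1, j - 1); tbS(i, j) = 2; }
      double xs = S(i - 1, j) - gapOpen, xx = X(i - 1, j) - gapExt, xy = Y(i - 1, j) - gapOpen;
      if (xs >= xx && xs >= xy) { X(i, j) = xs; tbX(i, j) = 0; }
      else if (xx >= xy)        { X(i, j) = xx; tbX(i, j) = 1; }
      else                      { X(i, j) = xy; tbX(i, j) = 2; }
      double ys = S(i, j - 1) - gapOpen, yx = X(i, j - 1) - gapOpen, yy = Y(i, j - 1) - gapExt;
      if (ys >= yy && ys >= yx) { Y(i, j) = ys; tbY(i, j) = 0; }
      else if (yy >= yx)        { Y(i, j) = yy; tbY(i, j) = 2; }
      else                      { Y(i, j) = yx; tbY(i, j) = 1; }
    }
  std::vector<int> advA, advB;
  int i = m, j = n, layer;
  if (S(m, n) >= X(m, n) && S(m, n) >= Y(m, n)) layer = 0;
  else if (X(m, n) >= Y(m, n)) layer = 1;
  else layer = 2;
  while (i > 0 || j > 0) {
    if (layer == 0) {
      advA.push_back(1); advB.push_back(1);
      layer = tbS(i, j); --i; --j;
    } else if (layer == 1) {
      advA.push_back(1); advB.push_back(0);
      layer = tbX(i, j); --i;
    } else {
      advA.push_back(0); advB.push_back(1);
      layer = tbY(i, j); --j;
    }
  }
  std::reverse(advA.begin(), advA.end());
  std::reverse(advB.begin(), advB.end());
  return List::create(_["advance_a"] = wrap(advA), _["advance_b"] = wrap(advB),
                      _["score"] = std::max(S(m, n), std::max(X(m, n), Y(m, n))));
}
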