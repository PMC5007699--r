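#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
// Convention: a gap of length L costs go + L * ge, matching the usual
// "gapOpening + gapExtension per residue" accounting so that results are
// directly comparable with other affine-gap implementations.
//
// States: 0 = M (residue/residue), 1 = X (residue of a vs gap),
//         2 = Y (residue of b vs gap), 3 = local start.

static const double NEG = -1e15;

// [[Rcpp::export]]
List align_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                      double go, double ge, bool local) {
  const int n = a.size(), m = b.size();
  const double open_cost = go + ge;
  const int nS = S.nrow();
  const double *Sp = REAL(S);

  // Pointer matrices for the traceback (one byte per state per cell);
  // score rows are rolled to keep memory traffic low.
  std::vector<unsigned char> pM((size_t)(n + 1) * (m + 1), 3),
      pX((size_t)(n + 1) * (m + 1), 3), pY((size_t)(n + 1) * (m + 1), 3);
#define IDX(i, j) ((size_t)(i) * (m + 1) + (j))

  // per-subject score profile: prof[x * m + j] = S(x, b[j])
  int amax = 0;
  for (int i = 0; i < n; ++i) if (a[i] > amax) amax = a[i];
  std::vector<double> prof((size_t)(amax + 1) * m);
  for (int x = 0; x <= amax; ++x) {
    for (int j = 0; j < m; ++j) prof[(size_t)x * m + j] = Sp[b[j] * nS + x];
  }

  std::vector<double> M0(m + 1, NEG), X0(m + 1, NEG), Y0(m + 1, NEG),
      M1(m + 1), X1(m + 1), Y1(m + 1);
  M0[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Y0[j] = -go - j * ge;
    pY[IDX(0, j)] = 2;
    if (local) M0[j] = 0.0;
  }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    const double *sr = &prof[(size_t)a[i - 1] * m];
    unsigned char *pMi = &pM[IDX(i, 0)], *pXi = &pX[IDX(i, 0)],
        *pYi = &pY[IDX(i, 0)];
    M1[0] = local ? 0.0 : NEG;
    X1[0] = -go - i * ge;
    pXi[0] = 1;
    Y1[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      // M
      double vm = M0[j - 1], vx = X0[j - 1], vy = Y0[j - 1];
      double mv = vm;
      unsigned char mp = 0;
      if (vx > mv) { mv = vx; mp = 1; }
      if (vy > mv) { mv = vy; mp = 2; }
      if (local && 0.0 > mv) { mv = 0.0; mp = 3; }
      const double mval = mv + sr[j - 1];
      M1[j] = mval;
      pMi[j] = mp;
      if (local && mval > best) { best = mval; bi = i; bj = j; }
      // X: consume a[i-1] against a gap
      vm = M0[j] - open_cost; vx = X0[j] - ge; vy = Y0[j] - open_cost;
      mv = vm; mp = 0;
      if (vx > mv) { mv = vx; mp = 1; }
      if (vy > mv) { mv = vy; mp = 2; }
      X1[j] = mv;
      pXi[j] = mp;
      // Y: consume b[j-1] against a gap
      vm = M1[j - 1] - open_cost; vx = X1[j - 1] - open_cost;
      vy = Y1[j - 1] - ge;
      mv = vm; mp = 0;
      if (vx > mv) { mv = vx; mp = 1; }
      if (vy > mv) { mv = vy; mp = 2; }
      Y1[j] = mv;
      pYi[j] = mp;
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }

  double score;
  int state;
  int i, j;
  if (local) {
    score = best;
    i = bi; j = bj; state = 0;
    if (best <= 0.0) {  // empty local alignment
      return List::create(_["score"] = 0.0,
                          _["pairs"] = IntegerMatrix(0, 2),
                          _["states"] = IntegerVector(0));
    }
  } else {
    double vm = M0[m], vx = X0[m], vy = Y0[m];
    score = vm; state = 0;
    if (vx > score) { score = vx; state = 1; }
    if (vy > score) { score = vy; state = 2; }
    i = n; j = m;
  }

  // Traceback: record one row per alignment column.
  std::vector<int> ca, cb, st;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char p = pM[IDX(i, j)];
      ca.push_back(i); cb.push_back(j); st.push_back(0);
      --i; --j;
      if (local && p == 3) break;
      state = p;
    } else if (state == 1) {
      unsigned char p = pX[IDX(i, j)];
      ca.push_back(i); cb.push_back(0); st.push_back(1);
      --i;
      state = p;
    } else {
      unsigned char p = pY[IDX(i, j)];
      ca.push_back(0); cb.push_back(j); st.push_back(2);
      --j;
      state = p;
    }
    if (local && i == 0 && j == 0) break;
  }
  const int L = ca.size();
  IntegerMatrix pairs(L, 2);
  IntegerVector states(L);
  for (int k = 0; k < L; ++k) {
    pairs(k, 0) = ca[L - 1 - k];
    pairs(k, 1) = cb[L - 1 - k];
    states[k] = st[L - 1 - k];
  }
  return List::create(_["score"] = score, _["pairs"] = pairs,
                      _["states"] = states);
#undef IDX
}

// All-vs-all p-distance from global affine alignments: for each pair,
// p = mismatched residue columns / residue-residue columns.
// [[Rcpp::export]]
NumericMatrix pairwise_pdist_cpp(List seqs, NumericMatrix S, double go,
                                 double ge) {
  const int n = seqs.size();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = seqs[i];
    for (int j = i + 1; j < n; ++j) {
      IntegerVector b = seqs[j];
      List al = align_affine_cpp(a, b, S, go, ge, false);
      IntegerMatrix pairs = al["pairs"];
      int shared = 0, mism = 0;
      for (int k = 0; k < pairs.nrow(); ++k) {
        if (pairs(k, 0) > 0 && pairs(k, 1) > 0) {
          ++shared;
          if (a[pairs(k, 0) - 1] != b[pairs(k, 1) - 1]) ++mism;
        }
      }
      double p = shared > 0 ? (double)mism / shared : 1.0;
      D(i, j) = p;
      D(j, i) = p;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}

// Global affine DP over a precomputed column-score matrix (profile-profile
// alignment for progressive MSA). Returns the path as moves:
// 0 = diagonal (column of A with column of B), 1 = A column vs gap,
// 2 = B column vs gap.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix CS, double go, double ge) {
  const int n = CS.nrow(), m = CS.ncol();
  const double open_cost = go + ge;
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> pM((n + 1) * (m + 1), 3), pX((n + 1) * (m + 1), 3),
      pY((n + 1) * (m + 1), 3);
#define IDX(i, j) ((i) * (m + 1) + (j))
  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) { X[IDX(i, 0)] = -go - i * ge; pX[IDX(i, 0)] = 1; }
  for (int j = 1; j <= m; ++j) { Y[IDX(0, j)] = -go - j * ge; pY[IDX(0, j)] = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double vm = M[IDX(i - 1, j - 1)], vx = X[IDX(i - 1, j - 1)],
             vy = Y[IDX(i - 1, j - 1)];
      double mv = vm; unsigned char mp = 0;
      if (vx > mv) { mv = vx; mp = 1; }
      if (vy > mv) { mv = vy; mp = 2; }
      M[IDX(i, j)] = mv + CS(i - 1, j - 1);
      pM[IDX(i, j)] = mp;
      vm = M[IDX(i - 1, j)] - open_cost; vx = X[IDX(i - 1, j)] - ge;
      vy = Y[IDX(i - 1, j)] - open_cost;
      mv = vm; mp = 0;
      if (vx > mv) { mv = vx; mp = 1; }
      if (vy > mv) { mv = vy; mp = 2; }
      X[IDX(i, j)] = mv; pX[IDX(i, j)] = mp;
      vm = M[IDX(i, j - 1)] - open_cost; vx = X[IDX(i, j - 1)] - open_cost;
      vy = Y[IDX(i, j - 1)] - ge;
      mv = vm; mp = 0;
      if (vx > mv) { mv = vx; mp = 1; }
      if (vy > mv) { mv = vy; mp = 2; }
      Y[IDX(i, j)] = mv; pY[IDX(i, j)] = mp;
    }
  }
  double vm = M[IDX(n, m)], vx = X[IDX(n, m)], vy = Y[IDX(n, m)];
  double score = vm; int state = 0;
  if (vx > score) { score = vx; state = 1; }
  if (vy > score) { score = vy; state = 2; }
  std::vector<int> mv;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      state = pM[IDX(i, j)]; mv.push_back(0); --i; --j;
    } else if (state == 1) {
      state = pX[IDX(i, j)]; mv.push_back(1); --i;
    } else {
      state = pY[IDX(i, j)]; mv.push_back(2); --j;
    }
  }
  std::reverse(mv.begin(), mv.end());
  return List::create(_["score"] = score, _["moves"] = wrap(mv));
#undef IDX
}
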