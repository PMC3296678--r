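#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Gotoh affine-gap local alignment. Gap of length L costs open + (L-1)*extend.
// Characters outside {A,C,G,T} (e.g. N) never match and never count as identities.

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string t,
                  double match = 5.0, double mismatch = -4.0,
                  double gap_open = 12.0, double gap_extend = 2.0) {
  const int n = q.size(), m = t.size();
  // matrices are (n+1) x (m+1), row-major
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> Ix((n + 1) * (m + 1), R_NegInf);
  std::vector<double> Iy((n + 1) * (m + 1), R_NegInf);
  // traceback: 0 stop, 1 diag-from-M, 2 diag-from-Ix, 3 diag-from-Iy,
  // for Ix: 1 open (from M), 2 extend; same for Iy
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int k = i * (m + 1) + j;
      const int ku = (i - 1) * (m + 1) + j;   // up
      const int kl = k - 1;                   // left
      const int kd = ku - 1;                  // diag
      // Ix: gap in target (consumes query char); 1 = open from M,
      // 2 = extend, 3 = open from the opposite gap state
      double xoM = M[ku] - gap_open, xoY = Iy[ku] - gap_open,
             xe = Ix[ku] - gap_extend;
      if (xoM >= xe && xoM >= xoY) { Ix[k] = xoM; tbX[k] = 1; }
      else if (xe >= xoY)          { Ix[k] = xe;  tbX[k] = 2; }
      else                         { Ix[k] = xoY; tbX[k] = 3; }
      // Iy: gap in query (consumes target char)
      double yoM = M[kl] - gap_open, yoX = Ix[kl] - gap_open,
             ye = Iy[kl] - gap_extend;
      if (yoM >= ye && yoM >= yoX) { Iy[k] = yoM; tbY[k] = 1; }
      else if (ye >= yoX)          { Iy[k] = ye;  tbY[k] = 2; }
      else                         { Iy[k] = yoX; tbY[k] = 3; }
      // M: diagonal
      const char tc = t[j - 1];
      double s = (qc == tc && is_acgt(qc)) ? match : mismatch;
      double dM = M[kd], dX = Ix[kd], dY = Iy[kd];
      double dbest = dM; unsigned char src = 1;
      if (dX > dbest) { dbest = dX; src = 2; }
      if (dY > dbest) { dbest = dY; src = 3; }
      double v = dbest + s;
      if (v <= 0.0) { M[k] = 0.0; tbM[k] = 0; }
      else { M[k] = v; tbM[k] = src; }
      // local alignments end in a match/mismatch state
      if (M[k] > best) { best = M[k]; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["t_start"] = NA_INTEGER,
                        _["t_end"] = NA_INTEGER, _["aligned_cols"] = 0L,
                        _["n_ident"] = 0L, _["q_aligned"] = 0L);
  }

  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 0; // 0=M, 1=Ix, 2=Iy
  int cols = 0, ident = 0, qaln = 0;
  int qe = bi, te = bj, qs = bi, ts = bj;
  while (i > 0 && j > 0) {
    const int k = i * (m + 1) + j;
    if (state == 0) {
      unsigned char src = tbM[k];
      if (src == 0 && M[k] == 0.0 && !(i == bi && j == bj)) break;
      // consume diagonal
      ++cols; ++qaln;
      if (q[i - 1] == t[j - 1] && is_acgt(q[i - 1])) ++ident;
      qs = i; ts = j;
      --i; --j;
      if (src == 0) break;       // alignment started here
      state = (src == 1) ? 0 : (src == 2 ? 1 : 2);
    } else if (state == 1) {
      unsigned char src = tbX[k];
      ++cols; ++qaln; qs = i;
      --i;
      state = (src == 1) ? 0 : (src == 2 ? 1 : 2);
    } else {
      unsigned char src = tbY[k];
      ++cols; ts = j;
      --j;
      state = (src == 1) ? 0 : (src == 2 ? 2 : 1);
    }
  }

  return List::create(_["score"] = best, _["q_start"] = qs, _["q_end"] = qe,
                      _["t_start"] = ts, _["t_end"] = te,
                      _["aligned_cols"] = cols, _["n_ident"] = ident,
                      _["q_aligned"] = qaln);
}

// score-only variant with O(m) memory, for shuffle nulls and prescreens
// [[Rcpp::export]]
double sw_score_cpp(std::string q, std::string t,
                    double match = 5.0, double mismatch = -4.0,
                    double gap_open = 12.0, double gap_extend = 2.0) {
  const int n = q.size(), m = t.size();
  std::vector<double> Mprev(m + 1, 0.0), Mcur(m + 1, 0.0);
  std::vector<double> Xprev(m + 1, R_NegInf), Xcur(m + 1, R_NegInf);
  std::vector<double> Yprev(m + 1, R_NegInf), Ycur(m + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    const bool qok = is_acgt(qc);
    Mcur[0] = 0.0; Xcur[0] = R_NegInf; Ycur[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      double x = std::max(std::max(Mprev[j], Yprev[j]) - gap_open,
                          Xprev[j] - gap_extend);
      double y = std::max(std::max(Mcur[j - 1], Xcur[j - 1]) - gap_open,
                          Ycur[j - 1] - gap_extend);
      double s = (qc == t[j - 1] && qok) ? match : mismatch;
      double d = std::max(std::max(Mprev[j - 1], Xprev[j - 1]), Yprev[j - 1]) + s;
      double v = d > 0.0 ? d : 0.0;
      Mcur[j] = v; Xcur[j] = x; Ycur[j] = y;
      if (v > best) best = v;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  return best;
}

// Global (Needleman-Wunsch) profile-profile alignment with affine gaps and a
// gap-separation surcharge near already-gapped columns. Profiles are
// 7 x L frequency matrices over the alphabet A,C,G,T,N,X,- (rows in that
// order, columns sum to 1). Returns the aligned column paths: integers
// indexing profile columns (1-based), 0 where a new gap is inserted.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix p1, NumericMatrix p2, NumericMatrix subst,
                       LogicalVector near_gap1, LogicalVector near_gap2,
                       double gap_open = 80.0, double gap_extend = 0.0,
                       double gap_sep = 10.0) {
  const int n = p1.ncol(), m = p2.ncol(), A = subst.nrow();
  // precompute column pair scores
  std::vector<double> colsc((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    double f1[7];
    for (int a = 0; a < A; ++a) f1[a] = p1(a, i);
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int a = 0; a < A; ++a) {
        if (f1[a] == 0.0) continue;
        double acc = 0.0;
        for (int b = 0; b < A; ++b) acc += p2(b, j) * subst(a, b);
        s += f1[a] * acc;
      }
      colsc[(size_t)i * m + j] = s;
    }
  }
  const double NEG = -1e30;
  std::vector<double> M((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> Ix((size_t)(n + 1) * (m + 1), NEG); // gap in p2 (consume p1 col)
  std::vector<double> Iy((size_t)(n + 1) * (m + 1), NEG); // gap in p1 (consume p2 col)
  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbX((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbY((size_t)(n + 1) * (m + 1), 0);
  M[0] = 0.0;
  // traceback codes for Ix/Iy: 1 = opened from M, 2 = extension,
  // 3 = opened from the opposite gap state
  for (int i = 1; i <= n; ++i) {
    size_t k = (size_t)i * (m + 1);
    double open = gap_open + (near_gap1[i - 1] ? gap_sep : 0.0);
    double xo = M[k - (m + 1)] - open, xe = Ix[k - (m + 1)] - gap_extend;
    if (xo >= xe) { Ix[k] = xo; tbX[k] = 1; } else { Ix[k] = xe; tbX[k] = 2; }
  }
  for (int j = 1; j <= m; ++j) {
    double open = gap_open + (near_gap2[j - 1] ? gap_sep : 0.0);
    double yo = M[j - 1] - open, ye = Iy[j - 1] - gap_extend;
    if (yo >= ye) { Iy[j] = yo; tbY[j] = 1; } else { Iy[j] = ye; tbY[j] = 2; }
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t k = (size_t)i * (m + 1) + j;
      const size_t ku = k - (m + 1), kl = k - 1, kd = ku - 1;
      double openx = gap_open + (near_gap1[i - 1] ? gap_sep : 0.0);
      double openy = gap_open + (near_gap2[j - 1] ? gap_sep : 0.0);
      double xoM = M[ku] - openx, xoY = Iy[ku] - openx,
             xe = Ix[ku] - gap_extend;
      if (xoM >= xe && xoM >= xoY) { Ix[k] = xoM; tbX[k] = 1; }
      else if (xe >= xoY)          { Ix[k] = xe;  tbX[k] = 2; }
      else                         { Ix[k] = xoY; tbX[k] = 3; }
      double yoM = M[kl] - openy, yoX = Ix[kl] - openy,
             ye = Iy[kl] - gap_extend;
      if (yoM >= ye && yoM >= yoX) { Iy[k] = yoM; tbY[k] = 1; }
      else if (ye >= yoX)          { Iy[k] = ye;  tbY[k] = 2; }
      else                         { Iy[k] = yoX; tbY[k] = 3; }
      double s = colsc[(size_t)(i - 1) * m + (j - 1)];
      double dM = M[kd], dX = Ix[kd], dY = Iy[kd];
      double dbest = dM; unsigned char src = 1;
      if (dX > dbest) { dbest = dX; src = 2; }
      if (dY > dbest) { dbest = dY; src = 3; }
      M[k] = dbest + s; tbM[k] = src;
    }
  }
  // traceback from best terminal state
  size_t kend = (size_t)n * (m + 1) + m;
  int state = 0;
  double endbest = M[kend];
  if (Ix[kend] > endbest) { endbest = Ix[kend]; state = 1; }
  if (Iy[kend] > endbest) { endbest = Iy[kend]; state = 2; }
  std::vector<int> a, b;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t k = (size_t)i * (m + 1) + j;
    if (state == 0 && i > 0 && j > 0) {
      unsigned char src = tbM[k];
      a.push_back(i); b.push_back(j);
      --i; --j;
      state = (src == 1) ? 0 : (src == 2 ? 1 : 2);
    } else if ((state == 1 && i > 0) || (state == 0 && j == 0) || (state == 2 && j == 0)) {
      unsigned char src = tbX[k];
      a.push_back(i); b.push_back(0);
      --i;
      state = (src == 1) ? 0 : (src == 2 ? 1 : 2);
      if (j == 0) state = 1;
    } else {
      unsigned char src = tbY[k];
      a.push_back(0); b.push_back(j);
      --j;
      state = (src == 1) ? 0 : (src == 2 ? 2 : 1);
      if (i == 0) state = 2;
    }
  }
  std::reverse(a.begin(), a.end());
  std::reverse(b.begin(), b.end());
  return List::create(_["path1"] = wrap(a), _["path2"] = wrap(b),
                      _["score"] = endbest);
}
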