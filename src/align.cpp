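// Affine-gap dynamic-programming alignment kernels.
//
// Gap model: a gap of length L costs gap_open + (L-1) * gap_extend, with both
// penalties non-positive (the first gapped position is charged gap_open).
// Two modes:
//   * local   — Smith-Waterman; the alignment starts and ends on an aligned
//               pair and the score is floored at zero (score 0 == "no hit").
//   * overlap — free end gaps on both sequences; the contiguous aligned core
//               may start and end anywhere (used for candidate-vs-reference
//               coding-sequence comparison).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Build a 256-entry char -> matrix index map from the substitution matrix's
// single-character row names. Unknown characters score as the worst entry.
static void build_charmap(const NumericMatrix& submat, int* cmap) {
  CharacterVector rn = rownames(submat);
  for (int i = 0; i < 256; ++i) cmap[i] = -1;
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() != 1) stop("substitution matrix row names must be single characters");
    cmap[(unsigned char)s[0]] = i;
  }
}

static inline double sub_score(const NumericMatrix& submat, const int* cmap,
                               double worst, char ca, char cb) {
  int ia = cmap[(unsigned char)ca], ib = cmap[(unsigned char)cb];
  if (ia < 0 || ib < 0) return worst;
  return submat(ia, ib);
}

// ptr codes: in M, 0 = diag from M, 1 = diag from Ix, 2 = diag from Iy,
// 3 = fresh start; in Ix/Iy, 0/1/2 = came from M/Ix/Iy.
struct DP {
  int n, m;
  std::vector<double> M, Ix, Iy;
  std::vector<unsigned char> pM, pIx, pIy;
  DP(int n_, int m_) : n(n_), m(m_),
    M((n_ + 1) * (m_ + 1), NEG_INF), Ix(M), Iy(M),
    pM((n_ + 1) * (m_ + 1), 0), pIx(pM), pIy(pM) {}
  inline int at(int i, int j) const { return i * (m + 1) + j; }
};

static List traceback(const DP& dp, const std::string& a, const std::string& b,
                      int bi, int bj, double best, bool local) {
  // walk back from (bi, bj) in state M until a fresh start
  std::string a_aln, b_aln;
  int i = bi, j = bj, state = 0; // 0 = M, 1 = Ix, 2 = Iy
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) break;
      unsigned char p = dp.pM[dp.at(i, j)];
      a_aln.push_back(a[i - 1]);
      b_aln.push_back(b[j - 1]);
      --i; --j;
      if (p == 3) break;            // fresh start: aligned pair consumed
      state = p;
    } else if (state == 1) {
      unsigned char p = dp.pIx[dp.at(i, j)];
      a_aln.push_back(a[i - 1]);
      b_aln.push_back('-');
      --i;
      state = p;
    } else {
      unsigned char p = dp.pIy[dp.at(i, j)];
      a_aln.push_back('-');
      b_aln.push_back(b[j - 1]);
      --j;
      state = p;
    }
    if (local && state == 0 && i == 0 && j == 0) break;
  }
  std::reverse(a_aln.begin(), a_aln.end());
  std::reverse(b_aln.begin(), b_aln.end());
  int n_ident = 0, n_cols = (int)a_aln.size();
  for (int k = 0; k < n_cols; ++k)
    if (a_aln[k] == b_aln[k] && a_aln[k] != '-') ++n_ident;
  return List::create(
    _["score"] = best,
    _["a_start"] = i + 1, _["a_end"] = bi,
    _["b_start"] = j + 1, _["b_end"] = bj,
    _["a_aln"] = a_aln, _["b_aln"] = b_aln,
    _["n_ident"] = n_ident, _["n_cols"] = n_cols);
}

// [[Rcpp::export(name = ".align_dp_cpp")]]
List align_dp_cpp(std::string a, std::string b, NumericMatrix submat,
                  double gap_open, double gap_extend, std::string mode) {
  bool local = (mode == "local");
  if (!local && mode != "overlap") stop("mode must be 'local' or 'overlap'");
  int n = (int)a.size(), m = (int)b.size();
  int cmap[256];
  build_charmap(submat, cmap);
  double worst = submat(0, 0);
  for (int i = 0; i < submat.nrow(); ++i)
    for (int j = 0; j < submat.ncol(); ++j)
      if (submat(i, j) < worst) worst = submat(i, j);

  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["a_aln"] = "", _["b_aln"] = "",
                        _["n_ident"] = 0, _["n_cols"] = 0);

  DP dp(n, m);
  // borders: overlap gets free prefixes through M; local starts are handled
  // by the fresh-start option in the M recursion.
  dp.M[dp.at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) dp.M[dp.at(i, 0)] = local ? NEG_INF : 0.0;
  for (int j = 1; j <= m; ++j) dp.M[dp.at(0, j)] = local ? NEG_INF : 0.0;

  double best = local ? 0.0 : NEG_INF;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // gap states
      double x_m = dp.M[dp.at(i - 1, j)] + gap_open;
      double x_x = dp.Ix[dp.at(i - 1, j)] + gap_extend;
      double x_y = dp.Iy[dp.at(i - 1, j)] + gap_open;
      double xv = x_m; unsigned char xp = 0;
      if (x_x > xv) { xv = x_x; xp = 1; }
      if (x_y > xv) { xv = x_y; xp = 2; }
      dp.Ix[dp.at(i, j)] = xv; dp.pIx[dp.at(i, j)] = xp;

      double y_m = dp.M[dp.at(i, j - 1)] + gap_open;
      double y_x = dp.Ix[dp.at(i, j - 1)] + gap_open;
      double y_y = dp.Iy[dp.at(i, j - 1)] + gap_extend;
      double yv = y_m; unsigned char yp = 0;
      if (y_x > yv) { yv = y_x; yp = 1; }
      if (y_y > yv) { yv = y_y; yp = 2; }
      dp.Iy[dp.at(i, j)] = yv; dp.pIy[dp.at(i, j)] = yp;

      double s = sub_score(submat, cmap, worst, a[i - 1], b[j - 1]);
      double d_m = dp.M[dp.at(i - 1, j - 1)];
      double d_x = dp.Ix[dp.at(i - 1, j - 1)];
      double d_y = dp.Iy[dp.at(i - 1, j - 1)];
      double dv = d_m; unsigned char dpp = 0;
      if (d_x > dv) { dv = d_x; dpp = 1; }
      if (d_y > dv) { dv = d_y; dpp = 2; }
      if (local && 0.0 > dv) { dv = 0.0; dpp = 3; }
      double mv = s + dv;
      dp.M[dp.at(i, j)] = mv; dp.pM[dp.at(i, j)] = dpp;

      bool candidate = local ? (mv > best) : (mv > best);
      if (candidate) { best = mv; bi = i; bj = j; }
    }
  }

  if (local && best <= 0.0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["a_aln"] = "", _["b_aln"] = "",
                        _["n_ident"] = 0, _["n_cols"] = 0);

  return traceback(dp, a, b, bi, bj, best, local);
}
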