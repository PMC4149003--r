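// Affine-gap pairwise alignment kernel (Gotoh three-state DP) plus
// brute-force path-enumeration reference scorers used as test oracles.
//
// Gap cost convention: a run of L consecutive gaps in one sequence costs
// gap_open + L * gap_extend.  Adjacent runs in different sequences are
// separate runs (each pays the opening cost).
//
// Tie-break: diagonal > up (gap in b) > left (gap in a); within a state,
// predecessor preference M > X > Y.  Strict '>' everywhere so the first
// preferred option wins, giving a deterministic traceback.

#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

static const double NEG = -1e30;

struct CharIndex {
  int map[256];
  CharIndex(const std::string& chars) {
    for (int i = 0; i < 256; ++i) map[i] = -1;
    for (size_t i = 0; i < chars.size(); ++i)
      map[static_cast<unsigned char>(chars[i])] = static_cast<int>(i);
  }
  int at(char c) const {
    int v = map[static_cast<unsigned char>(c)];
    if (v < 0) stop("character '%s' not in scoring alphabet",
                    std::string(1, c).c_str());
    return v;
  }
};

// states: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a,
// consumes b), 3 = local-alignment start marker.

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b, NumericMatrix sub,
                    std::string chars, double gap_open, double gap_extend,
                    int type) {
  // type: 0 = global, 1 = local, 2 = semiglobal (free terminal gaps)
  const int n = static_cast<int>(a.size());
  const int m = static_cast<int>(b.size());
  if (n == 0 || m == 0) stop("empty sequence");
  CharIndex ix(chars);
  std::vector<int> ia(n), ib(m);
  for (int i = 0; i < n; ++i) ia[i] = ix.at(a[i]);
  for (int j = 0; j < m; ++j) ib[j] = ix.at(b[j]);

  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  std::vector<signed char> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);

  M[0] = 0.0;
  const double go = gap_open + gap_extend;
  for (int i = 1; i <= n; ++i) {
    if (type == 0) {  // global: leading gap run in b
      X[i * W] = -(gap_open + gap_extend * i);
      tX[i * W] = (i == 1) ? 0 : 1;
    } else if (type == 2) {  // semiglobal: free leading gaps
      X[i * W] = 0.0;
      tX[i * W] = (i == 1) ? 0 : 1;
    } else {  // local: empty alignment may start anywhere
      M[i * W] = 0.0;
      tM[i * W] = 3;
    }
  }
  for (int j = 1; j <= m; ++j) {
    if (type == 0) {
      Y[j] = -(gap_open + gap_extend * j);
      tY[j] = (j == 1) ? 0 : 2;
    } else if (type == 2) {
      Y[j] = 0.0;
      tY[j] = (j == 1) ? 0 : 2;
    } else {
      M[j] = 0.0;
      tM[j] = 3;
    }
  }
  if (type == 1) tM[0] = 3;

  double bestLoc = 0.0;
  int bestLi = 0, bestLj = 0;

  for (int i = 1; i <= n; ++i) {
    const int r = i * W, p = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const double s = sub(ia[i - 1], ib[j - 1]);
      // M state
      double best = M[p + j - 1];
      signed char bs = 0;
      if (X[p + j - 1] > best) { best = X[p + j - 1]; bs = 1; }
      if (Y[p + j - 1] > best) { best = Y[p + j - 1]; bs = 2; }
      double mv = (best <= NEG / 2) ? NEG : s + best;
      if (type == 1 && mv < 0.0) { mv = 0.0; bs = 3; }
      M[r + j] = mv;
      tM[r + j] = bs;
      // X state (consume a[i-1], gap in b)
      double xo = (M[p + j] <= NEG / 2) ? NEG : M[p + j] - go;
      signed char xs = 0;
      double xe = (X[p + j] <= NEG / 2) ? NEG : X[p + j] - gap_extend;
      if (xe > xo) { xo = xe; xs = 1; }
      double xy = (Y[p + j] <= NEG / 2) ? NEG : Y[p + j] - go;
      if (xy > xo) { xo = xy; xs = 2; }
      X[r + j] = xo;
      tX[r + j] = xs;
      // Y state (consume b[j-1], gap in a)
      double yo = (M[r + j - 1] <= NEG / 2) ? NEG : M[r + j - 1] - go;
      signed char ys = 0;
      double yx = (X[r + j - 1] <= NEG / 2) ? NEG : X[r + j - 1] - go;
      if (yx > yo) { yo = yx; ys = 1; }
      double ye = (Y[r + j - 1] <= NEG / 2) ? NEG : Y[r + j - 1] - gap_extend;
      if (ye > yo) { yo = ye; ys = 2; }
      Y[r + j] = yo;
      tY[r + j] = ys;

      if (type == 1 && M[r + j] > bestLoc) {
        bestLoc = M[r + j];
        bestLi = i;
        bestLj = j;
      }
    }
  }

  double score;
  int ei, ej, state;
  if (type == 0) {
    ei = n; ej = m;
    score = M[n * W + m]; state = 0;
    if (X[n * W + m] > score) { score = X[n * W + m]; state = 1; }
    if (Y[n * W + m] > score) { score = Y[n * W + m]; state = 2; }
  } else if (type == 2) {
    // best over last column then last row, free trailing gaps
    score = NEG; ei = n; ej = m; state = 0;
    for (int i = 0; i <= n; ++i) {
      double v = M[i * W + m]; int st = 0;
      if (X[i * W + m] > v) { v = X[i * W + m]; st = 1; }
      if (Y[i * W + m] > v) { v = Y[i * W + m]; st = 2; }
      if (v > score) { score = v; ei = i; ej = m; state = st; }
    }
    for (int j = 0; j <= m; ++j) {
      double v = M[n * W + j]; int st = 0;
      if (X[n * W + j] > v) { v = X[n * W + j]; st = 1; }
      if (Y[n * W + j] > v) { v = Y[n * W + j]; st = 2; }
      if (v > score) { score = v; ei = n; ej = j; state = st; }
    }
  } else {
    score = bestLoc; ei = bestLi; ej = bestLj; state = 0;
    if (score <= 0.0) {
      return List::create(_["aligned_a"] = "", _["aligned_b"] = "",
                          _["score"] = 0.0, _["start_a"] = 0, _["end_a"] = 0,
                          _["start_b"] = 0, _["end_b"] = 0);
    }
  }

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = ei, j = ej;
  if (type == 2) {  // pad free trailing gaps
    for (int k = n; k > ei; --k) { ra.push_back(a[k - 1]); rb.push_back('-'); }
    for (int k = m; k > ej; --k) { ra.push_back('-'); rb.push_back(b[k - 1]); }
  }
  bool done = false;
  while (!done) {
    if (i == 0 && j == 0) break;
    // a floored/boundary M cell marks the start of a local alignment
    if (type == 1 && state == 0 && tM[i * W + j] == 3) break;
    if (type != 1 && i == 0) {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
      continue;
    }
    if (type != 1 && j == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      continue;
    }
    signed char ns;
    switch (state) {
      case 0:
        ns = tM[i * W + j];
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        --i; --j;
        if (ns == 3) { done = true; break; }
        state = ns;
        break;
      case 1:
        ns = tX[i * W + j];
        ra.push_back(a[i - 1]);
        rb.push_back('-');
        --i;
        state = ns;
        break;
      default:
        ns = tY[i * W + j];
        ra.push_back('-');
        rb.push_back(b[j - 1]);
        --j;
        state = ns;
        break;
    }
    if (type == 1 && done) break;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  if (type == 1) {
    return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                        _["score"] = score, _["start_a"] = i + 1,
                        _["end_a"] = ei, _["start_b"] = j + 1,
                        _["end_b"] = ej);
  }
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}

// ---- brute-force enumeration oracles (no DP, used only for validation) ----

namespace {
struct Brute {
  const std::string& a;
  const std::string& b;
  const CharIndex& ix;
  const NumericMatrix& sub;
  double open, ext;
  double best;
  size_t a0, a1, b0, b1;  // substring window [a0,a1), [b0,b1)
  Brute(const std::string& a_, const std::string& b_, const CharIndex& ix_,
        const NumericMatrix& sub_, double open_, double ext_)
      : a(a_), b(b_), ix(ix_), sub(sub_), open(open_), ext(ext_), best(NEG),
        a0(0), a1(a_.size()), b0(0), b1(b_.size()) {}
  void rec(size_t i, size_t j, int last, double acc) {
    if (i == a1 && j == b1) {
      if (acc > best) best = acc;
      return;
    }
    if (i < a1 && j < b1)
      rec(i + 1, j + 1, 0, acc + sub(ix.at(a[i]), ix.at(b[j])));
    if (i < a1) rec(i + 1, j, 1, acc - (last == 1 ? ext : open + ext));
    if (j < b1) rec(i, j + 1, 2, acc - (last == 2 ? ext : open + ext));
  }
};
}  // namespace

// [[Rcpp::export]]
double brute_global_score_cpp(std::string a, std::string b, NumericMatrix sub,
                              std::string chars, double gap_open,
                              double gap_extend) {
  CharIndex ix(chars);
  Brute br(a, b, ix, sub, gap_open, gap_extend);
  br.rec(0, 0, 0, 0.0);
  return br.best;
}

// [[Rcpp::export]]
double brute_local_score_cpp(std::string a, std::string b, NumericMatrix sub,
                             std::string chars, double gap_open,
                             double gap_extend) {
  CharIndex ix(chars);
  double best = 0.0;  // empty alignment allowed
  for (size_t i0 = 0; i0 < a.size(); ++i0)
    for (size_t i1 = i0 + 1; i1 <= a.size(); ++i1)
      for (size_t j0 = 0; j0 < b.size(); ++j0)
        for (size_t j1 = j0 + 1; j1 <= b.size(); ++j1) {
          Brute br(a, b, ix, sub, gap_open, gap_extend);
          br.a0 = i0; br.a1 = i1; br.b0 = j0; br.b1 = j1;
          br.best = NEG;
          br.rec(i0, j0, 0, 0.0);
          if (br.best > best) best = br.best;
        }
  return best;
}
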