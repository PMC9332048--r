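// Dynamic-programming core: alignment of a nucleotide sequence against a
// 16-row dinucleotide position-weight matrix (PWM), with linear indel
// penalties, plus the matrix-vs-matrix Needleman-Wunsch used for class
// clustering and the shuffle machinery for Monte-Carlo nulls.
//
// Conventions shared with the R layer:
//   * bases are coded 0=A, 1=T, 2=C, 3=G; -1 marks N/unknown;
//   * the PWM has L1-1 informative columns; sequence position t (1-based)
//     aligned to column l scores pwm(code[t-2] + 4*code[t-1], l-1), i.e. the
//     dinucleotide formed with the *actual* previous sequence base, so the
//     match score is a pure function of the sequence (gaps do not re-pair
//     bases across an indel);
//   * position t = 1 has no previous base and scores 0 in any column, as do
//     positions where either base of the pair is N.
//
// Hot loops use a row-major copy of the PWM (one contiguous row per
// dinucleotide) and raw pointers; per-window DPs are two-row.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>

using namespace Rcpp;

static std::vector<int> as_codes(const IntegerVector& s) {
  std::vector<int> v(s.size());
  for (R_xlen_t i = 0; i < s.size(); ++i)
    v[i] = (s[i] == NA_INTEGER) ? -1 : s[i];
  return v;
}

// row-major copy: P[srow * C + (l-1)]; row 16 is all zeros (used for
// positions whose dinucleotide is undefined)
static std::vector<double> flat_pwm(const NumericMatrix& pwm) {
  const int C = pwm.ncol();
  std::vector<double> P(17 * (size_t)C, 0.0);
  for (int s = 0; s < 16; ++s)
    for (int l = 0; l < C; ++l) P[(size_t)s * C + l] = pwm(s, l);
  return P;
}

// dinucleotide row (0..15) per sequence position (0-based t-1), 16 = undefined
static std::vector<int> dinuc_rows(const std::vector<int>& c) {
  std::vector<int> r(c.size(), 16);
  for (size_t t = 1; t < c.size(); ++t)
    if (c[t - 1] >= 0 && c[t] >= 0) r[t] = c[t - 1] + 4 * c[t];
  return r;
}

static inline double max3(double a, double b, double c) {
  double m = a > b ? a : b;
  return m > c ? m : c;
}

static std::string rle_cigar(const std::string& ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

// score-only global DP; rows/P as prepared above, positions [t0, t0+n)
static double global_score(const int* rows, int n, const double* P, int C,
                           double d, double* prev, double* cur) {
  for (int l = 0; l <= C; ++l) prev[l] = -d * l;
  for (int t = 1; t <= n; ++t) {
    const double* W = P + (size_t)rows[t - 1] * C - 1;  // W[l] = w(t, l)
    cur[0] = -d * t;
    double left = cur[0];
    for (int l = 1; l <= C; ++l) {
      double v = max3(prev[l - 1] + W[l], prev[l] - d, left - d);
      cur[l] = v;
      left = v;
    }
    std::swap(prev, cur);
  }
  return prev[C];
}

// Full-matrix global alignment (Needleman-Wunsch) of sequence vs PWM.
// Returns the terminal score F(n, C) and, optionally, the traceback as a
// CIGAR-like string (M = seq position vs column, I = seq position unmatched,
// D = column unmatched).
// [[Rcpp::export]]
List cpp_global_align(IntegerVector codes, NumericMatrix pwm, double d,
                      bool trace = false) {
  std::vector<int> c = as_codes(codes);
  const int n = (int) c.size();
  const int C = pwm.ncol();
  if (n < 2) stop("sequence must have length >= 2");
  if (pwm.nrow() != 16) stop("PWM must have 16 rows");
  std::vector<double> P = flat_pwm(pwm);
  std::vector<int> rows = dinuc_rows(c);

  if (!trace) {
    std::vector<double> prev(C + 1), cur(C + 1);
    double sc = global_score(rows.data(), n, P.data(), C, d,
                             prev.data(), cur.data());
    return List::create(_["score"] = sc);
  }

  std::vector<double> F((size_t)(n + 1) * (C + 1));
  auto at = [&](int t, int l) -> double& { return F[(size_t)t * (C + 1) + l]; };
  for (int l = 0; l <= C; ++l) at(0, l) = -d * l;
  for (int t = 1; t <= n; ++t) {
    const double* W = P.data() + (size_t)rows[t - 1] * C - 1;
    at(t, 0) = -d * t;
    for (int l = 1; l <= C; ++l)
      at(t, l) = max3(at(t - 1, l - 1) + W[l], at(t - 1, l) - d,
                      at(t, l - 1) - d);
  }
  std::string ops;
  int t = n, l = C;
  const double eps = 1e-9;
  while (t > 0 || l > 0) {
    if (t > 0 && l > 0 &&
        std::abs(at(t, l) - (at(t - 1, l - 1) +
                             P[(size_t)rows[t - 1] * C + l - 1])) < eps) {
      ops += 'M'; --t; --l;
    } else if (t > 0 && std::abs(at(t, l) - (at(t - 1, l) - d)) < eps) {
      ops += 'I'; --t;
    } else {
      ops += 'D'; --l;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = at(n, C), _["cigar"] = rle_cigar(ops),
                      _["i0"] = 1, _["imax"] = n, _["l0"] = 1, _["lmax"] = C);
}

// Smith-Waterman-style local alignment of sequence vs PWM (floor at 0).
// Reports the best score, its sequence/column intervals (1-based, within
// the supplied sequence) and the traceback.
// [[Rcpp::export]]
List cpp_local_align(IntegerVector codes, NumericMatrix pwm, double d,
                     bool trace = true) {
  std::vector<int> c = as_codes(codes);
  const int n = (int) c.size();
  const int C = pwm.ncol();
  if (n < 2) stop("sequence must have length >= 2");
  if (pwm.nrow() != 16) stop("PWM must have 16 rows");
  std::vector<double> P = flat_pwm(pwm);
  std::vector<int> rows = dinuc_rows(c);

  std::vector<double> F((size_t)(n + 1) * (C + 1), 0.0);
  auto at = [&](int t, int l) -> double& { return F[(size_t)t * (C + 1) + l]; };
  double best = 0.0; int bt = 0, bl = 0;
  for (int t = 1; t <= n; ++t) {
    const double* W = P.data() + (size_t)rows[t - 1] * C - 1;
    for (int l = 1; l <= C; ++l) {
      double m = max3(at(t - 1, l - 1) + W[l], at(t - 1, l) - d,
                      at(t, l - 1) - d);
      if (m < 0) m = 0;
      at(t, l) = m;
      if (m > best) { best = m; bt = t; bl = l; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["i0"] = NA_INTEGER,
                        _["imax"] = NA_INTEGER, _["l0"] = NA_INTEGER,
                        _["lmax"] = NA_INTEGER, _["cigar"] = "");
  std::string ops;
  int t = bt, l = bl;
  const double eps = 1e-9;
  while (t > 0 && l > 0 && at(t, l) > eps) {
    if (std::abs(at(t, l) - (at(t - 1, l - 1) +
                             P[(size_t)rows[t - 1] * C + l - 1])) < eps) {
      ops += 'M'; --t; --l;
    } else if (std::abs(at(t, l) - (at(t - 1, l) - d)) < eps) {
      ops += 'I'; --t;
    } else if (std::abs(at(t, l) - (at(t, l - 1) - d)) < eps) {
      ops += 'D'; --l;
    } else break;
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["i0"] = t + 1, _["imax"] = bt,
                      _["l0"] = l + 1, _["lmax"] = bl,
                      _["cigar"] = trace ? rle_cigar(ops) : std::string(""));
}

// Sliding-window local-alignment scan of a chromosome against one PWM.
// Windows of length `wlen` are taken every `stride` positions; windows
// whose N fraction exceeds `max_n_frac` are skipped. For each scored
// window the best local score and its chromosome/column intervals are
// returned (columns: wstart, emax, i0, imax, l0, lmax; 1-based).
// Two-row DP; the start cell of the best path is propagated per cell as a
// packed int (seq_start * (C+1) + col_start).
// [[Rcpp::export]]
NumericMatrix cpp_scan_windows(IntegerVector codes, NumericMatrix pwm,
                               double d, int wlen, int stride,
                               double max_n_frac) {
  std::vector<int> c = as_codes(codes);
  const int n = (int) c.size();
  const int C = pwm.ncol();
  if (pwm.nrow() != 16) stop("PWM must have 16 rows");
  if (wlen < 2 || stride < 1) stop("invalid window/stride");
  if (n < wlen) return NumericMatrix(0, 6);
  std::vector<double> P = flat_pwm(pwm);
  std::vector<int> rows = dinuc_rows(c);

  std::vector<int> npre(n + 1, 0);
  for (int i = 0; i < n; ++i) npre[i + 1] = npre[i] + (c[i] < 0 ? 1 : 0);

  std::vector<double> res;
  std::vector<double> buf0(C + 1), buf1(C + 1);
  std::vector<int> sbuf0(C + 1), sbuf1(C + 1);
  const int packC = C + 1;

  for (int k = 0; k + wlen <= n; k += stride) {
    if ((double)(npre[k + wlen] - npre[k]) / wlen > max_n_frac) continue;
    double* prev = buf0.data(); double* cur = buf1.data();
    int* pstart = sbuf0.data(); int* cstart = sbuf1.data();
    std::memset(prev, 0, sizeof(double) * (C + 1));
    std::memset(pstart, 0, sizeof(int) * (C + 1));
    double best = 0.0; int bt = 0, bl = 0, bstart = 0;
    for (int t = 1; t <= wlen; ++t) {
      // window position t uses the dinucleotide at chromosome position
      // k + t; the first window position has no previous base *within the
      // window*, score it 0 (row 16) to keep windows self-contained
      int row = (t >= 2) ? rows[k + t - 1] : 16;
      const double* W = P.data() + (size_t)row * C - 1;
      cur[0] = 0.0; cstart[0] = 0;
      double left = 0.0; int leftstart = 0;
      for (int l = 1; l <= C; ++l) {
        double diag = prev[l - 1] + W[l];
        double up = prev[l] - d;
        double dleft = left - d;
        double m; int st;
        if (diag >= up && diag >= dleft) {
          m = diag;
          st = (prev[l - 1] <= 0.0) ? (t * packC + l) : pstart[l - 1];
        } else if (up >= dleft) {
          m = up; st = pstart[l];
        } else {
          m = dleft; st = leftstart;
        }
        if (m <= 0.0) { m = 0.0; st = 0; }
        cur[l] = m; cstart[l] = st;
        left = m; leftstart = st;
        if (m > best) { best = m; bt = t; bl = l; bstart = st; }
      }
      std::swap(prev, cur);
      std::swap(pstart, cstart);
    }
    res.push_back(k + 1);
    res.push_back(best);
    if (best > 0.0) {
      res.push_back(k + bstart / packC);       // i0 (chromosome, 1-based)
      res.push_back(k + bt);                   // imax
      res.push_back(bstart % packC);           // l0
      res.push_back(bl);                       // lmax
    } else {
      res.push_back(NA_REAL); res.push_back(NA_REAL);
      res.push_back(NA_REAL); res.push_back(NA_REAL);
    }
  }
  int m = (int)(res.size() / 6);
  NumericMatrix out(m, 6);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < 6; ++j) out(i, j) = res[(size_t)i * 6 + j];
  colnames(out) = CharacterVector::create("wstart", "emax", "i0", "imax",
                                          "l0", "lmax");
  return out;
}

// Global-alignment scores of `n` independent mononucleotide shuffles of
// the sequence against the PWM. Uses R's RNG so results are reproducible
// under set.seed().
// [[Rcpp::export]]
NumericVector cpp_shuffled_global_scores(IntegerVector codes,
                                         NumericMatrix pwm, double d, int n) {
  std::vector<int> c = as_codes(codes);
  const int len = (int) c.size();
  const int C = pwm.ncol();
  if (pwm.nrow() != 16) stop("PWM must have 16 rows");
  std::vector<double> P = flat_pwm(pwm);
  NumericVector out(n);
  std::vector<double> prev(C + 1), cur(C + 1);
  RNGScope scope;
  for (int r = 0; r < n; ++r) {
    for (int i = len - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(c[i], c[j]);
    }
    std::vector<int> rows = dinuc_rows(c);
    out[r] = global_score(rows.data(), len, P.data(), C, d,
                          prev.data(), cur.data());
  }
  return out;
}

// Needleman-Wunsch over a precomputed column-match weight matrix W
// (rows = columns of the first frequency matrix, cols = columns of the
// second), with boundary F(i,0) = -d*i, F(0,j) = -d*j. Returns the
// terminal score and the number of indel steps on one optimal traceback.
// [[Rcpp::export]]
List cpp_nw_matrix(NumericMatrix W, double d) {
  const int n = W.nrow(), m = W.ncol();
  std::vector<double> F((size_t)(n + 1) * (m + 1));
  auto at = [&](int i, int j) -> double& { return F[(size_t)i * (m + 1) + j]; };
  for (int i = 0; i <= n; ++i) at(i, 0) = -d * i;
  for (int j = 0; j <= m; ++j) at(0, j) = -d * j;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      at(i, j) = max3(at(i - 1, j - 1) + W(i - 1, j - 1),
                      at(i - 1, j) - d, at(i, j - 1) - d);
  int i = n, j = m, nindel = 0;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(at(i, j) - (at(i - 1, j - 1) + W(i - 1, j - 1))) < eps) {
      --i; --j;
    } else if (i > 0 && std::abs(at(i, j) - (at(i - 1, j) - d)) < eps) {
      --i; ++nindel;
    } else {
      --j; ++nindel;
    }
  }
  return List::create(_["score"] = at(n, m), _["n_indel"] = nindel);
}
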