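// Local alignment (Smith-Waterman with Gotoh affine gaps) with full
// traceback, returning score, match count, number of aligned (non-gap)
// columns and the coordinates of the aligned region on both sequences.
// A gap of length L costs gap_open + L * gap_ext (BLAST convention).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// 128x128 lookup built from an R scoring matrix with single-letter
// dimnames; letters absent from the matrix score the matrix minimum.
static void build_table(const NumericMatrix& m, std::vector<double>& tab) {
  double minv = R_PosInf;
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j)
      if (m(i, j) < minv) minv = m(i, j);
  tab.assign(128 * 128, minv);
  List dn = m.attr("dimnames");
  CharacterVector rn = dn[0], cn = dn[1];
  for (int i = 0; i < m.nrow(); ++i) {
    char a = Rcpp::as<std::string>(rn[i])[0];
    for (int j = 0; j < m.ncol(); ++j) {
      char b = Rcpp::as<std::string>(cn[j])[0];
      tab[(unsigned char)a * 128 + (unsigned char)b] = m(i, j);
    }
  }
}

// out: score, matches, align_cols, q_start, q_end, s_start, s_end (1-based)
static void sw_core(const std::string& q, const std::string& s,
                    const std::vector<double>& tab,
                    double go, double ge, double* out) {
  const int n = (int)q.size(), m = (int)s.size();
  for (int z = 0; z < 7; ++z) out[z] = 0.0;
  if (n == 0 || m == 0) return;

  const int W = m + 1;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, NEG_INF),
      F((n + 1) * W, NEG_INF);
  // PH: 0 stop, 1 diag, 2 from E (gap in query), 3 from F (gap in subject)
  // PE/PF: 1 = opened from H, 0 = extended
  std::vector<unsigned char> PH((n + 1) * W, 0), PE((n + 1) * W, 0),
      PF((n + 1) * W, 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const unsigned char qc = (unsigned char)q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int id = i * W + j;
      double e_open = H[id - 1] - go - ge;
      double e_ext  = E[id - 1] - ge;
      if (e_open >= e_ext) { E[id] = e_open; PE[id] = 1; }
      else                 { E[id] = e_ext;  PE[id] = 0; }
      double f_open = H[id - W] - go - ge;
      double f_ext  = F[id - W] - ge;
      if (f_open >= f_ext) { F[id] = f_open; PF[id] = 1; }
      else                 { F[id] = f_ext;  PF[id] = 0; }
      double diag = H[id - W - 1] + tab[qc * 128 + (unsigned char)s[j - 1]];
      double h = 0.0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (E[id] > h) { h = E[id]; p = 2; }
      if (F[id] > h) { h = F[id]; p = 3; }
      H[id] = h; PH[id] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) return;

  int i = bi, j = bj, matches = 0, cols = 0;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (true) {
    const int id = i * W + j;
    if (state == 0) {
      unsigned char p = PH[id];
      if (p == 0) break;
      if (p == 1) {
        ++cols;
        if (q[i - 1] == s[j - 1]) ++matches;
        --i; --j;
      } else if (p == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      unsigned char p = PE[id];
      --j;
      if (p == 1) state = 0;
    } else {
      unsigned char p = PF[id];
      --i;
      if (p == 1) state = 0;
    }
  }
  out[0] = best;
  out[1] = (double)matches;
  out[2] = (double)cols;
  out[3] = (double)(i + 1);
  out[4] = (double)bi;
  out[5] = (double)(j + 1);
  out[6] = (double)bj;
}

// [[Rcpp::export]]
NumericVector sw_align_cpp(std::string query, std::string subject,
                           NumericMatrix smat, double gap_open,
                           double gap_ext) {
  std::vector<double> tab;
  build_table(smat, tab);
  NumericVector out(7);
  sw_core(query, subject, tab, gap_open, gap_ext, REAL(out));
  out.names() = CharacterVector::create("score", "matches", "align_cols",
                                        "q_start", "q_end", "s_start",
                                        "s_end");
  return out;
}

// Score-only Smith-Waterman (rolling rows, no traceback): used for bulk
// screening passes; the full-traceback kernel then runs only on the
// winning candidate.
static double sw_score_only(const std::string& q, const std::string& s,
                            const std::vector<double>& tab,
                            double go, double ge) {
  const int n = (int)q.size(), m = (int)s.size();
  if (n == 0 || m == 0) return 0.0;
  // H holds the previous row left of j and the current row at/left of
  // j-1 (updated in place); Fcol carries the vertical gap state per
  // column; e carries the horizontal gap state within the row.
  std::vector<double> H(m + 1, 0.0), Fcol(m + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    const unsigned char qc = (unsigned char)q[i - 1];
    double diag_prev = 0.0;  // H[i-1][j-1], starts at H[i-1][0] = 0
    double e = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      e = std::max(H[j - 1] - go - ge, e - ge);
      Fcol[j] = std::max(H[j] - go - ge, Fcol[j] - ge);
      double d = diag_prev + tab[qc * 128 + (unsigned char)s[j - 1]];
      diag_prev = H[j];
      double h = 0.0;
      if (d > h) h = d;
      if (e > h) h = e;
      if (Fcol[j] > h) h = Fcol[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector sw_score_batch_cpp(CharacterVector queries, std::string subject,
                                 NumericMatrix smat, double gap_open,
                                 double gap_ext) {
  std::vector<double> tab;
  build_table(smat, tab);
  NumericVector out(queries.size());
  for (int i = 0; i < queries.size(); ++i) {
    std::string q = Rcpp::as<std::string>(queries[i]);
    out[i] = sw_score_only(q, subject, tab, gap_open, gap_ext);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix sw_batch_cpp(CharacterVector queries, std::string subject,
                           NumericMatrix smat, double gap_open,
                           double gap_ext) {
  std::vector<double> tab;
  build_table(smat, tab);
  const int n = queries.size();
  NumericMatrix out(n, 7);
  double row[7];
  for (int i = 0; i < n; ++i) {
    std::string q = Rcpp::as<std::string>(queries[i]);
    sw_core(q, subject, tab, gap_open, gap_ext, row);
    for (int z = 0; z < 7; ++z) out(i, z) = row[z];
  }
  colnames(out) = CharacterVector::create("score", "matches", "align_cols",
                                          "q_start", "q_end", "s_start",
                                          "s_end");
  return out;
}
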