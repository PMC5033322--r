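#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// Nucleotide code: A,C,G,T -> 0..3; anything else (N, ambiguity) -> 4.
// Code 4 never matches, not even itself: ambiguous positions count as
// mismatches everywhere, which keeps identities conservative and exact.
static inline int nt_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// Semi-global alignment: the query (a fragment) is aligned end-to-end,
// the subject contributes a free-floating window (leading/trailing subject
// positions cost nothing). Linear gap penalty. Returns the best-scoring
// placement with match/column counts from the traceback.
//
// With match=+1, mismatch=-1, gap=-2, a substitution is always cheaper than
// an indel pair, so on ungapped (collinear) inputs the optimal path is the
// true diagonal and identity equals the per-site match fraction exactly.
// [[Rcpp::export(name = ".align_semiglobal_cpp")]]
List align_semiglobal_cpp(std::string query, std::string subject,
                          double match = 1.0, double mismatch = -1.0,
                          double gap = -2.0) {
  const int m = (int) query.size();
  const int n = (int) subject.size();
  if (m == 0 || n == 0) stop("empty sequence in alignment");

  std::vector<int> q(m), s(n);
  for (int i = 0; i < m; ++i) q[i] = nt_code(query[i]);
  for (int j = 0; j < n; ++j) s[j] = nt_code(subject[j]);

  // H is (m+1) x (n+1); traceback bytes: 0 diag, 1 up (gap in subject),
  // 2 left (gap in query).
  std::vector<double> prev(n + 1), cur(n + 1);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);

  for (int j = 0; j <= n; ++j) prev[j] = 0.0;           // free start in subject
  for (int i = 1; i <= m; ++i) {
    cur[0] = gap * i;
    tb[(size_t) i * (n + 1)] = 1;
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const double sc = (qi == s[j - 1] && qi < 4) ? match : mismatch;
      double best = prev[j - 1] + sc;
      uint8_t dir = 0;
      const double up = prev[j] + gap;
      if (up > best) { best = up; dir = 1; }
      const double left = cur[j - 1] + gap;
      if (left > best) { best = left; dir = 2; }
      cur[j] = best;
      tb[(size_t) i * (n + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }

  // free end in subject: best cell in the last row
  int jbest = 0;
  double best_score = -std::numeric_limits<double>::infinity();
  for (int j = 0; j <= n; ++j) {
    if (prev[j] > best_score) { best_score = prev[j]; jbest = j; }
  }

  int i = m, j = jbest;
  long matches = 0, columns = 0;
  int send = jbest, sstart = jbest + 1;
  while (i > 0) {
    const uint8_t dir = tb[(size_t) i * (n + 1) + j];
    if (dir == 0) {
      ++columns;
      if (q[i - 1] == s[j - 1] && q[i - 1] < 4) ++matches;
      --i; --j;
    } else if (dir == 1) {
      ++columns; --i;
    } else {
      ++columns; --j;
    }
  }
  sstart = j + 1;

  return List::create(
    _["score"] = best_score,
    _["matches"] = (double) matches,
    _["columns"] = (double) columns,
    _["query_length"] = (double) m,
    _["sstart"] = sstart,
    _["send"] = send);
}

// Smith-Waterman local alignment with affine gaps and an arbitrary
// substitution matrix (e.g. BLOSUM62). Used for protein similarity search.
// gap_open/gap_ext are positive penalties; opening a gap of length L costs
// gap_open + L * gap_ext (BLAST convention with defaults 11/1).
struct SWResult {
  double score;
  long identities, columns;
  int qstart, qend, sstart, send;
};

static SWResult sw_core(const std::vector<int> &a, const std::vector<int> &b,
                        const std::vector<double> &mat, int nalpha,
                        double gap_open, double gap_ext) {
  const int m = (int) a.size(), n = (int) b.size();
  const double NEG = -1e30;
  // states: 0 = M (diag), 1 = X (gap in b / up), 2 = Y (gap in a / left)
  std::vector<double> Mprev(n + 1, 0.0), Mcur(n + 1, 0.0);
  std::vector<double> Xprev(n + 1, NEG), Xcur(n + 1, NEG);
  std::vector<double> Yprev(n + 1, NEG), Ycur(n + 1, NEG);
  // traceback: 2 bits per state packed in one byte per cell:
  // tbM: 0 stop, 1 fromM, 2 fromX, 3 fromY ; tbX: 1 fromM, 2 fromX ;
  // tbY: 1 fromM, 3 fromY
  std::vector<uint8_t> tbM((size_t)(m + 1) * (n + 1), 0),
      tbX((size_t)(m + 1) * (n + 1), 0), tbY((size_t)(m + 1) * (n + 1), 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Mcur[0] = 0.0; Xcur[0] = NEG; Ycur[0] = NEG;
    const int ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const size_t idx = (size_t) i * (n + 1) + j;
      const double sub = mat[(size_t) ai * nalpha + b[j - 1]];
      // M
      double mdiag = Mprev[j - 1], xdiag = Xprev[j - 1], ydiag = Yprev[j - 1];
      double mbest = 0.0; uint8_t mdir = 0;
      if (mdiag + sub > mbest) { mbest = mdiag + sub; mdir = 1; }
      if (xdiag + sub > mbest) { mbest = xdiag + sub; mdir = 2; }
      if (ydiag + sub > mbest) { mbest = ydiag + sub; mdir = 3; }
      Mcur[j] = mbest; tbM[idx] = mdir;
      // X: gap in b (consume a), from above
      double xo = Mprev[j] - gap_open - gap_ext;
      double xe = Xprev[j] - gap_ext;
      if (xo >= xe) { Xcur[j] = xo; tbX[idx] = 1; }
      else          { Xcur[j] = xe; tbX[idx] = 2; }
      // Y: gap in a (consume b), from left
      double yo = Mcur[j - 1] - gap_open - gap_ext;
      double ye = Ycur[j - 1] - gap_ext;
      if (yo >= ye) { Ycur[j] = yo; tbY[idx] = 1; }
      else          { Ycur[j] = ye; tbY[idx] = 3; }
      if (Mcur[j] > best) { best = Mcur[j]; bi = i; bj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  SWResult r; r.score = best; r.identities = 0; r.columns = 0;
  r.qstart = r.qend = r.sstart = r.send = 0;
  if (best <= 0.0) return r;

  int i = bi, j = bj; uint8_t state = 0; // start in M at the max cell
  r.qend = bi; r.send = bj;
  while (i > 0 && j > 0) {
    const size_t idx = (size_t) i * (n + 1) + j;
    if (state == 0) {
      const uint8_t dir = tbM[idx];
      if (dir == 0) break;
      ++r.columns;
      if (a[i - 1] == b[j - 1]) ++r.identities;
      --i; --j;
      state = (dir == 1) ? 0 : (dir == 2 ? 1 : 2);
    } else if (state == 1) {
      ++r.columns;
      const uint8_t dir = tbX[idx];
      --i;
      state = (dir == 1) ? 0 : 1;
    } else {
      ++r.columns;
      const uint8_t dir = tbY[idx];
      --j;
      state = (dir == 1) ? 0 : 2;
    }
  }
  r.qstart = i + 1; r.sstart = j + 1;
  return r;
}

// [[Rcpp::export(name = ".sw_all_pairs_cpp")]]
DataFrame sw_all_pairs_cpp(CharacterVector queries, CharacterVector db,
                           NumericMatrix submat, double gap_open = 11.0,
                           double gap_ext = 1.0) {
  List dn = submat.attr("dimnames");
  if (dn.size() != 2) stop("substitution matrix needs dimnames");
  CharacterVector alpha = dn[0];
  const int nalpha = alpha.size();
  if (submat.nrow() != nalpha || submat.ncol() != nalpha)
    stop("substitution matrix must be square");
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < nalpha; ++i) {
    std::string ch = as<std::string>(alpha[i]);
    if (ch.size() != 1) stop("alphabet entries must be single characters");
    lut[(unsigned char) ch[0]] = i;
    lut[(unsigned char) tolower(ch[0])] = i;
  }
  std::vector<double> mat(submat.begin(), submat.end());
  // NumericMatrix is column-major; sw_core indexes mat[a*nalpha + b], which
  // for a symmetric scoring matrix is equivalent, but transpose defensively.
  std::vector<double> matT((size_t) nalpha * nalpha);
  for (int i = 0; i < nalpha; ++i)
    for (int j = 0; j < nalpha; ++j)
      matT[(size_t) i * nalpha + j] = submat(i, j);

  const int nq = queries.size(), nd = db.size();
  std::vector<std::vector<int> > qenc(nq), denc(nd);
  for (int i = 0; i < nq; ++i) {
    std::string s = as<std::string>(queries[i]);
    qenc[i].resize(s.size());
    for (size_t k = 0; k < s.size(); ++k) {
      int c = lut[(unsigned char) s[k]];
      if (c < 0) stop("residue '%s' not in substitution alphabet",
                      std::string(1, s[k]).c_str());
      qenc[i][k] = c;
    }
  }
  for (int i = 0; i < nd; ++i) {
    std::string s = as<std::string>(db[i]);
    denc[i].resize(s.size());
    for (size_t k = 0; k < s.size(); ++k) {
      int c = lut[(unsigned char) s[k]];
      if (c < 0) stop("residue '%s' not in substitution alphabet",
                      std::string(1, s[k]).c_str());
      denc[i][k] = c;
    }
  }

  const size_t total = (size_t) nq * nd;
  IntegerVector qi(total), si(total);
  NumericVector score(total), ident(total), cols(total);
  IntegerVector qlen(total), slen(total);
  size_t k = 0;
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nd; ++j, ++k) {
      SWResult r = sw_core(qenc[i], denc[j], matT, nalpha, gap_open, gap_ext);
      qi[k] = i + 1; si[k] = j + 1;
      score[k] = r.score; ident[k] = (double) r.identities;
      cols[k] = (double) r.columns;
      qlen[k] = (int) qenc[i].size(); slen[k] = (int) denc[j].size();
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
    _["query"] = qi, _["subject"] = si, _["score"] = score,
    _["identities"] = ident, _["columns"] = cols,
    _["query_length"] = qlen, _["subject_length"] = slen);
}

// Per-site mismatch count between equal-length sequences (ambiguity codes
// count as mismatches). Used by distance oracles and the simulator.
// [[Rcpp::export(name = ".count_site_matches_cpp")]]
List count_site_matches_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  long match = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    const int ca = nt_code(a[i]), cb = nt_code(b[i]);
    if (ca == cb && ca < 4) ++match;
  }
  return List::create(_["matches"] = (double) match,
                      _["length"] = (double) a.size());
}
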