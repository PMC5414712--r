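#include <Rcpp.h>
using namespace Rcpp;

// Bidirectional, defect-tolerant extension of an anchored complementary base
// pair into a maximal inverted-repeat alignment.
//
// Coordinates are 1-based. A column of the alignment pairs a left-arm
// position p (read 5'->3') with a right-arm position q (read 3'->5'), and is
// a match when seq[p] is the Watson-Crick complement of seq[q]; N never
// matches. A single mismatch or indel column is accepted only when the
// immediately following column is a match, which enforces the stopping rule
// that two consecutive defects terminate extension. Terminal columns are
// therefore always matches.

static inline char comp_base(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';   // N and anything unexpected never match
  }
}

static inline bool base_pairs(const std::string& s, int p, int q) {
  char a = s[p - 1], b = s[q - 1];
  if (a == 'N' || b == 'N') return false;
  return a == comp_base(b);
}

// Length of the exact complementary run walking outward from (p, q).
static int run_outward(const std::string& s, int p, int q, int n) {
  int r = 0;
  while (p >= 1 && q <= n && base_pairs(s, p, q)) { ++r; --p; ++q; }
  return r;
}

// Length of the exact complementary run walking inward from (p, q); stops
// before the cursors cross so the spacer stays non-negative.
static int run_inward(const std::string& s, int p, int q) {
  int r = 0;
  while (p < q && base_pairs(s, p, q)) { ++r; ++p; --q; }
  return r;
}

// Outward extension: left cursor p decreases, right cursor q increases.
// cols collects column kinds in extension order (M match, X mismatch,
// L gap in left arm, R gap in right arm).
static void extend_outward(const std::string& s, int n, int& p, int& q,
                           std::string& cols, int& ndef) {
  for (;;) {
    int np = p - 1, nq = q + 1;
    if (np < 1 || nq > n) break;
    if (base_pairs(s, np, nq)) { cols.push_back('M'); p = np; q = nq; continue; }
    // repairs: each is allowed only if the column after it is a match
    bool sub_ok = (np - 1 >= 1 && nq + 1 <= n && base_pairs(s, np - 1, nq + 1));
    if (sub_ok) { cols.push_back('X'); ++ndef; p = np; q = nq; continue; }
    bool gl_ok = (nq + 1 <= n && base_pairs(s, np, nq + 1));  // extra base on right arm
    bool gr_ok = (np - 1 >= 1 && base_pairs(s, np - 1, nq));  // extra base on left arm
    if (gl_ok && gr_ok) {
      // prefer the gap followed by the longer exact run; tie -> gap_right
      int rl = run_outward(s, np, nq + 1, n);
      int rr = run_outward(s, np - 1, nq, n);
      if (rl > rr) gr_ok = false; else gl_ok = false;
    }
    if (gl_ok) { cols.push_back('L'); ++ndef; q = nq; continue; }
    if (gr_ok) { cols.push_back('R'); ++ndef; p = np; continue; }
    break;  // no repair is followed by a match: two consecutive defects
  }
}

// Inward extension: p increases, q decreases; never lets the arms cross.
static void extend_inward(const std::string& s, int& p, int& q,
                          std::string& cols, int& ndef) {
  for (;;) {
    int np = p + 1, nq = q - 1;
    if (np >= nq) break;  // at most one unpaired base left between the arms
    if (base_pairs(s, np, nq)) { cols.push_back('M'); p = np; q = nq; continue; }
    bool sub_ok = (np + 1 < nq - 1 && base_pairs(s, np + 1, nq - 1));
    if (sub_ok) { cols.push_back('X'); ++ndef; p = np; q = nq; continue; }
    bool gl_ok = (np < nq - 1 && base_pairs(s, np, nq - 1));
    bool gr_ok = (np + 1 < nq && base_pairs(s, np + 1, nq));
    if (gl_ok && gr_ok) {
      int rl = run_inward(s, np, nq - 1);
      int rr = run_inward(s, np + 1, nq);
      if (rl > rr) gr_ok = false; else gl_ok = false;
    }
    if (gl_ok) { cols.push_back('L'); ++ndef; q = nq; continue; }
    if (gr_ok) { cols.push_back('R'); ++ndef; p = np; continue; }
    break;
  }
}

// Extend each anchored match column (anchor_left[i], anchor_right[i]) into
// its maximal alignment. Returns one row per anchor with the arm bounds,
// defect count and the column string ordered 5'->3' along the left arm.
// [[Rcpp::export]]
DataFrame extend_anchors_cpp(std::string seq,
                             IntegerVector anchor_left,
                             IntegerVector anchor_right) {
  int n = (int) seq.size();
  R_xlen_t m = anchor_left.size();
  if (anchor_right.size() != m)
    stop("anchor vectors must have equal length");

  IntegerVector ls(m), le(m), rs(m), re(m), nd(m);
  CharacterVector al(m);

  for (R_xlen_t i = 0; i < m; ++i) {
    int a = anchor_left[i], b = anchor_right[i];
    if (a < 1 || b > n || a >= b)
      stop("anchor out of range at index %d", (int)(i + 1));
    if (!base_pairs(seq, a, b))
      stop("anchor positions %d and %d are not complementary", a, b);

    int po = a, qo = b;             // outward cursors
    std::string out_cols;
    int ndef = 0;
    extend_outward(seq, n, po, qo, out_cols, ndef);

    int pi = a, qi = b;             // inward cursors
    std::string in_cols;
    extend_inward(seq, pi, qi, in_cols, ndef);

    // 5'->3' along the left arm: outward columns reversed, anchor, inward
    std::string cols(out_cols.rbegin(), out_cols.rend());
    cols.push_back('M');
    cols += in_cols;

    ls[i] = po; le[i] = pi; rs[i] = qi; re[i] = qo;
    nd[i] = ndef;
    al[i] = cols;
  }

  return DataFrame::create(
    _["left_start"] = ls, _["left_end"] = le,
    _["right_start"] = rs, _["right_end"] = re,
    _["n_defects"] = nd, _["alignment"] = al,
    _["stringsAsFactors"] = false);
}
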