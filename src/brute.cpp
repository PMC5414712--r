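#include <Rcpp.h>
#include <map>
#include <array>
using namespace Rcpp;

// Exhaustive inverted-repeat finder used as a correctness oracle on small
// sequences. Independent of the scanner's window machinery and k-mer
// hashing: every pair of disjoint positions (a, b) whose k bases form
// reverse-complementary words (checked base by base, b > a + k - 1) is
// grown into its maximal defect-tolerant alignment; results are filtered
// by the acceptance thresholds and deduplicated on coordinates. Quadratic
// in the sequence length, so callers guard the input size.
//
// Defect model (shared with the scanner by specification, implemented
// separately here): a mismatch or single-base gap column is permitted only
// when the next column pairs; otherwise extension in that direction stops.

namespace oracle {

static int cindex(char b) {
  // A<->T, C<->G via a small lookup; anything else (incl. N) is unpairable
  switch (b) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static bool wc(const std::string& s, int p, int q) {
  int a = cindex(s[p - 1]), b = cindex(s[q - 1]);
  return a >= 0 && b >= 0 && (a + b == 3);
}

// Walk one direction from an already-matched column. dir = -1 walks outward
// (p down, q up); dir = +1 walks inward (p up, q down, arms must not cross).
// Appends column codes to cols and updates the cursors in place.
static void walk(const std::string& s, int n, int dir,
                 int& p, int& q, std::string& cols, int& ndef) {
  for (;;) {
    int np = p + dir, nq = q - dir;
    bool in_range = (dir < 0) ? (np >= 1 && nq <= n) : (np < nq);
    if (!in_range) break;

    if (wc(s, np, nq)) { cols.push_back('M'); p = np; q = nq; continue; }

    // lookahead targets for the three single-defect repairs
    int sp = np + dir, sq = nq - dir;                 // after substitution
    bool sub_ok = ((dir < 0) ? (sp >= 1 && sq <= n) : (sp < sq)) && wc(s, sp, sq);
    bool gl_ok  = ((dir < 0) ? (sq <= n) : (np < sq)) && wc(s, np, sq);  // gap in left arm
    bool gr_ok  = ((dir < 0) ? (sp >= 1) : (sp < nq)) && wc(s, sp, nq);  // gap in right arm

    if (sub_ok) { cols.push_back('X'); ++ndef; p = np; q = nq; continue; }
    if (gl_ok && gr_ok) {
      // longer subsequent exact run wins; tie prefers the right-arm gap
      int rl = 0, pl = np, ql = sq;
      while (((dir < 0) ? (pl >= 1 && ql <= n) : (pl < ql)) && wc(s, pl, ql)) {
        ++rl; pl += dir; ql -= dir;
      }
      int rr = 0, pr = sp, qr = nq;
      while (((dir < 0) ? (pr >= 1 && qr <= n) : (pr < qr)) && wc(s, pr, qr)) {
        ++rr; pr += dir; qr -= dir;
      }
      if (rl > rr) gr_ok = false; else gl_ok = false;
    }
    if (gl_ok) { cols.push_back('L'); ++ndef; q = nq; continue; }
    if (gr_ok) { cols.push_back('R'); ++ndef; p = np; continue; }
    break;
  }
}

struct Hit {
  int ndef;
  double rate, gc;
  std::string cols;
};

static double arm_gc(const std::string& s, int a1, int a2, int b1, int b2) {
  long gccount = 0, acgt = 0;
  for (int p = a1; p <= a2; ++p) {
    int c = cindex(s[p - 1]);
    if (c >= 0) { ++acgt; if (c == 1 || c == 2) ++gccount; }
  }
  for (int p = b1; p <= b2; ++p) {
    int c = cindex(s[p - 1]);
    if (c >= 0) { ++acgt; if (c == 1 || c == 2) ++gccount; }
  }
  return acgt > 0 ? (double) gccount / (double) acgt : NA_REAL;
}

}  // namespace oracle

// [[Rcpp::export]]
DataFrame brute_force_cpp(std::string seq, int seed_size, int min_arm,
                          double max_mismatch_rate, double min_gc) {
  using namespace oracle;
  int n = (int) seq.size();
  int k = seed_size;

  std::map<std::array<int, 4>, Hit> found;

  for (int a = 1; a + k - 1 <= n; ++a) {
    for (int b = a + k; b + k - 1 <= n; ++b) {
      // seed test: columns (a + t, b + k - 1 - t) must all pair
      bool seeded = true;
      for (int t = 0; t < k; ++t) {
        if (!wc(seq, a + t, b + k - 1 - t)) { seeded = false; break; }
      }
      if (!seeded) continue;
      int i = a, j = b + k - 1;  // anchor on the seed's outermost column

      int po = i, qo = j;
      std::string down;
      int ndef = 0;
      walk(seq, n, -1, po, qo, down, ndef);

      int pi = i, qi = j;
      std::string up;
      walk(seq, n, +1, pi, qi, up, ndef);

      int la = pi - po + 1, ra = qo - qi + 1;
      int stem = la < ra ? la : ra;
      if (stem < min_arm) continue;
      double rate = (double) ndef / (double) stem;
      if (!(rate < max_mismatch_rate)) continue;
      double gc = arm_gc(seq, po, pi, qi, qo);
      if (!(gc > min_gc)) continue;

      std::string cols(down.rbegin(), down.rend());
      cols.push_back('M');
      cols += up;

      std::array<int, 4> key = {po, pi, qi, qo};
      Hit h{ndef, rate, gc, cols};
      auto it = found.find(key);
      if (it == found.end() ||
          h.ndef < it->second.ndef ||
          (h.ndef == it->second.ndef && h.cols < it->second.cols)) {
        found[key] = h;
      }
    }
  }

  R_xlen_t m = (R_xlen_t) found.size();
  IntegerVector ls(m), le(m), rs(m), re(m), nd(m);
  NumericVector rate(m), gc(m);
  CharacterVector cols(m);
  R_xlen_t out_i = 0;
  for (auto& kv : found) {
    ls[out_i] = kv.first[0]; le[out_i] = kv.first[1];
    rs[out_i] = kv.first[2]; re[out_i] = kv.first[3];
    nd[out_i] = kv.second.ndef;
    rate[out_i] = kv.second.rate;
    gc[out_i] = kv.second.gc;
    cols[out_i] = kv.second.cols;
    ++out_i;
  }
  return DataFrame::create(
    _["left_start"] = ls, _["left_end"] = le,
    _["right_start"] = rs, _["right_end"] = re,
    _["n_defects"] = nd, _["mismatch_rate"] = rate, _["gc"] = gc,
    _["alignment"] = cols, _["stringsAsFactors"] = false);
}
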