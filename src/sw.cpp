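#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
using namespace Rcpp;

// Exhaustive linear-gap Smith-Waterman with traceback. Scores are the
// read-mapping criteria: match/mismatch/gap supplied by the caller
// (defaults +1/-1/-2 at the R level). Identity is counted over alignment
// columns including gap columns, matching the package-wide convention.

struct SWRes {
  int score, nmatch, ncols;
  int a_start, a_end, b_start, b_end; // 0-based half-open on the inputs
};

static SWRes sw_nt(const std::string& a, const std::string& b,
                   int match, int mismatch, int gap,
                   std::vector<unsigned char>& tb) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  tb.assign((size_t)(n + 1) * (m + 1), 0); // 0 stop, 1 diag, 2 up, 3 left
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int v = prev[j - 1] + ((ai == b[j - 1]) ? match : mismatch);
      unsigned char t = 1;
      const int up = prev[j] + gap;
      if (up > v) { v = up; t = 2; }
      const int lf = cur[j - 1] + gap;
      if (lf > v) { v = lf; t = 3; }
      if (v <= 0) { v = 0; t = 0; }
      cur[j] = v;
      tb[(size_t)i * (m + 1) + j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  SWRes r; r.score = best; r.nmatch = 0; r.ncols = 0;
  r.a_end = bi; r.b_end = bj;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (t == 0) break;
    if (t == 1) { if (a[i - 1] == b[j - 1]) ++r.nmatch; ++r.ncols; --i; --j; }
    else if (t == 2) { ++r.ncols; --i; }
    else { ++r.ncols; --j; }
  }
  r.a_start = i; r.b_start = j;
  return r;
}

// [[Rcpp::export(name = ".sw_nt_pair_cpp")]]
IntegerVector sw_nt_pair_cpp(std::string a, std::string b,
                             int match, int mismatch, int gap) {
  std::vector<unsigned char> tb;
  SWRes r = sw_nt(a, b, match, mismatch, gap, tb);
  return IntegerVector::create(
    _["score"] = r.score, _["nmatch"] = r.nmatch, _["ncols"] = r.ncols,
    _["a_start"] = r.a_start, _["a_end"] = r.a_end,
    _["b_start"] = r.b_start, _["b_end"] = r.b_end);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// k-mer position index for one reference (k <= 12): hash table from
// k-mer code to (a few of) its reference end positions
struct KmerIndex {
  int k;
  std::vector<bool> present;
  std::unordered_map<int, std::vector<int> > pos; // code -> end positions
  void build(const std::string& s, int kk) {
    k = kk;
    const size_t sz = (size_t)1 << (2 * k);
    present.assign(sz, false);
    pos.clear();
    const int n = (int)s.size();
    int code = 0, run = 0;
    const int mask = (int)(sz - 1);
    for (int i = 0; i < n; ++i) {
      const int b = base_code(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | b) & mask;
      if (++run >= k) {
        present[code] = true;
        std::vector<int>& v = pos[code];
        if (v.size() < 8) v.push_back(i); // cap per-kmer positions
      }
    }
  }
};

// most-voted alignment diagonal (ref_pos - read_pos) shared by read and
// reference k-mers; returns false when no k-mer is shared
static bool anchor_diagonal(const std::string& read, const KmerIndex& idx,
                            int& diag_out) {
  const int n = (int)read.size();
  const int mask = (int)(((size_t)1 << (2 * idx.k)) - 1);
  std::unordered_map<int, int> votes;
  int code = 0, run = 0;
  bool any = false;
  for (int i = 0; i < n; ++i) {
    const int b = base_code(read[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    if (++run >= idx.k && idx.present[code]) {
      std::unordered_map<int, std::vector<int> >::const_iterator it =
        idx.pos.find(code);
      if (it != idx.pos.end()) {
        for (size_t t = 0; t < it->second.size(); ++t) {
          ++votes[it->second[t] - i];
          any = true;
        }
      }
    }
  }
  if (!any) return false;
  int best_d = 0, best_v = -1;
  for (std::unordered_map<int, int>::iterator it = votes.begin();
       it != votes.end(); ++it)
    if (it->second > best_v || (it->second == best_v && it->first < best_d)) {
      best_v = it->second; best_d = it->first;
    }
  diag_out = best_d;
  return true;
}

// Banded Smith-Waterman restricted to diagonals within +/- band of the
// anchor diagonal. Exact for alignments staying inside the band; with a
// substitution-dominated error model the optimal alignment sits on the
// anchor diagonal itself.
static SWRes sw_nt_banded(const std::string& a, const std::string& b,
                          int match, int mismatch, int gap,
                          int d0, int band,
                          std::vector<unsigned char>& tb) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = 2 * band + 1;
  const int NEG = -1000000000;
  std::vector<int> prev(W, NEG), cur(W, NEG);
  tb.assign((size_t)(n + 1) * W, 0);
  int best = 0, bi = 0, boff = 0;
  // row i covers ref columns j in [i + d0 - band, i + d0 + band]
  for (int off = 0; off < W; ++off) {
    int j0 = 0 + d0 - band + off; // virtual row 0
    prev[off] = (j0 >= 0 && j0 <= m) ? 0 : NEG;
  }
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    unsigned char* tbrow = &tb[(size_t)i * W];
    const int lo = i + d0 - band;
    for (int off = 0; off < W; ++off) {
      const int j = lo + off;
      if (j < 1 || j > m) { cur[off] = NEG; continue; }
      // diag neighbor (i-1, j-1) has the same offset in the prev row
      int dv = prev[off];
      if (dv == NEG && j == 1) dv = 0;        // column 0 boundary
      int v = (dv == NEG ? NEG : dv + ((ai == b[j - 1]) ? match : mismatch));
      unsigned char t = 1;
      if (off + 1 < W && prev[off + 1] != NEG) {      // up (i-1, j)
        const int up = prev[off + 1] + gap;
        if (up > v) { v = up; t = 2; }
      }
      if (off - 1 >= 0 && cur[off - 1] != NEG) {      // left (i, j-1)
        const int lf = cur[off - 1] + gap;
        if (lf > v) { v = lf; t = 3; }
      }
      if (v <= 0) { v = 0; t = 0; }
      cur[off] = v; tbrow[off] = t;
      if (v > best) { best = v; bi = i; boff = off; }
    }
    std::swap(prev, cur);
  }
  SWRes r; r.score = best; r.nmatch = 0; r.ncols = 0;
  int i = bi, off = boff;
  r.a_end = bi; r.b_end = bi + d0 - band + boff;
  while (i > 0) {
    unsigned char t = tb[(size_t)i * W + off];
    if (t == 0) break;
    const int j = i + d0 - band + off;
    if (t == 1) { if (a[i - 1] == b[j - 1]) ++r.nmatch; ++r.ncols; --i; }
    else if (t == 2) { ++r.ncols; --i; ++off; }
    else { ++r.ncols; --off; }
    if (off < 0 || off >= W) break;
  }
  r.a_start = i; r.b_start = i + d0 - band + off;
  return r;
}

// Best-reference assignment for a batch of reads. With k > 0 each
// reference sharing a k-mer with the read is aligned by banded
// Smith-Waterman around the most-voted shared diagonal (band +/- 16
// diagonals); k = 0 disables the prefilter and runs exhaustive SW
// against every reference. The best-scoring hit passing min_identity
// (percent, over alignment columns) and min_cols is kept; score ties
// resolve to the lowest reference index. ref = -1 marks unassigned.
// [[Rcpp::export(name = ".sw_nt_best_cpp")]]
List sw_nt_best_cpp(CharacterVector reads, CharacterVector refs,
                    int match, int mismatch, int gap,
                    int k, double min_identity, int min_cols) {
  const int nr = reads.size(), nf = refs.size();
  const int band = 16;
  std::vector<std::string> rs(nf);
  std::vector<KmerIndex> idx(k > 0 ? nf : 0);
  for (int f = 0; f < nf; ++f) {
    rs[f] = as<std::string>(refs[f]);
    if (k > 0) idx[f].build(rs[f], k);
  }
  IntegerVector best_ref(nr, -1), best_score(nr, NA_INTEGER),
                best_cols(nr, NA_INTEGER);
  NumericVector best_ident(nr, NA_REAL);
  std::vector<unsigned char> tb;
  for (int i = 0; i < nr; ++i) {
    const std::string rd = as<std::string>(reads[i]);
    int bscore = -1, bref = -1, bcols = 0, bmatch = 0;
    for (int f = 0; f < nf; ++f) {
      SWRes r;
      if (k > 0) {
        int d0;
        if (!anchor_diagonal(rd, idx[f], d0)) continue;
        r = sw_nt_banded(rd, rs[f], match, mismatch, gap, d0, band, tb);
      } else {
        r = sw_nt(rd, rs[f], match, mismatch, gap, tb);
      }
      if (r.ncols < min_cols) continue;
      const double ident = 100.0 * r.nmatch / r.ncols;
      if (ident < min_identity) continue;
      if (r.score > bscore) {
        bscore = r.score; bref = f; bcols = r.ncols; bmatch = r.nmatch;
      }
    }
    if (bref >= 0) {
      best_ref[i] = bref + 1;
      best_score[i] = bscore;
      best_cols[i] = bcols;
      best_ident[i] = 100.0 * bmatch / bcols;
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["ref"] = best_ref, _["score"] = best_score,
                      _["identity"] = best_ident, _["aln_len"] = best_cols);
}

// Sickle-style sliding-window quality trim. Window = max(1, floor(frac *
// length)); the 5' end advances while the window mean quality is below q,
// the 3' end retreats symmetrically. Reads shorter than min_len after
// trimming are flagged dropped (keep = FALSE).
// [[Rcpp::export(name = ".trim_reads_cpp")]]
List trim_reads_cpp(CharacterVector seqs, CharacterVector quals,
                    int q, int min_len, double frac) {
  const int n = seqs.size();
  CharacterVector out_seq(n), out_qual(n);
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string qu = as<std::string>(quals[i]);
    const int len = (int)s.size();
    if ((int)qu.size() != len)
      stop("sequence/quality length mismatch in read %d", i + 1);
    const int w = std::max(1, (int)(frac * len));
    std::vector<int> ph(len);
    for (int j = 0; j < len; ++j) ph[j] = (int)qu[j] - 33;
    int lo = 0, hi = len; // half-open kept window
    while (hi - lo >= w) {
      long sum = 0;
      for (int j = lo; j < lo + w; ++j) sum += ph[j];
      if ((double)sum / w >= q) break;
      ++lo;
    }
    while (hi - lo >= w) {
      long sum = 0;
      for (int j = hi - w; j < hi; ++j) sum += ph[j];
      if ((double)sum / w >= q) break;
      --hi;
    }
    // strip residual sub-threshold bases at the ends so trimming is
    // stable under re-application (window size varies with length)
    while (lo < hi && ph[lo] < q) ++lo;
    while (hi > lo && ph[hi - 1] < q) --hi;
    if (hi - lo < w) { lo = 0; hi = 0; } // nothing of acceptable quality
    keep[i] = (hi - lo) >= min_len;
    out_seq[i] = s.substr(lo, hi - lo);
    out_qual[i] = qu.substr(lo, hi - lo);
  }
  return List::create(_["seq"] = out_seq, _["qual"] = out_qual,
                      _["keep"] = keep);
}
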