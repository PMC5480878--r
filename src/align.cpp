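#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Ends-free ungapped alignment of each read against one subject.
// Scores every diagonal with at least `min_overlap` columns (match +2,
// mismatch -2, read 'N' contributes 0) and keeps the best-scoring diagonal
// per read; ties keep the first (smallest offset) diagonal.
// [[Rcpp::export]]
List align_ungapped_cpp(CharacterVector reads, std::string subject,
                        int min_overlap) {
  const int k = reads.size();
  const int n = subject.size();
  IntegerVector score(k), m_out(k), mm_out(k), read_start(k), read_end(k),
      offset(k);
  for (int i = 0; i < k; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    const int L = LENGTH(STRING_ELT(reads, i));
    int bs = INT_MIN, bm = 0, bmm = 0, br1 = 1, br2 = 0, bd = 0;
    for (int d = -(L - min_overlap); d <= n - min_overlap; ++d) {
      const int r1 = std::max(1, 1 - d);
      const int r2 = std::min(L, n - d);
      const int ov = r2 - r1 + 1;
      if (ov < min_overlap) continue;
      int m = 0, nN = 0;
      const char *sp = subject.c_str() + (r1 - 1 + d);
      const char *rp = r + (r1 - 1);
      for (int p = 0; p < ov; ++p) {
        const char c = rp[p];
        if (c == 'N') { ++nN; continue; }
        if (c == sp[p]) ++m;
      }
      const int mm = ov - m - nN;
      const int sc = 2 * m - 2 * mm;
      if (sc > bs) { bs = sc; bm = m; bmm = mm; br1 = r1; br2 = r2; bd = d; }
    }
    score[i] = bs; m_out[i] = bm; mm_out[i] = bmm;
    read_start[i] = br1; read_end[i] = br2; offset[i] = bd;
  }
  return List::create(_["score"] = score, _["m"] = m_out, _["mm"] = mm_out,
                      _["read_start"] = read_start, _["read_end"] = read_end,
                      _["offset"] = offset);
}

// Longest ungapped run of consecutive matches between each junction and
// each D segment, over all relative offsets. Returns the run length and
// the 1-based junction position where the best run starts.
// [[Rcpp::export]]
List longest_run_cpp(CharacterVector junctions, CharacterVector dsegs) {
  const int k = junctions.size(), nd = dsegs.size();
  IntegerMatrix len(k, nd), at(k, nd);
  for (int i = 0; i < k; ++i) {
    const char *a = CHAR(STRING_ELT(junctions, i));
    const int la = LENGTH(STRING_ELT(junctions, i));
    for (int j = 0; j < nd; ++j) {
      const char *b = CHAR(STRING_ELT(dsegs, j));
      const int lb = LENGTH(STRING_ELT(dsegs, j));
      int best = 0, best_at = NA_INTEGER;
      for (int off = -(lb - 1); off <= la - 1; ++off) {
        int run = 0;
        const int ia0 = std::max(0, off), ia1 = std::min(la - 1, lb - 1 + off);
        for (int ia = ia0; ia <= ia1; ++ia) {
          if (a[ia] == b[ia - off]) {
            ++run;
            if (run > best) { best = run; best_at = ia - run + 2; }
          } else {
            run = 0;
          }
        }
      }
      len(i, j) = best;
      at(i, j) = best_at;
    }
  }
  return List::create(_["length"] = len, _["start"] = at);
}
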