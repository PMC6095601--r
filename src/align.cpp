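#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global ("overlap" / dovetail) Needleman-Wunsch with free end gaps.
//
// Conventions (shared with the pure-R reference used in the tests):
//  * H has (n+1) x (m+1) cells, H[0][j] = H[i][0] = 0 (leading end gaps free).
//  * The alignment ends at the best cell on the last row or last column;
//    trailing end gaps are free.  Tie-break: scan the last column top to
//    bottom (i = 0..n), then the last row left to right (j = 0..m-1), and
//    keep the first cell attaining the maximum.
//  * Traceback prefers diagonal, then up (gap in b), then left (gap in a).
//  * shift  = start row - start col: signed offset of b's start relative to
//    a's start in the layout implied by the alignment.
//  * overlap = number of alignment columns; errors = mismatches + gaps.

struct AlnResult {
  int score, shift, overlap, errors;
};

static void semiglobal_core(const char* a, int n, const char* b, int m,
                            int match, int mismatch, int gap,
                            std::vector<int>& H, AlnResult& res) {
  const int W = m + 1;
  if ((int)H.size() < (n + 1) * W) H.resize((size_t)(n + 1) * W);
  for (int j = 0; j <= m; ++j) H[j] = 0;
  for (int i = 1; i <= n; ++i) {
    int* cur = &H[(size_t)i * W];
    int* prev = &H[(size_t)(i - 1) * W];
    cur[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (ai == b[j - 1] ? match : mismatch);
      int u = prev[j] + gap;
      int l = cur[j - 1] + gap;
      int best = d >= u ? d : u;
      if (l > best) best = l;
      cur[j] = best;
    }
  }
  // end cell: last column scanned first (i ascending), then last row
  int bi = 0, bj = m, bscore = H[m];
  for (int i = 1; i <= n; ++i) {
    int v = H[(size_t)i * W + m];
    if (v > bscore) { bscore = v; bi = i; bj = m; }
  }
  for (int j = 0; j < m; ++j) {
    int v = H[(size_t)n * W + j];
    if (v > bscore) { bscore = v; bi = n; bj = j; }
  }
  // traceback
  int i = bi, j = bj, cols = 0, errs = 0;
  while (i > 0 && j > 0) {
    int h = H[(size_t)i * W + j];
    int d = H[(size_t)(i - 1) * W + (j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch);
    if (h == d) {
      if (a[i - 1] != b[j - 1]) ++errs;
      ++cols; --i; --j;
    } else if (h == H[(size_t)(i - 1) * W + j] + gap) {
      ++cols; ++errs; --i;
    } else {
      ++cols; ++errs; --j;
    }
  }
  res.score = bscore;
  res.shift = i - j;
  res.overlap = cols;
  res.errors = errs;
}

//' @noRd
// [[Rcpp::export(name = ".semiglobal_one_cpp")]]
IntegerVector semiglobal_one_cpp(std::string a, std::string b,
                                 int match, int mismatch, int gap) {
  std::vector<int> H;
  AlnResult r;
  semiglobal_core(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(),
                  match, mismatch, gap, H, r);
  return IntegerVector::create(_["score"] = r.score, _["shift"] = r.shift,
                               _["overlap"] = r.overlap, _["errors"] = r.errors);
}

// Batch alignment of many pairs drawn from one sequence pool; the DP buffer
// is reused across pairs.  ai/bi are 1-based indices into seqs.
//' @noRd
// [[Rcpp::export(name = ".semiglobal_batch_cpp")]]
IntegerMatrix semiglobal_batch_cpp(CharacterVector seqs, IntegerVector ai,
                                   IntegerVector bi, int match, int mismatch,
                                   int gap) {
  const int np = ai.size();
  std::vector<std::string> pool(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) pool[i] = as<std::string>(seqs[i]);
  IntegerMatrix out(np, 4);
  colnames(out) = CharacterVector::create("score", "shift", "overlap", "errors");
  std::vector<int> H;
  AlnResult r;
  for (int p = 0; p < np; ++p) {
    const std::string& a = pool[ai[p] - 1];
    const std::string& b = pool[bi[p] - 1];
    semiglobal_core(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(),
                    match, mismatch, gap, H, r);
    out(p, 0) = r.score; out(p, 1) = r.shift;
    out(p, 2) = r.overlap; out(p, 3) = r.errors;
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Extend an exact match seed at (cpos, rpos) (1-based) in both directions
// while characters agree; returns c(cstart, cend, rstart, rend), 1-based
// inclusive.  Used by the reference-based evaluation to grow anchor blocks.
//' @noRd
// [[Rcpp::export(name = ".extend_exact_cpp")]]
IntegerVector extend_exact_cpp(std::string contig, std::string ref,
                               int cpos, int rpos, int len) {
  int cs = cpos - 1, rs = rpos - 1;          // 0-based starts
  int ce = cs + len - 1, re = rs + len - 1;  // 0-based ends
  while (cs > 0 && rs > 0 && contig[cs - 1] == ref[rs - 1]) { --cs; --rs; }
  int cn = (int)contig.size(), rn = (int)ref.size();
  while (ce + 1 < cn && re + 1 < rn && contig[ce + 1] == ref[re + 1]) { ++ce; ++re; }
  return IntegerVector::create(cs + 1, ce + 1, rs + 1, re + 1);
}
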