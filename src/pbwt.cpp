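#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One PBWT column step k -> k+1. `col` is the allele column in haplotype-id
// order; a, d are updated in place. The stable two-class partition keeps the
// radix-sort semantics; p/q are the transient running maxima that produce the
// next divergence values.
static void advance_step(const int* col, std::vector<int>& a, std::vector<int>& d,
                         std::vector<int>& a0, std::vector<int>& d0,
                         std::vector<int>& a1, std::vector<int>& d1, int k) {
  const int M = (int)a.size();
  int u = 0, v = 0;
  int p = k + 1, q = k + 1;
  for (int i = 0; i < M; ++i) {
    const int di = d[i];
    if (di > p) p = di;
    if (di > q) q = di;
    if (col[a[i]] == 0) {
      a0[u] = a[i]; d0[u] = p; ++u; p = 0;
    } else {
      a1[v] = a[i]; d1[v] = q; ++v; q = 0;
    }
  }
  for (int i = 0; i < u; ++i) { a[i] = a0[i]; d[i] = d0[i]; }
  for (int i = 0; i < v; ++i) { a[u + i] = a1[i]; d[u + i] = d1[i]; }
}

static void check_binary_column(const int* col, int M, int k) {
  for (int i = 0; i < M; ++i) {
    if (col[i] != 0 && col[i] != 1)
      stop("non-binary allele at locus %d, haplotype %d", k, i);
  }
}

// Advance (a, d) from locus `start` to locus `end` over the panel columns.
// [[Rcpp::export]]
List cpp_build_range(const IntegerMatrix& panel, const IntegerVector& a_in,
                     const IntegerVector& d_in, int start, int end) {
  const int M = panel.nrow();
  if ((int)a_in.size() != M || (int)d_in.size() != M)
    stop("state arrays do not match panel haplotype count");
  if (start < 0 || end > panel.ncol() || start > end)
    stop("invalid locus range [%d, %d)", start, end);
  std::vector<int> a(a_in.begin(), a_in.end()), d(d_in.begin(), d_in.end());
  std::vector<int> a0(M), d0(M), a1(M), d1(M);
  const int* base = panel.length() ? &panel[0] : nullptr;
  for (int k = start; k < end; ++k) {
    const int* col = base + (size_t)k * M;
    check_binary_column(col, M, k);
    advance_step(col, a, d, a0, d0, a1, d1, k);
  }
  return List::create(_["a"] = IntegerVector(a.begin(), a.end()),
                      _["d"] = IntegerVector(d.begin(), d.end()));
}

// Single-column advance at true locus k (column in haplotype-id order).
// [[Rcpp::export]]
List cpp_advance(const IntegerVector& column, const IntegerVector& a_in,
                 const IntegerVector& d_in, int k) {
  const int M = (int)column.size();
  if ((int)a_in.size() != M || (int)d_in.size() != M)
    stop("state arrays do not match column length");
  std::vector<int> a(a_in.begin(), a_in.end()), d(d_in.begin(), d_in.end());
  std::vector<int> a0(M), d0(M), a1(M), d1(M);
  check_binary_column(&column[0], M, k);
  advance_step(&column[0], a, d, a0, d0, a1, d1, k);
  return List::create(_["a"] = IntegerVector(a.begin(), a.end()),
                      _["d"] = IntegerVector(d.begin(), d.end()));
}

struct MatchSink {
  std::vector<int> hi, hj, st, en;
  void emit(int x, int y, int s, int e) {
    if (x > y) std::swap(x, y);
    hi.push_back(x); hj.push_back(y); st.push_back(s); en.push_back(e);
  }
  List as_list() const {
    return List::create(_["hap_i"] = IntegerVector(hi.begin(), hi.end()),
                        _["hap_j"] = IntegerVector(hj.begin(), hj.end()),
                        _["start"] = IntegerVector(st.begin(), st.end()),
                        _["end"] = IntegerVector(en.begin(), en.end()));
  }
};

// Report matches of length >= L that terminate at locus k (allele mismatch at
// k, or k == N when flush). Blocks of adjacent haplotypes whose pairwise
// divergences are all <= k - L share runs of length >= L; the exact start of a
// pair's run is the running maximum of d over the positions between them.
static void report_long(const int* col, const std::vector<int>& a,
                        const std::vector<int>& d, int k, int L, bool flush,
                        MatchSink& out) {
  const int M = (int)a.size();
  int i0 = 0;
  for (int i = 1; i <= M; ++i) {
    if (i == M || d[i] > k - L) {
      if (i - i0 >= 2) {
        bool any0 = false, any1 = false;
        if (!flush) {
          for (int j = i0; j < i; ++j) (col[a[j]] == 0 ? any0 : any1) = true;
        }
        if (flush || (any0 && any1)) {
          for (int q = i0 + 1; q < i; ++q) {
            int m = 0;
            for (int p = q - 1; p >= i0; --p) {
              if (d[p + 1] > m) m = d[p + 1];
              if (flush || col[a[p]] != col[a[q]]) out.emit(a[p], a[q], m, k);
            }
          }
        }
      }
      i0 = i;
    }
  }
}

// Report set-maximal matches terminating at locus k. For sorted position i the
// longest matches of haplotype a[i] ending at k start at s* = min(d[i], d[i+1]);
// the partners achieving s* sit in the contiguous neighbour windows scanned
// below. If any such partner carries the same allele at k the match extends
// past k and nothing set-maximal ends here for a[i].
static void report_setmax(const int* col, const std::vector<int>& a,
                          const std::vector<int>& d, int k, bool flush,
                          MatchSink& out) {
  const int M = (int)a.size();
  for (int i = 0; i < M; ++i) {
    const int dab = d[i];                       // divergence to neighbour below
    const int dup = (i + 1 < M) ? d[i + 1] : k; // virtual sentinel d[M] = k
    if (dab >= k && dup >= k) continue;         // no nonempty match ends here
    const bool down = dab <= dup, up = dab >= dup;
    int m = i - 1, n = i + 1;
    bool continues = false;
    if (down) {
      while (m >= 0 && d[m + 1] <= dab) {
        if (!flush && col[a[m]] == col[a[i]]) { continues = true; break; }
        --m;
      }
    }
    if (up && !continues) {
      while (n < M && d[n] <= dup) {
        if (!flush && col[a[n]] == col[a[i]]) { continues = true; break; }
        ++n;
      }
    }
    if (continues) continue;
    if (down && dab < k)
      for (int j = m + 1; j < i; ++j) out.emit(a[i], a[j], dab, k);
    if (up && dup < k)
      for (int j = i + 1; j < n; ++j) out.emit(a[i], a[j], dup, k);
  }
}

// Sweep loci [start, end): at each k report matches terminating at k, then
// advance the state. When flush, also report matches still open at k == end
// (used by the final chunk, end == N).
// [[Rcpp::export]]
List cpp_match_range(const IntegerMatrix& panel, const IntegerVector& a_in,
                     const IntegerVector& d_in, int start, int end,
                     bool set_maximal, int L, bool flush) {
  const int M = panel.nrow();
  if ((int)a_in.size() != M || (int)d_in.size() != M)
    stop("state arrays do not match panel haplotype count");
  if (start < 0 || end > panel.ncol() || start > end)
    stop("invalid locus range [%d, %d)", start, end);
  std::vector<int> a(a_in.begin(), a_in.end()), d(d_in.begin(), d_in.end());
  std::vector<int> a0(M), d0(M), a1(M), d1(M);
  const int* base = panel.length() ? &panel[0] : nullptr;
  MatchSink out;
  for (int k = start; k < end; ++k) {
    const int* col = base + (size_t)k * M;
    check_binary_column(col, M, k);
    if (set_maximal) report_setmax(col, a, d, k, false, out);
    else report_long(col, a, d, k, L, false, out);
    advance_step(col, a, d, a0, d0, a1, d1, k);
  }
  if (flush) {
    if (set_maximal) report_setmax(nullptr, a, d, end, true, out);
    else report_long(nullptr, a, d, end, L, true, out);
  }
  return out.as_list();
}
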