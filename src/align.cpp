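#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with match +1, mismatch -1, linear
// gap -1. Among score-optimal alignments the one maximising the number of
// matched columns, then minimising alignment length, is reported; this makes
// the derived percent identity well defined and symmetric in its arguments.
// Remaining ties in the traceback are broken diagonal > up > left.

struct Cell { int score, matches, len; };

static inline bool better(const Cell &a, const Cell &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.matches != b.matches) return a.matches > b.matches;
  return a.len < b.len;
}

static Cell nw_cells(const std::string &a, const std::string &b,
                     std::vector<Cell> *full /* may be NULL */) {
  const int n = a.size(), m = b.size();
  // rolling rows as parallel arrays; the lexicographic objective
  // (score, matches, -len) is packed into one 64-bit key so each cell is a
  // single comparison: score in the high bits, matches in the middle,
  // (large constant - len) in the low bits. All three components are
  // bounded by n + m < 2^20, so the packing cannot overflow or alias.
  const long long B = 1LL << 21;
  std::vector<long long> prev(m + 1), cur(m + 1);
  const long long LEN0 = B - 1;     // len stored as LEN0 - len
  for (int j = 0; j <= m; ++j)
    prev[j] = ((long long)(-j + B / 2) * B + 0) * B + (LEN0 - j);
  if (full)
    for (int j = 0; j <= m; ++j) {
      long long v = prev[j];
      (*full)[j] = Cell{(int)(v / (B * B) - B / 2),
                        (int)((v / B) % B), (int)(LEN0 - v % B)};
    }
  const long long DIAG_MISS = -(B * B) + /* len +1 */ -1;
  const long long DIAG_HIT = (B * B) + B - 1;
  const long long GAP = -(B * B) - 1;
  for (int i = 1; i <= n; ++i) {
    cur[0] = ((long long)(-i + B / 2) * B + 0) * B + (LEN0 - i);
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      long long best = prev[j - 1] + (ai == b[j - 1] ? DIAG_HIT : DIAG_MISS);
      const long long up = prev[j] + GAP;
      if (up > best) best = up;
      const long long left = cur[j - 1] + GAP;
      if (left > best) best = left;
      cur[j] = best;
    }
    if (full)
      for (int j = 0; j <= m; ++j) {
        long long v = cur[j];
        (*full)[(size_t)i * (m + 1) + j] =
          Cell{(int)(v / (B * B) - B / 2), (int)((v / B) % B),
               (int)(LEN0 - v % B)};
      }
    std::swap(prev, cur);
  }
  long long v = prev[m];
  return Cell{(int)(v / (B * B) - B / 2), (int)((v / B) % B),
              (int)(LEN0 - v % B)};
}

// [[Rcpp::export(name = ".nw_align")]]
List nw_align_cpp(std::string a, std::string b, bool alignment = false) {
  const int n = a.size(), m = b.size();
  if (!alignment) {
    Cell fin = nw_cells(a, b, NULL);
    return List::create(_["score"] = fin.score, _["matches"] = fin.matches,
                        _["length"] = fin.len);
  }
  std::vector<Cell> full((size_t)(n + 1) * (m + 1));
  Cell fin = nw_cells(a, b, &full);
  // traceback: at each cell pick the predecessor consistent with the stored
  // optimum, preferring diagonal, then up, then left
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const Cell &c = full[(size_t)i * (m + 1) + j];
    bool done = false;
    if (i > 0 && j > 0) {
      const Cell &d = full[(size_t)(i - 1) * (m + 1) + (j - 1)];
      const bool hit = a[i - 1] == b[j - 1];
      if (c.score == d.score + (hit ? 1 : -1) &&
          c.matches == d.matches + (hit ? 1 : 0) && c.len == d.len + 1) {
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
        --i; --j; done = true;
      }
    }
    if (!done && i > 0) {
      const Cell &u = full[(size_t)(i - 1) * (m + 1) + j];
      if (c.score == u.score - 1 && c.matches == u.matches && c.len == u.len + 1) {
        ra.push_back(a[i - 1]); rb.push_back('-');
        --i; done = true;
      }
    }
    if (!done) {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = fin.score, _["matches"] = fin.matches,
                      _["length"] = fin.len, _["aligned_a"] = ra,
                      _["aligned_b"] = rb);
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    default: return 'N';
  }
}

// Palindromy of every circular window of width unit_len taken at the given
// stride: identity fraction of the window aligned globally against its own
// reverse complement. Returns one value per start position 1, 1+step, ...
// [[Rcpp::export(name = ".palindromy_scan")]]
NumericVector palindromy_scan_cpp(std::string seq, int unit_len, int step) {
  const int L = seq.size();
  std::string dd = seq + seq;
  const int nwin = (L + step - 1) / step;
  NumericVector out(nwin);
  std::string w(unit_len, 'A'), rc(unit_len, 'A');
  for (int k = 0; k < nwin; ++k) {
    const int s = k * step;
    for (int t = 0; t < unit_len; ++t) w[t] = dd[s + t];
    for (int t = 0; t < unit_len; ++t) rc[t] = comp(w[unit_len - 1 - t]);
    Cell fin = nw_cells(w, rc, NULL);
    out[k] = (double)fin.matches / (double)fin.len;
  }
  return out;
}
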