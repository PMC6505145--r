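#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; -1 for anything outside ACGT (case-insensitive)
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// [[Rcpp::export]]
std::string cpp_revcomp(const std::string& seq) {
  size_t n = seq.size();
  std::string out(n, 'N');
  for (size_t i = 0; i < n; ++i) {
    char c = seq[n - 1 - i];
    switch (c) {
      case 'A': case 'a': out[i] = 'T'; break;
      case 'C': case 'c': out[i] = 'G'; break;
      case 'G': case 'g': out[i] = 'C'; break;
      case 'T': case 't': out[i] = 'A'; break;
      default: out[i] = 'N';
    }
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_strrev(const std::string& seq) {
  return std::string(seq.rbegin(), seq.rend());
}

// Canonical k-mer codes at every position (0-based). code = NA where the
// window contains a non-ACGT base. flag = 1 when the forward k-mer is the
// canonical one, 0 when its reverse complement is. k <= 26 so the code is
// exact in a double (4^26 < 2^53).
// [[Rcpp::export]]
List cpp_kmer_codes(const std::string& seq, int k) {
  int L = (int)seq.size();
  int n = L - k + 1;
  if (n < 1) return List::create(_["code"] = NumericVector(0),
                                 _["flag"] = IntegerVector(0));
  NumericVector code(n, NA_REAL);
  IntegerVector flag(n, NA_INTEGER);
  uint64_t fw = 0, rc = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  int valid = 0;  // length of current run of valid bases ending at i
  for (int i = 0; i < L; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { valid = 0; fw = 0; rc = 0; continue; }
    fw = ((fw << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
    ++valid;
    if (valid >= k) {
      int pos = i - k + 1;
      if (fw <= rc) { code[pos] = (double)fw; flag[pos] = 1; }
      else          { code[pos] = (double)rc; flag[pos] = 0; }
    }
  }
  return List::create(_["code"] = code, _["flag"] = flag);
}

// Forward and reverse-complement window codes at stepped positions, for
// dot plots. Windows containing non-ACGT bases are skipped.
// [[Rcpp::export]]
List cpp_window_codes(const std::string& seq, int w, int step) {
  int L = (int)seq.size();
  std::vector<int> pos;
  std::vector<double> fwv, rcv;
  if (L >= w) {
    // precompute rolling codes at every position, then subsample by step
    std::vector<double> fall(L - w + 1, NA_REAL), rall(L - w + 1, NA_REAL);
    uint64_t fw = 0, rc = 0;
    const uint64_t mask = (w < 32) ? ((1ULL << (2 * w)) - 1) : ~0ULL;
    const int shift = 2 * (w - 1);
    int valid = 0;
    for (int i = 0; i < L; ++i) {
      int b = base_code(seq[i]);
      if (b < 0) { valid = 0; fw = 0; rc = 0; continue; }
      fw = ((fw << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
      ++valid;
      if (valid >= w) {
        fall[i - w + 1] = (double)fw;
        rall[i - w + 1] = (double)rc;
      }
    }
    for (int p = 0; p + w <= L; p += step) {
      if (!ISNA(fall[p])) {
        pos.push_back(p);
        fwv.push_back(fall[p]);
        rcv.push_back(rall[p]);
      }
    }
  }
  return List::create(_["pos"] = wrap(pos), _["fw"] = wrap(fwv),
                      _["rc"] = wrap(rcv));
}

// Co-linear chaining of seed anchors (q, t), both 0-based k-mer start
// positions on the same query/target/relative-strand. Anchors must be
// pre-sorted by (q, t). Returns one row per extracted chain:
// qs, qe, ts, te (starts of first/last anchor), n_anchors, score.
// [[Rcpp::export]]
IntegerMatrix cpp_chain(IntegerVector q, IntegerVector t, int k,
                        int max_gap, int min_anchors, int lookback) {
  int n = q.size();
  if (n == 0) return IntegerMatrix(0, 6);
  std::vector<double> dp(n);
  std::vector<int> parent(n, -1);
  for (int i = 0; i < n; ++i) {
    dp[i] = k;
    int j0 = std::max(0, i - lookback);
    for (int j = i - 1; j >= j0; --j) {
      if (q[j] >= q[i]) continue;
      if (t[j] >= t[i]) continue;
      int dq = q[i] - q[j], dt = t[i] - t[j];
      if (dq > max_gap || dt > max_gap) continue;
      int gain = std::min(std::min(dq, dt), k);
      double pen = 0.1 * std::abs(dq - dt);
      double cand = dp[j] + gain - pen;
      if (cand > dp[i]) { dp[i] = cand; parent[i] = j; }
    }
  }
  // extract chains greedily from best unused endpoints
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return dp[a] > dp[b]; });
  std::vector<bool> used(n, false);
  std::vector<std::array<int, 6>> chains;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    if (used[i]) continue;
    // walk back; stop at used anchors so chains never share anchors
    int cnt = 0, first = i, cur = i;
    while (cur >= 0 && !used[cur]) {
      used[cur] = true;
      first = cur;
      ++cnt;
      cur = parent[cur];
    }
    if (cnt >= min_anchors) {
      chains.push_back({q[first], q[i], t[first], t[i], cnt,
                        (int)std::lround(dp[i])});
    }
  }
  IntegerMatrix out((int)chains.size(), 6);
  for (size_t r = 0; r < chains.size(); ++r)
    for (int c = 0; c < 6; ++c) out((int)r, c) = chains[r][c];
  colnames(out) = CharacterVector::create("qs", "qe", "ts", "te",
                                          "n_anchors", "score");
  return out;
}

// Banded global alignment of a vs b counting matches on one optimal path.
// Returns (n_match, block_len). block_len = la + lb - n_diagonal_steps.
// Scores: match +1, mismatch -1, gap -1 (maximized). The band is centered
// on the straight line between the alignment endpoints.
// [[Rcpp::export]]
IntegerVector cpp_banded_stats(const std::string& a, const std::string& b,
                               int band) {
  int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0)
    return IntegerVector::create(0, la + lb);
  const int NEG = -1000000000;
  // cell (i, j) is stored at column index j - lo[i]; the band follows the
  // interpolated diagonal j ~ i * lb / la
  int W = 2 * band + 2;
  std::vector<int> ps(W), pm(W), pd(W), cs(W), cm(W), cd(W);
  std::vector<int> acode(la), bcode(lb);
  for (int i = 0; i < la; ++i) acode[i] = base_code(a[i]);
  for (int j = 0; j < lb; ++j) bcode[j] = base_code(b[j]);
  auto center = [&](int i) { return (int)((long long)i * lb / la); };
  int plo = 0, phi = std::min(lb, band);  // row 0 valid j range
  for (int j = plo; j <= phi; ++j) { ps[j - plo] = -j; pm[j - plo] = 0; pd[j - plo] = 0; }
  for (int i = 1; i <= la; ++i) {
    int c = center(i);
    int lo = std::max(0, c - band), hi = std::min(lb, c + band);
    for (int j = lo; j <= hi; ++j) {
      int bs = NEG, bm = 0, bd = 0;
      if (j == 0) {
        bs = -i;
      } else {
        int pj = j - 1 - plo;  // diagonal: (i-1, j-1)
        if (pj >= 0 && j - 1 <= phi) {
          bool eq = (acode[i - 1] >= 0 && acode[i - 1] == bcode[j - 1]);
          bs = ps[pj] + (eq ? 1 : -1);
          bm = pm[pj] + (eq ? 1 : 0);
          bd = pd[pj] + 1;
        }
        int uj = j - plo;      // up: (i-1, j)
        if (uj >= 0 && j <= phi) {
          int s = ps[uj] - 1;
          if (s > bs || (s == bs && pm[uj] > bm)) {
            bs = s; bm = pm[uj]; bd = pd[uj];
          }
        }
        if (j - 1 >= lo) {     // left: (i, j-1)
          int s = cs[j - 1 - lo] - 1;
          if (s > bs || (s == bs && cm[j - 1 - lo] > bm)) {
            bs = s; bm = cm[j - 1 - lo]; bd = cd[j - 1 - lo];
          }
        }
      }
      cs[j - lo] = bs; cm[j - lo] = bm; cd[j - lo] = bd;
    }
    std::swap(ps, cs); std::swap(pm, cm); std::swap(pd, cd);
    plo = lo; phi = hi;
  }
  if (lb < plo || lb > phi || ps[lb - plo] < NEG / 2)
    return IntegerVector::create(0, la + lb);
  return IntegerVector::create(pm[lb - plo], la + lb - pd[lb - plo]);
}

// Global alignment of two short windows with full traceback. For every
// position of `a`, reports the 0-based `b` position it aligns to (-1 when
// consumed by a gap) and whether the aligned bases match. Scores:
// match +2, mismatch -3, gap -2. Intended for breakpoint-refinement
// windows (a few hundred bp), not long sequences.
// [[Rcpp::export]]
List cpp_align_path(const std::string& a, const std::string& b) {
  int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> prev(lb + 1), curr(lb + 1);
  std::vector<unsigned char> tb((size_t)(la + 1) * (lb + 1));
  for (int j = 0; j <= lb; ++j) { prev[j] = -2 * j; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= la; ++i) {
    curr[0] = -2 * i;
    tb[(size_t)i * (lb + 1)] = 1;  // up (gap in b)
    for (int j = 1; j <= lb; ++j) {
      bool eq = (base_code(a[i - 1]) >= 0 &&
                 base_code(a[i - 1]) == base_code(b[j - 1]));
      int sd = prev[j - 1] + (eq ? 2 : -3);
      int su = prev[j] - 2;
      int sl = curr[j - 1] - 2;
      int s = sd; unsigned char t = 0;
      if (su > s) { s = su; t = 1; }
      if (sl > s) { s = sl; t = 2; }
      curr[j] = s;
      tb[(size_t)i * (lb + 1) + j] = t;
    }
    std::swap(prev, curr);
  }
  IntegerVector bidx(la, -1);
  LogicalVector match(la, false);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (lb + 1) + j];
    if (i > 0 && j > 0 && t == 0) {
      bidx[i - 1] = j - 1;
      match[i - 1] = (base_code(a[i - 1]) >= 0 &&
                      base_code(a[i - 1]) == base_code(b[j - 1]));
      --i; --j;
    } else if (i > 0 && (t == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
  }
  return List::create(_["b_index"] = bidx, _["match"] = match);
}

// Local (Smith-Waterman) alignment of two short windows with traceback
// from the best cell. For every `a` position on the optimal local path,
// reports the aligned `b` position and whether the bases match; positions
// off the path stay -1/false. Scores: match +2, mismatch -3, gap -2.
// [[Rcpp::export]]
List cpp_align_local(const std::string& a, const std::string& b) {
  int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> prev(lb + 1, 0), curr(lb + 1, 0);
  std::vector<unsigned char> tb((size_t)(la + 1) * (lb + 1), 3);  // 3 = stop
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    curr[0] = 0;
    for (int j = 1; j <= lb; ++j) {
      bool eq = (base_code(a[i - 1]) >= 0 &&
                 base_code(a[i - 1]) == base_code(b[j - 1]));
      int s = prev[j - 1] + (eq ? 2 : -3);
      unsigned char t = 0;
      if (prev[j] - 2 > s) { s = prev[j] - 2; t = 1; }
      if (curr[j - 1] - 2 > s) { s = curr[j - 1] - 2; t = 2; }
      if (s <= 0) { s = 0; t = 3; }
      curr[j] = s;
      tb[(size_t)i * (lb + 1) + j] = t;
      if (s > best) { best = s; bi = i; bj = j; }
    }
    std::swap(prev, curr);
  }
  IntegerVector bidx(la, -1);
  LogicalVector match(la, false);
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * (lb + 1) + j];
    if (t == 3) break;
    if (t == 0) {
      bidx[i - 1] = j - 1;
      match[i - 1] = (base_code(a[i - 1]) >= 0 &&
                      base_code(a[i - 1]) == base_code(b[j - 1]));
      --i; --j;
    } else if (t == 1) {
      --i;
    } else {
      --j;
    }
  }
  return List::create(_["b_index"] = bidx, _["match"] = match);
}

// Inject i.i.d. per-base errors. For each template base: deleted with
// probability del; otherwise emitted, substituted with probability sub;
// a random base is inserted after it with probability ins. Uses R's RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export]]
std::string cpp_mutate(const std::string& seq, double sub, double ins,
                       double del) {
  std::string out;
  out.reserve((size_t)(seq.size() * (1.0 + ins) + 16));
  for (size_t i = 0; i < seq.size(); ++i) {
    if (del > 0 && unif_rand() < del) {
      // deleted; fall through to possible insertion? no: deletion removes
      // the base entirely
    } else {
      char c = seq[i];
      if (sub > 0 && unif_rand() < sub) {
        int b = base_code(c);
        int r = (int)(unif_rand() * 3);
        if (r > 2) r = 2;
        // pick one of the three other bases
        int nb = (b < 0) ? r : (r + b + 1) % 4;
        c = BASES[nb];
      }
      out.push_back(c);
    }
    if (ins > 0 && unif_rand() < ins) {
      int r = (int)(unif_rand() * 4);
      if (r > 3) r = 3;
      out.push_back(BASES[r]);
    }
  }
  return out;
}
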