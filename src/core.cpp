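#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// 2-bit base codes; -1 for N / IUPAC ambiguity (breaks k-mer windows)
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// invertible 64-bit mix (Thomas Wang); used only to randomise minimizer order
static inline uint64_t hash64(uint64_t key, uint64_t mask) {
  key = (~key + (key << 21)) & mask;
  key = key ^ (key >> 24);
  key = ((key + (key << 3)) + (key << 8)) & mask;
  key = key ^ (key >> 14);
  key = ((key + (key << 2)) + (key << 4)) & mask;
  key = key ^ (key >> 28);
  key = (key + (key << 31)) & mask;
  return key;
}

struct Mz {
  uint64_t key;   // canonical packed k-mer (exact, collision-free for fixed k)
  uint64_t hash;  // mixed hash used for window-minimum selection
  int pos;        // 0-based start on forward strand
  uint8_t flag;   // 0 = canonical is forward, 1 = canonical is reverse
};

// minimizer sketch: leftmost-minimum of each window of w consecutive k-mers
static void sketch(const std::string& s, int k, int w, std::vector<Mz>& out) {
  int n = (int) s.size();
  if (n < k) return;
  uint64_t mask = (2 * k < 64) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int shift = 2 * (k - 1);
  uint64_t kf = 0, kr = 0;
  int l = 0;
  int nk = n - k + 1;
  std::vector<Mz> kms;           // valid k-mers, kms[i].pos strictly increasing
  kms.reserve(nk);
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { l = 0; kf = 0; kr = 0; continue; }
    kf = ((kf << 2) | (uint64_t) c) & mask;
    kr = (kr >> 2) | (((uint64_t) (3 - c)) << shift);
    if (++l < k) continue;
    int pos = i - k + 1;
    Mz m;
    if (kf <= kr) { m.key = kf; m.flag = 0; } else { m.key = kr; m.flag = 1; }
    m.hash = hash64(m.key, mask);
    m.pos = pos;
    kms.push_back(m);
  }
  if (kms.empty()) return;
  // slide a window of w consecutive k-mer start positions; emit the leftmost
  // minimal hash among valid k-mers present in the window
  int m = (int) kms.size();
  int last_emitted = -1;
  size_t lo = 0, hi = 0;  // kms index range [lo, hi) inside current window
  for (int wstart = 0; wstart <= nk - w || (w > nk && wstart == 0); ++wstart) {
    int wend = wstart + w;  // window covers k-mer positions [wstart, wend)
    while (hi < kms.size() && kms[hi].pos < wend) ++hi;
    while (lo < hi && kms[lo].pos < wstart) ++lo;
    if (lo >= hi) continue;
    size_t best = lo;
    for (size_t j = lo + 1; j < hi; ++j)
      if (kms[j].hash < kms[best].hash) best = j;
    if ((int) best != last_emitted) {
      out.push_back(kms[best]);
      last_emitted = (int) best;
    }
    if (w > nk) break;
  }
}

// [[Rcpp::export]]
DataFrame cpp_sketch(std::string seq, int k, int w) {
  std::vector<Mz> v;
  sketch(seq, k, w, v);
  int n = (int) v.size();
  IntegerVector pos(n), flag(n);
  NumericVector key(n);  // exact only for k <= 26; used in small-k tests
  for (int i = 0; i < n; ++i) {
    pos[i] = v[i].pos; flag[i] = v[i].flag; key[i] = (double) v[i].key;
  }
  return DataFrame::create(_["pos"] = pos, _["flag"] = flag, _["key"] = key);
}

struct Hit { int32_t contig; int32_t pos; uint8_t flag; };

struct MzIndex {
  int k, w;
  std::unordered_map<uint64_t, std::vector<Hit> > map;
};

// [[Rcpp::export]]
SEXP cpp_build_index(List seqs, int k, int w, int max_occ) {
  MzIndex* idx = new MzIndex();
  idx->k = k; idx->w = w;
  for (int ci = 0; ci < seqs.size(); ++ci) {
    std::string s = as<std::string>(seqs[ci]);
    std::vector<Mz> v;
    sketch(s, k, w, v);
    for (size_t j = 0; j < v.size(); ++j) {
      Hit h; h.contig = ci + 1; h.pos = v[j].pos; h.flag = v[j].flag;
      idx->map[v[j].key].push_back(h);
    }
  }
  // repetitive k-mers: drop keys observed more than max_occ times
  if (max_occ > 0) {
    for (auto it = idx->map.begin(); it != idx->map.end();) {
      if ((int) it->second.size() > max_occ) it = idx->map.erase(it);
      else ++it;
    }
  }
  XPtr<MzIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
DataFrame cpp_query_anchors(SEXP idx_ptr, std::string seq) {
  XPtr<MzIndex> idx(idx_ptr);
  std::vector<Mz> v;
  sketch(seq, idx->k, idx->w, v);
  std::vector<int> contig, bpos, apos, strand;
  for (size_t j = 0; j < v.size(); ++j) {
    auto it = idx->map.find(v[j].key);
    if (it == idx->map.end()) continue;
    const std::vector<Hit>& hits = it->second;
    for (size_t h = 0; h < hits.size(); ++h) {
      contig.push_back(hits[h].contig);
      bpos.push_back(v[j].pos);
      apos.push_back(hits[h].pos);
      strand.push_back(v[j].flag == hits[h].flag ? 1 : -1);
    }
  }
  return DataFrame::create(_["contig"] = contig, _["base_pos"] = bpos,
                           _["alt_pos"] = apos, _["strand"] = strand);
}

// Collinear chaining by sparse DP. Anchors must be sorted by (x, y).
// Score of appending anchor i after j: min(k, x_i - x_j, y_i - y_j); per-axis
// gap (start distance minus k) must not exceed gap_limit, the link must stay
// near the diagonal (|dx - dy| <= diag_limit, so a stray one-off match cannot
// bridge a rearrangement), and both coordinates must strictly advance. Each
// link pays diag_penalty per bp of off-diagonal drift, so within a tandem
// repeat the chain prefers the copy on the flanks' diagonal over an
// equal-scoring slipped copy.
// Returns a chain id per anchor plus per-chain scores.
// [[Rcpp::export]]
List cpp_chain(IntegerVector x, IntegerVector y, int k, double gap_limit,
               double diag_limit, double diag_penalty, int max_lookback) {
  int n = x.size();
  std::vector<double> f(n);
  std::vector<int> par(n, -1);
  for (int i = 0; i < n; ++i) {
    f[i] = k;
    int j0 = std::max(0, i - max_lookback);
    for (int j = i - 1; j >= j0; --j) {
      int dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx <= 0 || dy <= 0) continue;
      if (dx - k > gap_limit || dy - k > gap_limit) continue;
      if (std::abs(dx - dy) > diag_limit) continue;
      double cand = f[j] + std::min((double) k, (double) std::min(dx, dy))
        - diag_penalty * std::abs(dx - dy);
      if (cand > f[i]) { f[i] = cand; par[i] = j; }
    }
  }
  // peel chains best-first; a path stops when it reaches an already-used anchor
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return f[a] > f[b]; });
  std::vector<int> cid(n, 0);
  std::vector<double> scores;
  int nchain = 0;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    if (cid[i]) continue;
    ++nchain;
    double base_score = 0.0;
    int j = i;
    while (j >= 0 && !cid[j]) { cid[j] = nchain; j = par[j]; }
    if (j >= 0) base_score = f[j];  // shared prefix belongs to an earlier chain
    scores.push_back(f[i] - base_score);
  }
  return List::create(_["chain"] = wrap(cid), _["score"] = wrap(scores));
}
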