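#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Bit-packed GF(2) linear algebra for random linear block codes.
// Rows are codewords of length n packed into 64-bit words.

typedef std::vector<uint64_t> BitRow;

static inline int popcnt_row(const BitRow& r) {
  int s = 0;
  for (size_t w = 0; w < r.size(); ++w) s += __builtin_popcountll(r[w]);
  return s;
}

static inline void xor_row(BitRow& a, const BitRow& b) {
  for (size_t w = 0; w < a.size(); ++w) a[w] ^= b[w];
}

static inline bool get_bit(const BitRow& r, int j) {
  return (r[j >> 6] >> (j & 63)) & 1ULL;
}

static inline void set_bit(BitRow& r, int j) {
  r[j >> 6] |= (1ULL << (j & 63));
}

static std::vector<BitRow> pack_matrix(const IntegerMatrix& G) {
  const int k = G.nrow(), n = G.ncol();
  const int W = (n + 63) / 64;
  std::vector<BitRow> rows(k, BitRow(W, 0));
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < n; ++j)
      if (G(i, j)) set_bit(rows[i], j);
  return rows;
}

static BitRow pack_vector(const IntegerVector& v) {
  const int n = v.size();
  BitRow r((n + 63) / 64, 0);
  for (int j = 0; j < n; ++j) if (v[j]) set_bit(r, j);
  return r;
}

static IntegerVector unpack_row(const BitRow& r, int n) {
  IntegerVector out(n);
  for (int j = 0; j < n; ++j) out[j] = get_bit(r, j) ? 1 : 0;
  return out;
}

// sample k distinct values in 0..(n-1) using R's RNG (partial Fisher-Yates)
static void sample_columns(int n, int k, std::vector<int>& pool, std::vector<int>& out) {
  for (int i = 0; i < n; ++i) pool[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

// [[Rcpp::export]]
int cpp_gf2_rank(const IntegerMatrix& G) {
  std::vector<BitRow> rows = pack_matrix(G);
  const int k = G.nrow(), n = G.ncol();
  int rank = 0;
  for (int j = 0; j < n && rank < k; ++j) {
    int piv = -1;
    for (int i = rank; i < k; ++i)
      if (get_bit(rows[i], j)) { piv = i; break; }
    if (piv < 0) continue;
    std::swap(rows[rank], rows[piv]);
    for (int i = 0; i < k; ++i)
      if (i != rank && get_bit(rows[i], j)) xor_row(rows[i], rows[rank]);
    ++rank;
  }
  return rank;
}

// Reduce rows to systematic form on the selected columns.
// Returns false if the selection is not an information set.
static bool systematize(std::vector<BitRow>& rows, const std::vector<int>& cols) {
  const int k = rows.size();
  for (int j = 0; j < k; ++j) {
    int piv = -1;
    for (int i = j; i < k; ++i)
      if (get_bit(rows[i], cols[j])) { piv = i; break; }
    if (piv < 0) return false;
    std::swap(rows[j], rows[piv]);
    for (int i = 0; i < k; ++i)
      if (i != j && get_bit(rows[i], cols[j])) xor_row(rows[i], rows[j]);
  }
  return true;
}

// Information-set low-weight codeword search. Examines rows of random
// systematic forms and all pairwise row sums; returns the smallest nonzero
// codeword weight observed (an upper bound on the true minimum distance).
// [[Rcpp::export]]
int cpp_min_weight_isd(const IntegerMatrix& G, int iters, bool pair_sums) {
  std::vector<BitRow> base = pack_matrix(G);
  const int k = G.nrow(), n = G.ncol();
  const int W = (n + 63) / 64;
  std::vector<int> pool(n), cols(k);
  int best = n + 1;
  std::vector<BitRow> rows;
  BitRow tmp(W);
  for (int it = 0; it < iters; ++it) {
    sample_columns(n, k, pool, cols);
    rows = base;
    if (!systematize(rows, cols)) continue;
    for (int i = 0; i < k; ++i) {
      int w = popcnt_row(rows[i]);
      if (w > 0 && w < best) best = w;
    }
    if (pair_sums) {
      for (int i = 0; i < k; ++i)
        for (int j = i + 1; j < k; ++j) {
          tmp = rows[i];
          xor_row(tmp, rows[j]);
          int w = popcnt_row(tmp);
          if (w > 0 && w < best) best = w;
        }
    }
  }
  return best;
}

// Exhaustive minimum-weight via Gray-code enumeration of all 2^k codewords.
// [[Rcpp::export]]
int cpp_min_weight_exhaustive(const IntegerMatrix& G) {
  const int k = G.nrow(), n = G.ncol();
  if (k > 24) stop("exhaustive enumeration limited to k <= 24");
  std::vector<BitRow> rows = pack_matrix(G);
  BitRow c(rows[0].size(), 0);
  uint64_t prev = 0;
  int best = n + 1;
  const uint64_t N = 1ULL << k;
  for (uint64_t i = 1; i < N; ++i) {
    uint64_t g = i ^ (i >> 1);        // Gray code
    uint64_t diff = g ^ prev;
    xor_row(c, rows[__builtin_ctzll(diff)]);
    prev = g;
    int w = popcnt_row(c);
    if (w > 0 && w < best) best = w;
  }
  return best;
}

// message bits (grey-coded state) recovered from a Gray index
static IntegerVector gray_to_bits(uint64_t g, int k) {
  IntegerVector m(k);
  for (int i = 0; i < k; ++i) m[i] = (g >> i) & 1ULL;
  return m;
}

// Exhaustive nearest-codeword decoding. Returns the minimum-distance
// message, the distance, and the number of codewords attaining it.
// [[Rcpp::export]]
List cpp_decode_exhaustive(const IntegerVector& received, const IntegerMatrix& G) {
  const int k = G.nrow(), n = G.ncol();
  if (k > 24) stop("exhaustive decoding limited to k <= 24");
  if (received.size() != n) stop("received length != n");
  std::vector<BitRow> rows = pack_matrix(G);
  BitRow r = pack_vector(received);
  BitRow c(r.size(), 0), d(r.size(), 0);
  d = c;
  xor_row(d, r);
  int best = popcnt_row(d);
  uint64_t best_g = 0;
  int n_at_min = 1;
  uint64_t prev = 0;
  const uint64_t N = 1ULL << k;
  for (uint64_t i = 1; i < N; ++i) {
    uint64_t g = i ^ (i >> 1);
    uint64_t diff = g ^ prev;
    xor_row(c, rows[__builtin_ctzll(diff)]);
    prev = g;
    d = c;
    xor_row(d, r);
    int w = popcnt_row(d);
    if (w < best) { best = w; best_g = g; n_at_min = 1; }
    else if (w == best) ++n_at_min;
  }
  return List::create(_["message"] = gray_to_bits(best_g, k),
                      _["distance"] = best,
                      _["n_at_min"] = n_at_min);
}

// Information-set decoding: sample k columns forming an invertible
// submatrix, recover the message they imply, accept the first codeword
// within Hamming distance t of the received word. Tracks the best
// candidate seen for reporting when no codeword within t is found.
// [[Rcpp::export]]
List cpp_decode_isd(const IntegerVector& received, const IntegerMatrix& G,
                    int t, int iters) {
  const int k = G.nrow(), n = G.ncol();
  if (received.size() != n) stop("received length != n");
  std::vector<BitRow> Grows = pack_matrix(G);
  BitRow r = pack_vector(received);
  const int kW = (k + 63) / 64;
  std::vector<int> pool(n), cols(k);
  std::vector<BitRow> A(k), Inv(k);
  BitRow m(kW), c(r.size()), d(r.size());
  int best = n + 1;
  BitRow best_m(kW, 0);
  int tried = 0;
  for (int it = 0; it < iters; ++it) {
    sample_columns(n, k, pool, cols);
    // A[i] = bits of G restricted to the selected columns
    for (int i = 0; i < k; ++i) {
      A[i].assign(kW, 0);
      Inv[i].assign(kW, 0);
      set_bit(Inv[i], i);
      for (int j = 0; j < k; ++j)
        if (get_bit(Grows[i], cols[j])) set_bit(A[i], j);
    }
    // Gauss-Jordan inversion over GF(2)
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int piv = -1;
      for (int i = j; i < k; ++i)
        if (get_bit(A[i], j)) { piv = i; break; }
      if (piv < 0) { ok = false; break; }
      std::swap(A[j], A[piv]);
      std::swap(Inv[j], Inv[piv]);
      for (int i = 0; i < k; ++i)
        if (i != j && get_bit(A[i], j)) {
          xor_row(A[i], A[j]);
          xor_row(Inv[i], Inv[j]);
        }
    }
    if (!ok) continue;
    ++tried;
    // m = r_I * A^{-1} = XOR of Inv rows where the received bit is 1
    std::fill(m.begin(), m.end(), 0);
    for (int i = 0; i < k; ++i)
      if (get_bit(r, cols[i])) xor_row(m, Inv[i]);
    // c = m * G
    std::fill(c.begin(), c.end(), 0);
    for (int i = 0; i < k; ++i)
      if (get_bit(m, i)) xor_row(c, Grows[i]);
    d = c;
    xor_row(d, r);
    int w = popcnt_row(d);
    if (w < best) { best = w; best_m = m; }
    if (w <= t) break;
  }
  IntegerVector msg(k);
  for (int i = 0; i < k; ++i) msg[i] = get_bit(best_m, i) ? 1 : 0;
  return List::create(_["message"] = msg,
                      _["distance"] = best,
                      _["candidates_tried"] = tried,
                      _["found"] = best <= t);
}
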