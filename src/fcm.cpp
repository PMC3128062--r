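// Core engine: order-k finite-context models over the 2-bit DNA alphabet,
// inverted-repeat-aware count updates, block-wise competition among model
// orders, the adaptive side-channel model for the depth indices, and a
// binary arithmetic (CACM-style) coder driven by the same estimates.
//
// Symbol codes: A=0, C=1, G=2, T=3; complement(x) = 3-x.
// Packed context: last k codes, most recent symbol in the lowest 2 bits.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// count storage + estimator

struct FCM {
  int k;
  double alpha;
  uint64_t mask;
  bool dense;
  std::vector<uint64_t> tab;  // dense: 4 counters per context, context-major
  std::unordered_map<uint64_t, std::array<uint64_t, 4>> hash;
  uint64_t ctx = 0;           // warm-up context: all-A (packed 0)

  FCM(int k_, double alpha_, int hash_threshold)
      : k(k_), alpha(alpha_) {
    if (k < 1 || k > 24) stop("model order k must be in [1, 24]");
    if (alpha <= 0) stop("alpha must be > 0");
    mask = ((uint64_t)1 << (2 * k)) - 1;
    dense = (k <= hash_threshold);
    if (dense) tab.assign((size_t)1 << (2 * k + 2), 0);
  }

  inline void counts(uint64_t c, uint64_t out[4]) const {
    if (dense) {
      const uint64_t *p = &tab[(size_t)c << 2];
      out[0] = p[0]; out[1] = p[1]; out[2] = p[2]; out[3] = p[3];
    } else {
      auto it = hash.find(c);
      if (it == hash.end()) { out[0] = out[1] = out[2] = out[3] = 0; }
      else { const auto &a = it->second; out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; out[3]=a[3]; }
    }
  }

  // Eq-style estimator: p(s|c) = (n(s|c) + alpha) / (N(c) + 4 alpha)
  inline void probs(uint64_t c, double p[4]) const {
    uint64_t n[4];
    counts(c, n);
    double N = (double)(n[0] + n[1] + n[2] + n[3]);
    double denom = N + 4.0 * alpha;
    for (int s = 0; s < 4; ++s) p[s] = ((double)n[s] + alpha) / denom;
  }

  inline void add(uint64_t c, int s) {
    if (dense) tab[((size_t)c << 2) + s] += 1;
    else hash[c][s] += 1;  // operator[] value-initialises the array to zeros
  }

  inline uint64_t shift(uint64_t c, int s) const {
    return ((c << 2) | (uint64_t)s) & mask;
  }
};

// Inverted-repeat counterpart: with w = context.symbol (k+1 symbols, oldest
// first), the counterpart is (prefix, last) of reverse-complement(w).
static inline void ir_pair(uint64_t c, int s, int k, uint64_t &c2, int &s2) {
  int w[32];
  for (int i = 0; i < k; ++i) w[i] = (int)((c >> (2 * (k - 1 - i))) & 3);
  w[k] = s;
  c2 = 0;
  for (int i = 0; i < k; ++i) c2 = (c2 << 2) | (uint64_t)(3 - w[k - i]);
  s2 = 3 - w[0];
}

static inline void fcm_update_one(FCM &m, int s, bool use_ir) {
  uint64_t c = m.ctx;
  m.add(c, s);
  if (use_ir) {
    uint64_t c2; int s2;
    ir_pair(c, s, m.k, c2, s2);
    m.add(c2, s2);  // palindromic coincidence double-increments by design
  }
  m.ctx = m.shift(c, s);
}

// ---------------------------------------------------------------------------
// side-channel model: adaptive order-`order` FCM over the index alphabet {0..D-1}

struct SideModel {
  int D, order;
  double alpha;
  uint64_t nctx;
  std::vector<uint64_t> tab;
  uint64_t ctx = 0;  // warm-up: index 0 repeated

  SideModel(int D_, int order_, double alpha_) : D(D_), order(order_), alpha(alpha_) {
    if (D < 1) stop("side model needs >= 1 symbol");
    if (alpha <= 0) stop("side_alpha must be > 0");
    nctx = 1;
    for (int i = 0; i < order; ++i) nctx *= (uint64_t)D;
    tab.assign((size_t)nctx * D, 0);
  }
  inline void probs(std::vector<double> &p) const {
    const uint64_t *row = &tab[(size_t)ctx * D];
    uint64_t N = 0;
    for (int j = 0; j < D; ++j) N += row[j];
    double denom = (double)N + D * alpha;
    for (int j = 0; j < D; ++j) p[j] = ((double)row[j] + alpha) / denom;
  }
  inline void add_and_shift(int j) {
    tab[(size_t)ctx * D + j] += 1;
    ctx = (ctx * D + (uint64_t)j) % nctx;
  }
};

static double side_bits_of(const std::vector<int> &choices, int D, int order, double alpha) {
  SideModel sm(D, order, alpha);
  std::vector<double> p(D);
  double bits = 0.0;
  for (int c : choices) {
    sm.probs(p);
    bits += -std::log2(p[c]);
    sm.add_and_shift(c);
  }
  return bits;
}

// ---------------------------------------------------------------------------
// competition engine

struct EngineCfg {
  std::vector<int> depths;
  std::vector<double> alphas;
  int block_size;
  int side_order;
  double side_alpha;
  bool use_ir;
  int hash_threshold;
};

static EngineCfg make_cfg(const IntegerVector &depths, const NumericVector &alphas,
                          int block_size, int side_order, double side_alpha,
                          bool use_ir, int hash_threshold) {
  EngineCfg cfg;
  if (depths.size() == 0) stop("at least one model depth is required");
  if ((int)alphas.size() != (int)depths.size()) stop("alphas must match depths");
  if (block_size < 1) stop("block_size must be >= 1");
  if (side_order < 0) stop("side_order must be >= 0");
  cfg.depths.assign(depths.begin(), depths.end());
  cfg.alphas.assign(alphas.begin(), alphas.end());
  for (size_t i = 1; i < cfg.depths.size(); ++i)
    if (cfg.depths[i] <= cfg.depths[i - 1]) stop("depths must be strictly increasing");
  cfg.block_size = block_size;
  cfg.side_order = side_order;
  cfg.side_alpha = side_alpha;
  cfg.use_ir = use_ir;
  cfg.hash_threshold = hash_threshold;
  return cfg;
}

struct MultiResult {
  std::vector<int> chosen;          // per block, 0-based index into depths
  std::vector<double> profile;      // per symbol, bits of the winning model
  std::vector<double> block_costs;  // n_blocks x M, row-major
  std::vector<int> block_len;
  double symbol_bits = 0.0, side_bits = 0.0;
};

static void check_codes(const int *x, R_xlen_t n) {
  for (R_xlen_t i = 0; i < n; ++i)
    if (x[i] < 0 || x[i] > 3) stop("symbol codes must be integers in 0..3");
}

static MultiResult engine_multi(const int *x, R_xlen_t n, const EngineCfg &cfg,
                                bool keep_costs) {
  int M = (int)cfg.depths.size();
  std::vector<FCM> models;
  models.reserve(M);
  for (int m = 0; m < M; ++m)
    models.emplace_back(cfg.depths[m], cfg.alphas[m], cfg.hash_threshold);

  MultiResult res;
  res.profile.resize(n);
  std::vector<double> bcost(M);
  std::vector<double> bbits((size_t)M * cfg.block_size);
  double p[4];

  R_xlen_t pos = 0;
  while (pos < n) {
    R_xlen_t blen = std::min((R_xlen_t)cfg.block_size, n - pos);
    std::fill(bcost.begin(), bcost.end(), 0.0);
    for (R_xlen_t j = 0; j < blen; ++j) {
      int s = x[pos + j];
      for (int m = 0; m < M; ++m) {
        models[m].probs(models[m].ctx, p);
        double bits = -std::log2(p[s]);
        bcost[m] += bits;
        bbits[(size_t)m * cfg.block_size + j] = bits;
      }
      // every model's counters advance regardless of which one wins
      for (int m = 0; m < M; ++m) fcm_update_one(models[m], s, cfg.use_ir);
    }
    int best = 0;  // strict < keeps the lowest depth on ties
    for (int m = 1; m < M; ++m)
      if (bcost[m] < bcost[best]) best = m;
    res.chosen.push_back(best);
    res.block_len.push_back((int)blen);
    for (R_xlen_t j = 0; j < blen; ++j)
      res.profile[pos + j] = bbits[(size_t)best * cfg.block_size + j];
    res.symbol_bits += bcost[best];
    if (keep_costs)
      for (int m = 0; m < M; ++m) res.block_costs.push_back(bcost[m]);
    pos += blen;
  }
  res.side_bits = side_bits_of(res.chosen, M, cfg.side_order, cfg.side_alpha);
  return res;
}

// [[Rcpp::export]]
List cpp_run_multi(IntegerVector codes, IntegerVector depths, NumericVector alphas,
                   int block_size, int side_order, double side_alpha,
                   bool use_ir, int hash_threshold, bool keep_costs) {
  EngineCfg cfg = make_cfg(depths, alphas, block_size, side_order, side_alpha,
                           use_ir, hash_threshold);
  R_xlen_t n = codes.size();
  check_codes(codes.begin(), n);
  MultiResult r = engine_multi(codes.begin(), n, cfg, keep_costs);

  int M = (int)cfg.depths.size();
  int nb = (int)r.chosen.size();
  NumericMatrix costs(keep_costs ? nb : 0, keep_costs ? M : 0);
  if (keep_costs)
    for (int b = 0; b < nb; ++b)
      for (int m = 0; m < M; ++m) costs(b, m) = r.block_costs[(size_t)b * M + m];
  return List::create(
      _["profile"] = NumericVector(r.profile.begin(), r.profile.end()),
      _["chosen"] = IntegerVector(r.chosen.begin(), r.chosen.end()),
      _["block_len"] = IntegerVector(r.block_len.begin(), r.block_len.end()),
      _["block_costs"] = costs,
      _["symbol_bits"] = r.symbol_bits,
      _["side_bits"] = r.side_bits);
}

// [[Rcpp::export]]
List cpp_run_single(IntegerVector codes, int k, double alpha, bool use_ir,
                    int hash_threshold) {
  R_xlen_t n = codes.size();
  check_codes(codes.begin(), n);
  FCM m(k, alpha, hash_threshold);
  NumericVector prof(n);
  double total = 0.0, p[4];
  for (R_xlen_t i = 0; i < n; ++i) {
    int s = codes[i];
    m.probs(m.ctx, p);
    double bits = -std::log2(p[s]);
    prof[i] = bits;
    total += bits;
    fcm_update_one(m, s, use_ir);
  }
  return List::create(_["profile"] = prof, _["symbol_bits"] = total);
}

// [[Rcpp::export]]
double cpp_side_bits(IntegerVector choices, int n_symbols, int order, double alpha) {
  std::vector<int> ch(choices.begin(), choices.end());
  for (int c : ch)
    if (c < 0 || c >= n_symbols) stop("choice index out of range");
  return side_bits_of(ch, n_symbols, order, alpha);
}

// ---------------------------------------------------------------------------
// low-level model handle (worked examples, unit tests)

static uint64_t pack_ctx(const IntegerVector &v) {
  uint64_t c = 0;
  for (int x : v) {
    if (x < 0 || x > 3) stop("context codes must be in 0..3");
    c = (c << 2) | (uint64_t)x;
  }
  return c;
}

// [[Rcpp::export]]
SEXP cpp_fcm_create(int k, double alpha, int hash_threshold) {
  XPtr<FCM> ptr(new FCM(k, alpha, hash_threshold), true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector cpp_fcm_counts(SEXP xp, IntegerVector ctx) {
  XPtr<FCM> m(xp);
  if ((int)ctx.size() != m->k) stop("context length must equal model order");
  uint64_t n[4];
  m->counts(pack_ctx(ctx), n);
  return NumericVector::create((double)n[0], (double)n[1], (double)n[2], (double)n[3]);
}

// [[Rcpp::export]]
NumericVector cpp_fcm_probs(SEXP xp, IntegerVector ctx) {
  XPtr<FCM> m(xp);
  if ((int)ctx.size() != m->k) stop("context length must equal model order");
  double p[4];
  m->probs(pack_ctx(ctx), p);
  return NumericVector::create(p[0], p[1], p[2], p[3]);
}

// [[Rcpp::export]]
void cpp_fcm_set_counts(SEXP xp, IntegerVector ctx, NumericVector counts) {
  XPtr<FCM> m(xp);
  if ((int)ctx.size() != m->k) stop("context length must equal model order");
  if (counts.size() != 4) stop("counts must have length 4");
  uint64_t c = pack_ctx(ctx);
  for (int s = 0; s < 4; ++s) {
    if (counts[s] < 0) stop("counts must be non-negative");
    uint64_t v = (uint64_t)counts[s];
    if (m->dense) m->tab[((size_t)c << 2) + s] = v;
    else m->hash[c][s] = v;
  }
}

// [[Rcpp::export]]
void cpp_fcm_update(SEXP xp, IntegerVector ctx, int s, bool use_ir) {
  XPtr<FCM> m(xp);
  if ((int)ctx.size() != m->k) stop("context length must equal model order");
  if (s < 0 || s > 3) stop("symbol code must be in 0..3");
  uint64_t c = pack_ctx(ctx);
  m->add(c, s);
  if (use_ir) {
    uint64_t c2; int s2;
    ir_pair(c, s, m->k, c2, s2);
    m->add(c2, s2);
  }
}

// [[Rcpp::export]]
List cpp_ir_counterpart(IntegerVector ctx, int s) {
  int k = (int)ctx.size();
  if (k < 1 || k > 24) stop("context length must be in [1, 24]");
  if (s < 0 || s > 3) stop("symbol code must be in 0..3");
  uint64_t c2; int s2;
  ir_pair(pack_ctx(ctx), s, k, c2, s2);
  IntegerVector out(k);
  for (int i = 0; i < k; ++i) out[i] = (int)((c2 >> (2 * (k - 1 - i))) & 3);
  return List::create(_["context"] = out, _["symbol"] = s2);
}

// [[Rcpp::export]]
double cpp_pack_context(IntegerVector ctx) {
  return (double)pack_ctx(ctx);  // exact below 2^53, i.e. k <= 24
}

// ---------------------------------------------------------------------------
// arithmetic coder (binary, CACM-style, 32-bit state, 16-bit totals)

static const uint64_t AC_TOP = 0xFFFFFFFFull;
static const uint64_t AC_HALF = 0x80000000ull;
static const uint64_t AC_QTR = 0x40000000ull;
static const uint64_t AC_3QTR = 0xC0000000ull;
static const uint32_t FREQ_TOT = 1u << 16;

struct BitWriter {
  std::vector<uint8_t> bytes;
  uint64_t nbits = 0;
  inline void put(int b) {
    if ((nbits & 7) == 0) bytes.push_back(0);
    if (b) bytes.back() |= (uint8_t)(1u << (7 - (nbits & 7)));
    ++nbits;
  }
};

struct BitReader {
  const uint8_t *p;
  uint64_t nbits, pos = 0;
  BitReader(const uint8_t *p_, uint64_t nbytes) : p(p_), nbits(nbytes * 8) {}
  inline int get() {
    if (pos >= nbits) { ++pos; return 0; }  // zero-padding past the end
    int b = (p[pos >> 3] >> (7 - (pos & 7))) & 1;
    ++pos;
    return b;
  }
};

struct ACEncoder {
  uint64_t low = 0, high = AC_TOP, pending = 0;
  BitWriter bw;
  inline void emit(int b) {
    bw.put(b);
    while (pending) { bw.put(!b); --pending; }
  }
  void encode(uint32_t clo, uint32_t chi, uint32_t tot) {
    uint64_t range = high - low + 1;
    high = low + (range * chi) / tot - 1;
    low = low + (range * clo) / tot;
    for (;;) {
      if (high < AC_HALF) emit(0);
      else if (low >= AC_HALF) { emit(1); low -= AC_HALF; high -= AC_HALF; }
      else if (low >= AC_QTR && high < AC_3QTR) { ++pending; low -= AC_QTR; high -= AC_QTR; }
      else break;
      low <<= 1;
      high = (high << 1) | 1;
    }
  }
  void finish() {
    ++pending;
    emit(low < AC_QTR ? 0 : 1);
  }
};

struct ACDecoder {
  uint64_t low = 0, high = AC_TOP, value = 0;
  BitReader br;
  ACDecoder(const uint8_t *p, uint64_t nbytes) : br(p, nbytes) {
    for (int i = 0; i < 32; ++i) value = (value << 1) | (uint64_t)br.get();
  }
  uint32_t target(uint32_t tot) {
    uint64_t range = high - low + 1;
    return (uint32_t)(((value - low + 1) * tot - 1) / range);
  }
  void consume(uint32_t clo, uint32_t chi, uint32_t tot) {
    uint64_t range = high - low + 1;
    high = low + (range * chi) / tot - 1;
    low = low + (range * clo) / tot;
    for (;;) {
      if (high < AC_HALF) { /* nothing */ }
      else if (low >= AC_HALF) { low -= AC_HALF; high -= AC_HALF; value -= AC_HALF; }
      else if (low >= AC_QTR && high < AC_3QTR) { low -= AC_QTR; high -= AC_QTR; value -= AC_QTR; }
      else break;
      low <<= 1;
      high = (high << 1) | 1;
      value = (value << 1) | (uint64_t)br.get();
    }
  }
};

// Deterministic quantisation of a probability vector to integer frequencies
// summing exactly to FREQ_TOT, each >= 1; shared by encoder and decoder.
static void quantize(const double *p, int n, uint32_t *f) {
  uint64_t sum = 0;
  for (int i = 0; i < n; ++i) {
    long long v = std::llround(p[i] * (double)(FREQ_TOT - n));
    f[i] = (v < 1) ? 1u : (uint32_t)v;
    sum += f[i];
  }
  int imax = 0;
  for (int i = 1; i < n; ++i)
    if (f[i] > f[imax]) imax = i;
  f[imax] = (uint32_t)((int64_t)f[imax] + ((int64_t)FREQ_TOT - (int64_t)sum));
}

static void cum_of(const uint32_t *f, int sym, uint32_t &clo, uint32_t &chi) {
  clo = 0;
  for (int i = 0; i < sym; ++i) clo += f[i];
  chi = clo + f[sym];
}

// [[Rcpp::export]]
List cpp_encode(IntegerVector codes, IntegerVector depths, NumericVector alphas,
                int block_size, int side_order, double side_alpha,
                bool use_ir, int hash_threshold) {
  EngineCfg cfg = make_cfg(depths, alphas, block_size, side_order, side_alpha,
                           use_ir, hash_threshold);
  R_xlen_t n = codes.size();
  check_codes(codes.begin(), n);
  // pass 1: block winners from ideal (double) code lengths
  MultiResult eng = engine_multi(codes.begin(), n, cfg, false);

  // pass 2: replay with fresh models, coding depth index then block symbols
  int M = (int)cfg.depths.size();
  std::vector<FCM> models;
  models.reserve(M);
  for (int m = 0; m < M; ++m)
    models.emplace_back(cfg.depths[m], cfg.alphas[m], cfg.hash_threshold);
  SideModel side(M, cfg.side_order, cfg.side_alpha);
  std::vector<double> ps(M);
  std::vector<uint32_t> fs(M);
  ACEncoder enc;
  double p[4];
  uint32_t f4[4], clo, chi;

  R_xlen_t pos = 0;
  size_t bi = 0;
  while (pos < n) {
    int choice = eng.chosen[bi];
    side.probs(ps);
    quantize(ps.data(), M, fs.data());
    cum_of(fs.data(), choice, clo, chi);
    enc.encode(clo, chi, FREQ_TOT);
    side.add_and_shift(choice);

    R_xlen_t blen = std::min((R_xlen_t)cfg.block_size, n - pos);
    FCM &w = models[choice];
    for (R_xlen_t j = 0; j < blen; ++j) {
      int s = codes[pos + j];
      w.probs(w.ctx, p);
      quantize(p, 4, f4);
      cum_of(f4, s, clo, chi);
      enc.encode(clo, chi, FREQ_TOT);
      for (int m = 0; m < M; ++m) fcm_update_one(models[m], s, cfg.use_ir);
    }
    pos += blen;
    ++bi;
  }
  if (n > 0) enc.finish();

  RawVector payload(enc.bw.bytes.size());
  std::copy(enc.bw.bytes.begin(), enc.bw.bytes.end(), payload.begin());
  return List::create(
      _["payload"] = payload,
      _["payload_bits"] = (double)enc.bw.nbits,
      _["chosen"] = IntegerVector(eng.chosen.begin(), eng.chosen.end()),
      _["symbol_bits"] = eng.symbol_bits,
      _["side_bits"] = eng.side_bits);
}

// [[Rcpp::export]]
IntegerVector cpp_decode(RawVector payload, double n_symbols, IntegerVector depths,
                         NumericVector alphas, int block_size, int side_order,
                         double side_alpha, bool use_ir, int hash_threshold) {
  EngineCfg cfg = make_cfg(depths, alphas, block_size, side_order, side_alpha,
                           use_ir, hash_threshold);
  R_xlen_t n = (R_xlen_t)n_symbols;
  IntegerVector out(n);
  if (n == 0) return out;

  int M = (int)cfg.depths.size();
  std::vector<FCM> models;
  models.reserve(M);
  for (int m = 0; m < M; ++m)
    models.emplace_back(cfg.depths[m], cfg.alphas[m], cfg.hash_threshold);
  SideModel side(M, cfg.side_order, cfg.side_alpha);
  std::vector<double> ps(M);
  std::vector<uint32_t> fs(M);
  ACDecoder dec((const uint8_t *)RAW(payload), (uint64_t)payload.size());
  double p[4];
  uint32_t f4[4], clo, chi;

  R_xlen_t pos = 0;
  while (pos < n) {
    side.probs(ps);
    quantize(ps.data(), M, fs.data());
    uint32_t t = dec.target(FREQ_TOT);
    int choice = 0;
    {
      uint32_t acc = 0;
      while (choice < M - 1 && acc + fs[choice] <= t) { acc += fs[choice]; ++choice; }
      clo = acc; chi = acc + fs[choice];
    }
    dec.consume(clo, chi, FREQ_TOT);
    side.add_and_shift(choice);

    R_xlen_t blen = std::min((R_xlen_t)cfg.block_size, n - pos);
    FCM &w = models[choice];
    for (R_xlen_t j = 0; j < blen; ++j) {
      w.probs(w.ctx, p);
      quantize(p, 4, f4);
      uint32_t tt = dec.target(FREQ_TOT);
      int s = 0;
      uint32_t acc = 0;
      while (s < 3 && acc + f4[s] <= tt) { acc += f4[s]; ++s; }
      clo = acc; chi = acc + f4[s];
      dec.consume(clo, chi, FREQ_TOT);
      out[pos + j] = s;
      for (int m = 0; m < M; ++m) fcm_update_one(models[m], s, cfg.use_ir);
    }
    pos += blen;
  }
  return out;
}

// ---------------------------------------------------------------------------
// FNV-1a 32-bit checksum for container integrity

// [[Rcpp::export]]
double cpp_fnv1a(RawVector bytes) {
  uint32_t h = 2166136261u;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint32_t)bytes[i];
    h *= 16777619u;
  }
  return (double)h;
}
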