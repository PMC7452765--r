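// k-mer membership core: Bloom filter, cascading Bloom filter, exact counter.
// All sequence-level entry points canonicalize windows (lexicographic min of
// window and reverse complement); windows with non-ACGT characters are skipped.
// Single-k-mer entry points take the string verbatim so callers control
// canonicalization.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---- hashing ---------------------------------------------------------------

// FNV-1a 64-bit with a splitmix64 finalizer; two seeds give the two base
// hashes for double hashing h_i = (h1 + i*h2) mod m.
static inline uint64_t mix64(uint64_t h) {
  h ^= h >> 33;
  h *= 0xff51afd7ed558ccdULL;
  h ^= h >> 33;
  h *= 0xc4ceb9fe1a85ec53ULL;
  h ^= h >> 33;
  return h;
}

static inline uint64_t fnv1a64(const char* s, size_t n, uint64_t seed) {
  uint64_t h = seed;
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return mix64(h);
}

static const uint64_t SEED1 = 14695981039346656037ULL;
static const uint64_t SEED2 = 0x9E3779B97F4A7C15ULL;

// ---- canonicalization ------------------------------------------------------

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 0;
  }
}

static inline char upbase(char c) {
  if (c >= 'a' && c <= 'z') return c - 32;
  return c;
}

// Writes the canonical form of seq[p..p+k) into out; returns false if the
// window contains a non-ACGT character.
static bool canonical_window(const std::string& seq, size_t p, int k,
                             std::string& out) {
  out.resize(k);
  std::string rc(k, 'N');
  for (int i = 0; i < k; ++i) {
    char c = upbase(seq[p + i]);
    char cc = comp(c);
    if (!cc) return false;
    out[i] = c;
    rc[k - 1 - i] = cc;
  }
  if (rc < out) out.swap(rc);
  return true;
}

// [[Rcpp::export]]
List cpp_canonical_kmers(std::string seq, int k) {
  std::vector<int> pos;
  std::vector<std::string> kmers;
  if (k >= 1 && (int)seq.size() >= k) {
    std::string buf;
    for (size_t p = 0; p + k <= seq.size(); ++p) {
      if (canonical_window(seq, p, k, buf)) {
        pos.push_back((int)p);
        kmers.push_back(buf);
      }
    }
  }
  return List::create(_["pos"] = wrap(pos), _["kmer"] = wrap(kmers));
}

// ---- Bloom filter ----------------------------------------------------------

struct BloomFilter {
  int k;
  uint64_t m;  // bits
  int h;
  uint64_t n_inserted;
  std::vector<uint64_t> words;

  BloomFilter(int k_, uint64_t m_, int h_)
      : k(k_), m(m_), h(h_), n_inserted(0), words((m_ + 63) / 64, 0ULL) {}

  inline void probe(const std::string& kmer, uint64_t* idx) const {
    uint64_t h1 = fnv1a64(kmer.data(), kmer.size(), SEED1);
    uint64_t h2 = fnv1a64(kmer.data(), kmer.size(), SEED2) | 1ULL;
    for (int i = 0; i < h; ++i) idx[i] = (h1 + (uint64_t)i * h2) % m;
  }
  inline void insert(const std::string& kmer) {
    uint64_t idx[64];
    probe(kmer, idx);
    for (int i = 0; i < h; ++i) words[idx[i] >> 6] |= 1ULL << (idx[i] & 63);
    ++n_inserted;
  }
  inline bool contains(const std::string& kmer) const {
    uint64_t idx[64];
    probe(kmer, idx);
    for (int i = 0; i < h; ++i)
      if (!(words[idx[i] >> 6] & (1ULL << (idx[i] & 63)))) return false;
    return true;
  }
};

struct CascadeFilter {
  int k;
  uint64_t m;  // bits per level
  int h;
  std::vector<BloomFilter> levels;

  CascadeFilter(int k_, uint64_t m_, int h_, int L) : k(k_), m(m_), h(h_) {
    for (int i = 0; i < L; ++i) levels.emplace_back(k_, m_, h_);
  }
  // insert into the first level that does not already contain the k-mer
  inline void insert(const std::string& kmer) {
    for (auto& lv : levels) {
      if (!lv.contains(kmer)) {
        lv.insert(kmer);
        return;
      }
    }
  }
  inline bool solid(const std::string& kmer) const {
    return levels.back().contains(kmer);
  }
};

struct ExactCounter {
  int k;
  int levels;  // solidity threshold: count >= levels
  std::unordered_map<std::string, uint32_t> counts;
  ExactCounter(int k_, int L) : k(k_), levels(L) {}
};

static void check_k(int want, const std::string& kmer) {
  if ((int)kmer.size() != want)
    stop("k-mer length %d does not match filter k = %d", (int)kmer.size(),
         want);
}

// ---- Bloom filter API ------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_bf_new(int k, double m, int h) {
  if (k < 1 || m < 1 || h < 1) stop("require k >= 1, m >= 1, h >= 1");
  return XPtr<BloomFilter>(new BloomFilter(k, (uint64_t)m, h));
}

// [[Rcpp::export]]
void cpp_bf_insert(SEXP ptr, CharacterVector kmers) {
  XPtr<BloomFilter> f(ptr);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    check_k(f->k, s);
    f->insert(s);
  }
}

// [[Rcpp::export]]
LogicalVector cpp_bf_contains(SEXP ptr, CharacterVector kmers) {
  XPtr<BloomFilter> f(ptr);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    check_k(f->k, s);
    out[i] = f->contains(s);
  }
  return out;
}

// insert every canonical k-mer of every sequence; returns insert calls made
// [[Rcpp::export]]
double cpp_bf_insert_seqs(SEXP ptr, CharacterVector seqs) {
  XPtr<BloomFilter> f(ptr);
  std::string buf;
  double n = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < f->k) continue;
    for (size_t p = 0; p + f->k <= s.size(); ++p) {
      if (canonical_window(s, p, f->k, buf)) {
        f->insert(buf);
        ++n;
      }
    }
  }
  return n;
}

// per sequence, number of canonical k-mers found in the filter
// [[Rcpp::export]]
IntegerVector cpp_bf_shared_counts(SEXP ptr, CharacterVector seqs) {
  XPtr<BloomFilter> f(ptr);
  IntegerVector out(seqs.size());
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int n = 0;
    if ((int)s.size() >= f->k) {
      for (size_t p = 0; p + f->k <= s.size(); ++p)
        if (canonical_window(s, p, f->k, buf) && f->contains(buf)) ++n;
    }
    out[i] = n;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bf_info(SEXP ptr) {
  XPtr<BloomFilter> f(ptr);
  return List::create(_["k"] = f->k, _["m"] = (double)f->m, _["h"] = f->h,
                      _["n_inserted"] = (double)f->n_inserted);
}

// [[Rcpp::export]]
RawVector cpp_bf_bits(SEXP ptr) {
  XPtr<BloomFilter> f(ptr);
  uint64_t nbytes = (f->m + 7) / 8;
  RawVector out(nbytes);
  for (uint64_t b = 0; b < nbytes; ++b)
    out[b] = (Rbyte)((f->words[b >> 3] >> ((b & 7) * 8)) & 0xFF);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_bf_from_bits(int k, double m, int h, double n_inserted,
                      RawVector bits) {
  BloomFilter* f = new BloomFilter(k, (uint64_t)m, h);
  f->n_inserted = (uint64_t)n_inserted;
  uint64_t nbytes = (f->m + 7) / 8;
  if ((uint64_t)bits.size() != nbytes) {
    delete f;
    stop("bit array has %d bytes, expected %d", (int)bits.size(), (int)nbytes);
  }
  for (uint64_t b = 0; b < nbytes; ++b)
    f->words[b >> 3] |= ((uint64_t)(Rbyte)bits[b]) << ((b & 7) * 8);
  return XPtr<BloomFilter>(f);
}

// ---- cascading filter API --------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_cbf_new(int k, double m_per_level, int h, int levels) {
  if (levels < 1) stop("require levels >= 1");
  if (k < 1 || m_per_level < 1 || h < 1) stop("require k >= 1, m >= 1, h >= 1");
  return XPtr<CascadeFilter>(
      new CascadeFilter(k, (uint64_t)m_per_level, h, levels));
}

// [[Rcpp::export]]
void cpp_cbf_insert(SEXP ptr, CharacterVector kmers) {
  XPtr<CascadeFilter> c(ptr);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    check_k(c->k, s);
    c->insert(s);
  }
}

// [[Rcpp::export]]
void cpp_cbf_insert_seqs(SEXP ptr, CharacterVector seqs) {
  XPtr<CascadeFilter> c(ptr);
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < c->k) continue;
    for (size_t p = 0; p + c->k <= s.size(); ++p)
      if (canonical_window(s, p, c->k, buf)) c->insert(buf);
  }
}

// [[Rcpp::export]]
LogicalVector cpp_cbf_contains_level(SEXP ptr, CharacterVector kmers,
                                     int level) {
  XPtr<CascadeFilter> c(ptr);
  if (level < 0 || level >= (int)c->levels.size()) stop("no such level");
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    check_k(c->k, s);
    out[i] = c->levels[level].contains(s);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_cbf_solid(SEXP ptr, CharacterVector kmers) {
  XPtr<CascadeFilter> c(ptr);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    check_k(c->k, s);
    out[i] = c->solid(s);
  }
  return out;
}

// solidity mask over the canonical k-mer windows of one sequence
// [[Rcpp::export]]
LogicalVector cpp_cbf_mask(SEXP ptr, std::string seq) {
  XPtr<CascadeFilter> c(ptr);
  if ((int)seq.size() < c->k) return LogicalVector(0);
  LogicalVector out(seq.size() - c->k + 1, false);
  std::string buf;
  for (size_t p = 0; p + c->k <= seq.size(); ++p)
    if (canonical_window(seq, p, c->k, buf)) out[p] = c->solid(buf);
  return out;
}

// [[Rcpp::export]]
List cpp_cbf_info(SEXP ptr) {
  XPtr<CascadeFilter> c(ptr);
  NumericVector n(c->levels.size());
  for (size_t i = 0; i < c->levels.size(); ++i)
    n[i] = (double)c->levels[i].n_inserted;
  return List::create(_["k"] = c->k, _["m_per_level"] = (double)c->m,
                      _["h"] = c->h, _["levels"] = (int)c->levels.size(),
                      _["n_inserted"] = n);
}

// [[Rcpp::export]]
RawVector cpp_cbf_level_bits(SEXP ptr, int level) {
  XPtr<CascadeFilter> c(ptr);
  if (level < 0 || level >= (int)c->levels.size()) stop("no such level");
  BloomFilter& f = c->levels[level];
  uint64_t nbytes = (f.m + 7) / 8;
  RawVector out(nbytes);
  for (uint64_t b = 0; b < nbytes; ++b)
    out[b] = (Rbyte)((f.words[b >> 3] >> ((b & 7) * 8)) & 0xFF);
  return out;
}

// [[Rcpp::export]]
void cpp_cbf_set_level(SEXP ptr, int level, double n_inserted,
                       RawVector bits) {
  XPtr<CascadeFilter> c(ptr);
  if (level < 0 || level >= (int)c->levels.size()) stop("no such level");
  BloomFilter& f = c->levels[level];
  uint64_t nbytes = (f.m + 7) / 8;
  if ((uint64_t)bits.size() != nbytes)
    stop("bit array has %d bytes, expected %d", (int)bits.size(), (int)nbytes);
  f.n_inserted = (uint64_t)n_inserted;
  std::fill(f.words.begin(), f.words.end(), 0ULL);
  for (uint64_t b = 0; b < nbytes; ++b)
    f.words[b >> 3] |= ((uint64_t)(Rbyte)bits[b]) << ((b & 7) * 8);
}

// ---- exact counter API -----------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_exact_new(int k, int levels) {
  if (k < 1 || levels < 1) stop("require k >= 1, levels >= 1");
  return XPtr<ExactCounter>(new ExactCounter(k, levels));
}

// [[Rcpp::export]]
void cpp_exact_insert(SEXP ptr, CharacterVector kmers) {
  XPtr<ExactCounter> e(ptr);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    check_k(e->k, s);
    ++e->counts[s];
  }
}

// [[Rcpp::export]]
void cpp_exact_insert_seqs(SEXP ptr, CharacterVector seqs) {
  XPtr<ExactCounter> e(ptr);
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < e->k) continue;
    for (size_t p = 0; p + e->k <= s.size(); ++p)
      if (canonical_window(s, p, e->k, buf)) ++e->counts[buf];
  }
}

// [[Rcpp::export]]
LogicalVector cpp_exact_solid(SEXP ptr, CharacterVector kmers) {
  XPtr<ExactCounter> e(ptr);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    check_k(e->k, s);
    auto it = e->counts.find(s);
    out[i] = it != e->counts.end() && it->second >= (uint32_t)e->levels;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_exact_count(SEXP ptr, CharacterVector kmers) {
  XPtr<ExactCounter> e(ptr);
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    check_k(e->k, s);
    auto it = e->counts.find(s);
    out[i] = it == e->counts.end() ? 0 : (int)it->second;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_exact_mask(SEXP ptr, std::string seq) {
  XPtr<ExactCounter> e(ptr);
  if ((int)seq.size() < e->k) return LogicalVector(0);
  LogicalVector out(seq.size() - e->k + 1, false);
  std::string buf;
  for (size_t p = 0; p + e->k <= seq.size(); ++p) {
    if (canonical_window(seq, p, e->k, buf)) {
      auto it = e->counts.find(buf);
      out[p] = it != e->counts.end() && it->second >= (uint32_t)e->levels;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_exact_info(SEXP ptr) {
  XPtr<ExactCounter> e(ptr);
  return List::create(_["k"] = e->k, _["levels"] = e->levels,
                      _["n_distinct"] = (double)e->counts.size());
}
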