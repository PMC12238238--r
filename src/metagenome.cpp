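#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <cstdint>
#include <cmath>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// ---- k-mer panel index -----------------------------------------------------

// Open-addressed k-mer table (linear probing) behind a small bit filter;
// value is the owning gene index, or -2 when the k-mer occurs in >1 gene.
struct PanelIndex {
    int k;
    std::vector<uint64_t> bloom;          // bit filter, 2^bloom_bits bits
    int bloom_bits;
    std::vector<uint64_t> keys;           // flat table, EMPTY = ~0
    std::vector<int> vals;
    uint64_t tab_mask;
    std::unordered_map<uint64_t, std::vector<int> > multi; // shared kmers
};

static const uint64_t EMPTY_KEY = ~uint64_t(0);

static inline int table_find(const PanelIndex &px, uint64_t key) {
    uint64_t h = (key * 0x9E3779B97F4A7C15ULL) >> 32;
    uint64_t i = h & px.tab_mask;
    while (true) {
        const uint64_t kk = px.keys[i];
        if (kk == key) return px.vals[i];
        if (kk == EMPTY_KEY) return -1;
        i = (i + 1) & px.tab_mask;
    }
}

static void table_insert(PanelIndex &px, uint64_t key, int g) {
    uint64_t h = (key * 0x9E3779B97F4A7C15ULL) >> 32;
    uint64_t i = h & px.tab_mask;
    while (true) {
        if (px.keys[i] == EMPTY_KEY) { px.keys[i] = key; px.vals[i] = g; return; }
        if (px.keys[i] == key) {
            int &v = px.vals[i];
            if (v == g) return;
            if (v >= 0) { px.multi[key] = std::vector<int>{v, g}; v = -2; }
            else {
                std::vector<int> &m = px.multi[key];
                if (std::find(m.begin(), m.end(), g) == m.end()) m.push_back(g);
            }
            return;
        }
        i = (i + 1) & px.tab_mask;
    }
}

static const signed char BASE_TAB[256] = {
    // -1 everywhere except A/C/G/T (upper+lower)
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1, 0,-1, 1,-1,-1,-1, 2,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1, 3,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1, 0,-1, 1,-1,-1,-1, 2,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1, 3,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1};

static inline int base_code(char c) { return BASE_TAB[(unsigned char)c]; }

static inline uint64_t bloom_hash(uint64_t x, int bits) {
    return (x * 0x9E3779B97F4A7C15ULL) >> (64 - bits);
}

// xoshiro256** -- internal PRNG for read simulation, seeded from R's RNG so
// that results are reproducible under set.seed().
struct Xoshiro {
    uint64_t s[4];
    explicit Xoshiro(uint64_t seed) {
        // splitmix64 expansion of the seed
        for (int i = 0; i < 4; ++i) {
            seed += 0x9E3779B97F4A7C15ULL;
            uint64_t z = seed;
            z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
            z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
    inline uint64_t next() {
        const uint64_t result = rotl(s[1] * 5, 7) * 9;
        const uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
        s[3] = rotl(s[3], 45);
        return result;
    }
    inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

static uint64_t rng_seed_from_R() {
    GetRNGstate();
    const uint64_t a = (uint64_t)std::floor(unif_rand() * 4294967296.0);
    const uint64_t b = (uint64_t)std::floor(unif_rand() * 4294967296.0);
    PutRNGstate();
    return (a << 32) ^ b;
}

static void index_panel(const std::vector<std::string> &panel, int k, PanelIndex &px) {
    px.k = k;
    px.bloom_bits = 18;
    px.bloom.assign((size_t(1) << px.bloom_bits) / 64, 0ULL);
    size_t nk = 0;
    for (const auto &s : panel) if ((int)s.size() >= k) nk += 2 * (s.size() - k + 1);
    size_t cap = 1024; while (cap < 4 * nk) cap <<= 1;
    px.keys.assign(cap, EMPTY_KEY);
    px.vals.assign(cap, -1);
    px.tab_mask = cap - 1;
    const uint64_t mask = (k < 32) ? ((uint64_t(1) << (2 * k)) - 1) : ~uint64_t(0);
    for (size_t g = 0; g < panel.size(); ++g) {
        const std::string &s = panel[g];
        if ((int)s.size() < k) continue;
        uint64_t fwd = 0, rc = 0; int valid = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            const int b = base_code(s[i]);
            if (b < 0) { valid = 0; fwd = 0; rc = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)b) & mask;
            rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
            if (++valid < k) continue;
            for (int o = 0; o < 2; ++o) {
                const uint64_t key = o ? rc : fwd;
                const uint64_t h = bloom_hash(key, px.bloom_bits);
                px.bloom[h >> 6] |= (uint64_t(1) << (h & 63));
                table_insert(px, key, (int)g);
                if (fwd == rc) break;
            }
        }
    }
}

// Stride-8 probe prefilter. A read with >= need matching windows whose
// matches fall in at most ceil(need/8) maximal runs must contain a run of
// >= 8 consecutive matching windows, and every such run covers a window
// index divisible by 8. Reads from the simulator with <= 4 substitution
// errors have <= 5 runs, so for the default theta the filter is exact for
// them; a read failing every probe cannot be assignable unless its matches
// are fragmented into more runs than that.
static bool probe_prefilter(const char *r, int len, const PanelIndex &px) {
    const int k = px.k;
    const int nw = len - k + 1;
    if (nw < 64) return true; // short reads: always do the full scan
    const uint64_t mask = (k < 32) ? ((uint64_t(1) << (2 * k)) - 1) : ~uint64_t(0);
    const uint64_t *bloom = px.bloom.data();
    const int bits = px.bloom_bits;
    uint64_t fwd = 0; int valid = 0;
    for (int i = 0; i < len; ++i) {
        const int b = base_code(r[i]);
        if (b < 0) { valid = 0; fwd = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        if (++valid < k) continue;
        const int widx = i - k + 1;
        if (widx & 7) continue; // probe every 8th window only
        const uint64_t h = bloom_hash(fwd, bits);
        if (__builtin_expect((bloom[h >> 6] >> (h & 63)) & 1, 0)) {
            if (table_find(px, fwd) != -1) return true;
        }
    }
    return false;
}

// Map one read: per-gene shared-kmer counts -> best gene if the shared
// fraction reaches theta and the argmax is unique; ties / below threshold
// are unassigned (-1). Returns gene index or -1; nw = n kmers in read.
static int map_one(const char *r, int len, const PanelIndex &px, double theta,
                   std::vector<int> &cnt, std::vector<int> &touched,
                   bool prefilter) {
    const int k = px.k;
    const int nw = len - k + 1;
    if (nw <= 0) return -1;
    if (prefilter && !probe_prefilter(r, len, px)) return -1;
    const int need = (int)std::ceil(theta * nw - 1e-9);
    const uint64_t mask = (k < 32) ? ((uint64_t(1) << (2 * k)) - 1) : ~uint64_t(0);
    uint64_t fwd = 0; int valid = 0, maxc = 0;
    const uint64_t *bloom = px.bloom.data();
    const int bits = px.bloom_bits;
    for (int i = 0; i < len; ++i) {
        const int b = base_code(r[i]);
        if (b < 0) { valid = 0; fwd = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        if (++valid < k) continue;
        const int widx = i - k + 1;           // 0-based window index
        const uint64_t h = bloom_hash(fwd, bits);
        if (bloom[h >> 6] & (uint64_t(1) << (h & 63))) {
            const int own = table_find(px, fwd);
            if (own >= 0) {
                if (cnt[own]++ == 0) touched.push_back(own);
                if (cnt[own] > maxc) maxc = cnt[own];
            } else if (own == -2) {
                const std::vector<int> &v = px.multi.at(fwd);
                for (int g : v) {
                    if (cnt[g]++ == 0) touched.push_back(g);
                    if (cnt[g] > maxc) maxc = cnt[g];
                }
            }
        }
        const int remaining = nw - widx - 1;  // windows after this one
        if (maxc + remaining < need) break;   // cannot reach threshold
    }
    int best = -1, bestc = 0; bool tie = false;
    for (int g : touched) {
        if (cnt[g] > bestc) { bestc = cnt[g]; best = g; tie = false; }
        else if (cnt[g] == bestc && cnt[g] > 0) tie = true;
    }
    for (int g : touched) cnt[g] = 0;
    touched.clear();
    if (best < 0 || tie || bestc < need) return -1;
    return best;
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector panel, int k,
                   double theta, bool prefilter) {
    std::vector<std::string> pv(panel.size());
    for (int i = 0; i < panel.size(); ++i) pv[i] = as<std::string>(panel[i]);
    PanelIndex px; index_panel(pv, k, px);
    std::vector<int> cnt(pv.size(), 0), touched;
    IntegerVector counts(panel.size());
    IntegerVector assign(reads.size());
    for (int i = 0; i < reads.size(); ++i) {
        const char *r = CHAR(STRING_ELT(reads, i));
        const int len = LENGTH(STRING_ELT(reads, i));
        if (len < k) stop("read %d is shorter than k = %d", i + 1, k);
        const int g = map_one(r, len, px, theta, cnt, touched, prefilter);
        assign[i] = g + 1; // 0 = unassigned, else 1-based panel index
        if (g >= 0) counts[g]++;
    }
    return List::create(_["counts"] = counts, _["assignment"] = assign);
}

// ---- read simulation -------------------------------------------------------

// Draw one read into buf; the RNG draw sequence is shared by cpp_sim_reads
// and cpp_sim_and_map so the two paths generate identical reads.
static void draw_read(const std::vector<std::string> &src,
                      const std::vector<double> &cum, int readLen,
                      double errProb, char *buf, Xoshiro &rng) {
    const double u = rng.unif();
    size_t s = 0;
    while (s + 1 < cum.size() && u > cum[s]) ++s;
    const std::string &seq = src[s];
    const int maxStart = (int)seq.size() - readLen; // inclusive, 0-based
    int pos = (int)std::floor(rng.unif() * (maxStart + 1));
    if (pos > maxStart) pos = maxStart;
    std::memcpy(buf, seq.data() + pos, readLen);
    if (errProb > 0) {
        static const char bases[4] = {'A', 'C', 'G', 'T'};
        const double lq = std::log1p(-errProb);
        int i = -1;
        while (true) {
            // geometric skip-sampling: exact i.i.d. per-base Bernoulli errors
            const double u2 = rng.unif();
            const int skip = (int)std::floor(std::log(u2) / lq);
            i += 1 + skip;
            if (i >= readLen || skip < 0) break;
            const int cur = base_code(buf[i]);
            int nb = (int)std::floor(rng.unif() * 3.0); if (nb > 2) nb = 2;
            // uniform choice among the three other bases
            buf[i] = bases[cur < 0 ? nb : (cur + 1 + nb) % 4];
        }
    }
}

// [[Rcpp::export]]
CharacterVector cpp_sim_reads(CharacterVector sources, NumericVector probs,
                              int n, int readLen, double errProb) {
    std::vector<std::string> src(sources.size());
    for (int i = 0; i < sources.size(); ++i) {
        src[i] = as<std::string>(sources[i]);
        if ((int)src[i].size() < readLen)
            stop("read length %d exceeds source sequence %d", readLen, i + 1);
    }
    std::vector<double> cum(probs.size());
    double t = 0; for (int i = 0; i < probs.size(); ++i) { t += probs[i]; cum[i] = t; }
    for (auto &c : cum) c /= t;
    CharacterVector out(n);
    std::vector<char> buf(readLen);
    Xoshiro rng(rng_seed_from_R());
    for (int i = 0; i < n; ++i) {
        draw_read(src, cum, readLen, errProb, buf.data(), rng);
        out[i] = Rf_mkCharLen(buf.data(), readLen);
    }
    return out;
}

// Fused generate-and-map path: identical RNG stream to cpp_sim_reads followed
// by cpp_map_reads, but without materialising the reads in R memory.
// [[Rcpp::export]]
List cpp_sim_and_map(CharacterVector sources, NumericVector probs, int n,
                     int readLen, double errProb, CharacterVector panel,
                     int k, double theta, bool prefilter) {
    std::vector<std::string> src(sources.size());
    for (int i = 0; i < sources.size(); ++i) {
        src[i] = as<std::string>(sources[i]);
        if ((int)src[i].size() < readLen)
            stop("read length %d exceeds source sequence %d", readLen, i + 1);
    }
    std::vector<double> cum(probs.size());
    double t = 0; for (int i = 0; i < probs.size(); ++i) { t += probs[i]; cum[i] = t; }
    for (auto &c : cum) c /= t;
    std::vector<std::string> pv(panel.size());
    for (int i = 0; i < panel.size(); ++i) pv[i] = as<std::string>(panel[i]);
    if (readLen < k) stop("reads are shorter than k = %d", k);
    PanelIndex px; index_panel(pv, k, px);
    std::vector<int> cnt(pv.size(), 0), touched;
    IntegerVector counts(panel.size());
    int unassigned = 0;
    std::vector<char> buf(readLen);
    Xoshiro rng(rng_seed_from_R());
    for (int i = 0; i < n; ++i) {
        draw_read(src, cum, readLen, errProb, buf.data(), rng);
        const int g = map_one(buf.data(), readLen, px, theta, cnt, touched,
                              prefilter);
        if (g >= 0) counts[g]++; else ++unassigned;
    }
    return List::create(_["counts"] = counts, _["unassigned"] = unassigned,
                        _["total"] = n);
}
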