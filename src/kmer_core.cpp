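#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit packing (A=0, C=1, G=2, T=3) keeps k <= 32 in one 64-bit word;
// numeric order on packed words equals lexicographic order on the strings.

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static std::string decode_kmer(uint64_t x, int k) {
    static const char bases[] = "ACGT";
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = bases[x & 3ULL];
        x >>= 2;
    }
    return s;
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, bool canonical) {
    if (k < 1 || k > 32) stop("k must be in [1, 32]");
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift = 2 * (k - 1);
    std::unordered_map<uint64_t, int> counts;
    counts.reserve(1 << 16);
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        if (seqs[s] == NA_STRING) continue;
        const char *p = CHAR(seqs[s]);
        int len = LENGTH(seqs[s]);
        uint64_t fwd = 0, rev = 0;
        int run = 0;  // length of current valid-base run
        for (int i = 0; i < len; ++i) {
            int c = base_code(p[i]);
            if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)c) & mask;
            rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
            if (++run >= k) {
                uint64_t key = canonical ? (fwd < rev ? fwd : rev) : fwd;
                ++counts[key];
            }
        }
    }
    R_xlen_t n = (R_xlen_t)counts.size();
    CharacterVector kmers(n);
    IntegerVector cnt(n);
    R_xlen_t i = 0;
    for (auto &kv : counts) {
        kmers[i] = decode_kmer(kv.first, k);
        cnt[i] = kv.second;
        ++i;
    }
    return List::create(_["kmer"] = kmers, _["count"] = cnt);
}

// Canonical k-mer of every window of one sequence, with its 0-based
// offset and the strand on which the sliced (forward) window matches
// the canonical form ("+" if the slice is itself canonical).
// [[Rcpp::export]]
List cpp_kmer_positions(std::string seq, int k) {
    if (k < 1 || k > 32) stop("k must be in [1, 32]");
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift = 2 * (k - 1);
    std::vector<uint64_t> keys;
    std::vector<int> pos;
    std::vector<bool> fwd_is_canon;
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
        int c = base_code(seq[i]);
        if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
        if (++run >= k) {
            bool f = fwd <= rev;
            keys.push_back(f ? fwd : rev);
            pos.push_back((int)i - k + 1);
            fwd_is_canon.push_back(f);
        }
    }
    R_xlen_t n = (R_xlen_t)keys.size();
    CharacterVector kmers(n);
    IntegerVector offset(n);
    CharacterVector strand(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        kmers[i] = decode_kmer(keys[i], k);
        offset[i] = pos[i];
        strand[i] = fwd_is_canon[i] ? "+" : "-";
    }
    return List::create(_["kmer"] = kmers, _["offset"] = offset,
                        _["strand"] = strand);
}

// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector kmers) {
    R_xlen_t n = kmers.size();
    CharacterVector out(n);
    for (R_xlen_t j = 0; j < n; ++j) {
        if (kmers[j] == NA_STRING) stop("NA k-mer");
        const char *p = CHAR(kmers[j]);
        int k = LENGTH(kmers[j]);
        if (k < 1 || k > 32) stop("k-mer length must be in [1, 32]");
        uint64_t fwd = 0, rev = 0;
        for (int i = 0; i < k; ++i) {
            int c = base_code(p[i]);
            if (c < 0) stop("non-ACGT character in k-mer");
            fwd = (fwd << 2) | (uint64_t)c;
            rev |= ((uint64_t)(3 - c)) << (2 * i);
        }
        out[j] = (fwd <= rev) ? std::string(p, p + k) : decode_kmer(rev, k);
    }
    return out;
}
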