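#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding; k <= 31 so a k-mer fits in one uint64_t.
static inline int base2code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline uint64_t revcomp_code(uint64_t x, int k) {
    uint64_t r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (3 - (x & 3));
        x >>= 2;
    }
    return r;
}

typedef std::unordered_map<uint64_t, int> Census;

// Roll over one read, pushing the canonical code of every k-mer (skips
// nothing: caller guarantees A/C/G/T only).
static void read_kmers(const std::string &s, int k, std::vector<uint64_t> &out) {
    out.clear();
    int n = (int) s.size();
    if (n < k) return;
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t fwd = 0;
    for (int i = 0; i < n; ++i) {
        fwd = ((fwd << 2) | (uint64_t) base2code(s[i])) & mask;
        if (i >= k - 1) {
            uint64_t rc = revcomp_code(fwd, k);
            out.push_back(fwd < rc ? fwd : rc);
        }
    }
}

// [[Rcpp::export(name = ".kmer_census")]]
DataFrame kmer_census(CharacterVector reads, int k) {
    Census census;
    std::vector<uint64_t> km;
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        read_kmers(s, k, km);
        for (size_t i = 0; i < km.size(); ++i) census[km[i]]++;
    }
    size_t n = census.size();
    CharacterVector kmer(n);
    IntegerVector count(n);
    const char *BASES = "ACGT";
    size_t j = 0;
    for (Census::const_iterator it = census.begin(); it != census.end(); ++it) {
        uint64_t x = it->first;
        std::string s(k, 'A');
        for (int i = k - 1; i >= 0; --i) { s[i] = BASES[x & 3]; x >>= 2; }
        kmer[j] = s;
        count[j] = it->second;
        ++j;
    }
    return DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                             _["stringsAsFactors"] = false);
}

static inline bool is_trusted(uint64_t fwd, int k, const Census &census,
                              int threshold) {
    uint64_t rc = revcomp_code(fwd, k);
    uint64_t can = fwd < rc ? fwd : rc;
    Census::const_iterator it = census.find(can);
    return it != census.end() && it->second >= threshold;
}

// One correction attempt on one read. Returns true if a substitution was
// applied (read modified in place). The census is NOT updated.
//
// The applied substitution is the trusted-k-mer-count maximiser, applied
// only if it makes ALL the read's k-mers trusted, ties broken by smallest
// (position, base). A candidate can only reach all-trusted if its position
// is covered by every currently untrusted k-mer, so the search is
// restricted to that intersection window; the first candidate (ascending
// position, then base) that makes every overlapped k-mer trusted is
// exactly the tie-broken maximiser.
static bool correct_read_once(std::string &s, int k, const Census &census,
                              int threshold, std::vector<uint64_t> &codes,
                              std::vector<char> &tr) {
    int n = (int) s.size();
    if (n < k) return false;
    int nk = n - k + 1;
    codes.resize(nk);
    tr.resize(nk);
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t fwd = 0;
    for (int i = 0; i < n; ++i) {
        fwd = ((fwd << 2) | (uint64_t) base2code(s[i])) & mask;
        if (i >= k - 1) codes[i - k + 1] = fwd;
    }
    int firstU = -1, lastU = -1;
    for (int i = 0; i < nk; ++i) {
        bool t = is_trusted(codes[i], k, census, threshold);
        tr[i] = t;
        if (!t) { if (firstU < 0) firstU = i; lastU = i; }
    }
    if (firstU < 0) return false;           // all trusted already
    // positions covered by every untrusted k-mer
    int plo = lastU;
    int phi = firstU + k - 1;
    if (phi > n - 1) phi = n - 1;
    if (plo > phi) return false;            // no single base can fix all

    const char BASES[4] = {'A', 'C', 'G', 'T'};
    for (int p = plo; p <= phi; ++p) {
        char orig = s[p];
        int lo = p - k + 1; if (lo < 0) lo = 0;
        int hi = p; if (hi > nk - 1) hi = nk - 1;
        for (int b = 0; b < 4; ++b) {
            if (BASES[b] == orig) continue;
            bool all = true;
            for (int i = lo; i <= hi && all; ++i) {
                int shift = 2 * (k - 1 - (p - i));
                uint64_t code = (codes[i] & ~(3ULL << shift)) |
                                ((uint64_t) b << shift);
                if (!is_trusted(code, k, census, threshold)) all = false;
            }
            // [lo, hi] contains every untrusted k-mer (p is in the
            // intersection window), and k-mers outside it are trusted, so
            // `all` means the whole read becomes trusted.
            if (all) { s[p] = BASES[b]; return true; }
        }
    }
    return false;
}

// [[Rcpp::export(name = ".kspectrum_correct_cpp")]]
CharacterVector kspectrum_correct_cpp(CharacterVector reads, int k,
                                      int threshold, int passes) {
    Census census;
    std::vector<uint64_t> km;
    std::vector<std::string> seqs(reads.size());
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        seqs[r] = as<std::string>(reads[r]);
        read_kmers(seqs[r], k, km);
        for (size_t i = 0; i < km.size(); ++i) census[km[i]]++;
    }
    std::vector<uint64_t> codes;
    std::vector<char> flags;
    for (int pass = 0; pass < passes; ++pass) {
        bool changed = false;
        for (size_t r = 0; r < seqs.size(); ++r) {
            if (correct_read_once(seqs[r], k, census, threshold,
                                  codes, flags)) changed = true;
        }
        if (!changed) break;
    }
    CharacterVector out(reads.size());
    for (R_xlen_t r = 0; r < reads.size(); ++r) out[r] = seqs[r];
    out.names() = reads.names();
    return out;
}
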