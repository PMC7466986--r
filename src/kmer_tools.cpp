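#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// 2-bit base codes; anything not ACGT (e.g. N) is invalid and breaks k-mer runs.
static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

struct KmerEntry {
    uint64_t kmer;
    uint64_t aux; // pos | (seq << 32) | (orient << 62)
};

static inline uint32_t aux_pos(uint64_t a)    { return (uint32_t)(a & 0xffffffffULL); }
static inline uint32_t aux_seq(uint64_t a)    { return (uint32_t)((a >> 32) & 0x3fffffffULL); }
static inline int      aux_orient(uint64_t a) { return (int)((a >> 62) & 1ULL); }

// Collect canonical k-mers (min of forward and reverse-complement encoding)
// with position, sequence index and orientation-of-canonical flag.
static void collect_kmers(const std::vector<std::string>& seqs, int k,
                          std::vector<KmerEntry>& out) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    size_t total = 0;
    for (const auto& s : seqs) total += s.size();
    out.reserve(total);
    for (size_t s = 0; s < seqs.size(); ++s) {
        const std::string& str = seqs[s];
        const int n = (int)str.size();
        if (n < k) continue;
        uint64_t f = 0, r = 0;
        int run = 0;
        for (int i = 0; i < n; ++i) {
            int c = base_code(str[(size_t)i]);
            if (c < 0) { run = 0; f = 0; r = 0; continue; }
            f = ((f << 2) | (uint64_t)c) & mask;
            r = (r >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
            if (++run >= k) {
                uint64_t canon = std::min(f, r);
                int orient = (f <= r) ? 0 : 1;
                uint64_t pos = (uint64_t)(i - k + 1);
                KmerEntry e;
                e.kmer = canon;
                e.aux = pos | ((uint64_t)s << 32) | ((uint64_t)orient << 62);
                out.push_back(e);
            }
        }
    }
}

static void keep_unique(std::vector<KmerEntry>& v) {
    std::sort(v.begin(), v.end(),
              [](const KmerEntry& a, const KmerEntry& b) { return a.kmer < b.kmer; });
    size_t w = 0, i = 0;
    const size_t n = v.size();
    while (i < n) {
        size_t j = i;
        while (j + 1 < n && v[j + 1].kmer == v[i].kmer) ++j;
        if (j == i) v[w++] = v[i];
        i = j + 1;
    }
    v.resize(w);
}

// [[Rcpp::export]]
DataFrame anchor_seeds_cpp(CharacterVector qseqs, CharacterVector tseqs, int k) {
    if (k < 3 || k > 31) stop("k must be in [3, 31]");
    std::vector<std::string> qs(qseqs.size()), ts(tseqs.size());
    for (R_xlen_t i = 0; i < qseqs.size(); ++i) qs[(size_t)i] = as<std::string>(qseqs[i]);
    for (R_xlen_t i = 0; i < tseqs.size(); ++i) ts[(size_t)i] = as<std::string>(tseqs[i]);

    std::vector<KmerEntry> qk, tk;
    collect_kmers(qs, k, qk);
    keep_unique(qk);
    collect_kmers(ts, k, tk);
    keep_unique(tk);

    // merge-join on canonical k-mer value
    struct Seed { uint32_t qseq, qpos, tseq, tpos; uint8_t strand; };
    std::vector<Seed> seeds;
    size_t i = 0, j = 0;
    while (i < qk.size() && j < tk.size()) {
        if (qk[i].kmer < tk[j].kmer) ++i;
        else if (qk[i].kmer > tk[j].kmer) ++j;
        else {
            Seed sd;
            sd.qseq = aux_seq(qk[i].aux);
            sd.qpos = aux_pos(qk[i].aux);
            sd.tseq = aux_seq(tk[j].aux);
            sd.tpos = aux_pos(tk[j].aux);
            sd.strand = (aux_orient(qk[i].aux) == aux_orient(tk[j].aux)) ? 0 : 1;
            seeds.push_back(sd);
            ++i; ++j;
        }
    }
    qk.clear(); qk.shrink_to_fit();
    tk.clear(); tk.shrink_to_fit();

    std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
        if (a.qseq != b.qseq) return a.qseq < b.qseq;
        return a.qpos < b.qpos;
    });

    // merge maximal runs of overlapping (step-1) seeds into anchors
    std::vector<int> o_qseq, o_qstart, o_tseq, o_tstart, o_len;
    std::vector<int> o_strand;
    size_t n = seeds.size();
    size_t a = 0;
    while (a < n) {
        size_t b = a;
        while (b + 1 < n) {
            const Seed& p = seeds[b];
            const Seed& q = seeds[b + 1];
            bool ok = q.qseq == p.qseq && q.tseq == p.tseq && q.strand == p.strand &&
                      q.qpos == p.qpos + 1 &&
                      ((p.strand == 0 && q.tpos == p.tpos + 1) ||
                       (p.strand == 1 && q.tpos + 1 == p.tpos));
            if (!ok) break;
            ++b;
        }
        const Seed& first = seeds[a];
        const Seed& last = seeds[b];
        int runlen = (int)(b - a + 1);
        int len = runlen + k - 1;
        o_qseq.push_back((int)first.qseq + 1);
        o_qstart.push_back((int)first.qpos);
        o_tseq.push_back((int)first.tseq + 1);
        o_tstart.push_back(first.strand == 0 ? (int)first.tpos : (int)last.tpos);
        o_len.push_back(len);
        o_strand.push_back(first.strand == 0 ? 1 : -1);
        a = b + 1;
    }

    return DataFrame::create(
        _["q_seq"] = o_qseq, _["q_start"] = o_qstart,
        _["t_seq"] = o_tseq, _["t_start"] = o_tstart,
        _["length"] = o_len, _["strand_sign"] = o_strand);
}

// Maximum-weight co-linear chain among anchors (assumed sorted by q_start).
// Returns 1-based indices of the chain, in q order. Deterministic tie-breaks:
// earliest predecessor, earliest chain end.
// [[Rcpp::export]]
IntegerVector best_chain_cpp(NumericVector q_start, NumericVector q_end,
                             NumericVector t_start, NumericVector t_end,
                             IntegerVector strand_sign, NumericVector weight,
                             double max_gap) {
    const int n = q_start.size();
    if (n == 0) return IntegerVector(0);
    std::vector<double> f(n);
    std::vector<int> pred(n, -1);
    for (int i = 0; i < n; ++i) {
        f[i] = weight[i];
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            if (strand_sign[j] != strand_sign[i]) continue;
            if (!(q_start[j] < q_start[i])) continue;
            double qgap = q_start[i] - q_end[j];
            if (qgap < 0 || qgap > max_gap) continue;
            double tgap = (strand_sign[i] > 0) ? (t_start[i] - t_end[j])
                                               : (t_start[j] - t_end[i]);
            if (tgap < 0 || tgap > max_gap) continue;
            double cand = f[j] + weight[i];
            if (cand > f[i]) { f[i] = cand; pred[i] = j; }
        }
    }
    int best = 0;
    for (int i = 1; i < n; ++i) if (f[i] > f[best]) best = i;
    std::vector<int> chain;
    for (int i = best; i >= 0; i = pred[i]) chain.push_back(i + 1);
    std::reverse(chain.begin(), chain.end());
    return wrap(chain);
}

// Seed positions where the k-mer starting at i recurred at i - lag,
// lag in [min_lag, max_lag]; reported as (start_of_earlier_copy, lag).
// [[Rcpp::export]]
IntegerMatrix tandem_seeds_cpp(std::string seq, int k, int min_lag, int max_lag) {
    if (k < 3 || k > 31) stop("k must be in [3, 31]");
    const int n = (int)seq.size();
    std::vector<int> s_pos, s_lag;
    if (n >= k) {
        const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        std::unordered_map<uint64_t, int> last;
        last.reserve((size_t)n * 2);
        uint64_t f = 0;
        int run = 0;
        for (int i = 0; i < n; ++i) {
            int c = base_code(seq[(size_t)i]);
            if (c < 0) { run = 0; f = 0; continue; }
            f = ((f << 2) | (uint64_t)c) & mask;
            if (++run >= k) {
                int pos = i - k + 1;
                auto it = last.find(f);
                if (it != last.end()) {
                    int lag = pos - it->second;
                    if (lag >= min_lag && lag <= max_lag) {
                        s_pos.push_back(it->second);
                        s_lag.push_back(lag);
                    }
                    it->second = pos;
                } else {
                    last.emplace(f, pos);
                }
            }
        }
    }
    IntegerMatrix out((int)s_pos.size(), 2);
    for (size_t i = 0; i < s_pos.size(); ++i) {
        out((int)i, 0) = s_pos[i];
        out((int)i, 1) = s_lag[i];
    }
    colnames(out) = CharacterVector::create("pos", "lag");
    return out;
}

// Seeded ungapped scan: candidate placements of `pattern` in `subject` found
// via shared k-mers on matching diagonals, scored by Hamming identity.
// Returns (start0, identity) rows with identity >= min_identity.
// [[Rcpp::export]]
NumericMatrix scan_consensus_cpp(std::string subject, std::string pattern,
                                 int k, double min_identity) {
    const int n = (int)subject.size();
    const int L = (int)pattern.size();
    std::vector<int> starts;
    std::vector<double> idents;
    if (L >= k && n >= L) {
        const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        std::unordered_map<uint64_t, std::vector<int>> pk;
        {
            uint64_t f = 0; int run = 0;
            for (int i = 0; i < L; ++i) {
                int c = base_code(pattern[(size_t)i]);
                if (c < 0) { run = 0; f = 0; continue; }
                f = ((f << 2) | (uint64_t)c) & mask;
                if (++run >= k) pk[f].push_back(i - k + 1);
            }
        }
        std::vector<char> seen(n > 0 ? (size_t)n : 1, 0);
        std::vector<int> cand;
        {
            uint64_t f = 0; int run = 0;
            for (int i = 0; i < n; ++i) {
                int c = base_code(subject[(size_t)i]);
                if (c < 0) { run = 0; f = 0; continue; }
                f = ((f << 2) | (uint64_t)c) & mask;
                if (++run >= k) {
                    auto it = pk.find(f);
                    if (it != pk.end()) {
                        int pos = i - k + 1;
                        for (int off : it->second) {
                            int s = pos - off;
                            if (s >= 0 && s + L <= n && !seen[(size_t)s]) {
                                seen[(size_t)s] = 1;
                                cand.push_back(s);
                            }
                        }
                    }
                }
            }
        }
        std::sort(cand.begin(), cand.end());
        for (int s : cand) {
            int m = 0;
            for (int i = 0; i < L; ++i)
                if (subject[(size_t)(s + i)] == pattern[(size_t)i]) ++m;
            double ident = (double)m / (double)L;
            if (ident >= min_identity) {
                starts.push_back(s);
                idents.push_back(ident);
            }
        }
    }
    NumericMatrix out((int)starts.size(), 2);
    for (size_t i = 0; i < starts.size(); ++i) {
        out((int)i, 0) = starts[i];
        out((int)i, 1) = idents[i];
    }
    colnames(out) = CharacterVector::create("start", "identity");
    return out;
}

// Random DNA using R's RNG (respects set.seed): P(C)=P(G)=gc/2, P(A)=P(T)=(1-gc)/2.
// [[Rcpp::export]]
std::string random_dna_cpp(int n, double gc) {
    std::string s((size_t)n, 'A');
    const double half_gc = gc / 2.0, half_at = (1.0 - gc) / 2.0;
    GetRNGstate();
    for (int i = 0; i < n; ++i) {
        double u = unif_rand();
        char b;
        if (u < half_at) b = 'A';
        else if (u < 2 * half_at) b = 'T';
        else if (u < 2 * half_at + half_gc) b = 'C';
        else b = 'G';
        s[(size_t)i] = b;
    }
    PutRNGstate();
    return s;
}

// Per-base substitution at `rate`; mutated base drawn uniformly from the
// three alternatives. Uses R's RNG.
// [[Rcpp::export]]
std::string mutate_dna_cpp(std::string seq, double rate) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    GetRNGstate();
    for (size_t i = 0; i < seq.size(); ++i) {
        int c = base_code(seq[i]);
        if (c < 0) continue;
        if (unif_rand() < rate) {
            int alt = (int)(unif_rand() * 3.0);
            if (alt > 2) alt = 2;
            if (alt >= c) ++alt;
            seq[i] = bases[alt];
        }
    }
    PutRNGstate();
    return seq;
}
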