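#include "venomtx.h"
using namespace Rcpp;

// Canonical k-mer counts over all N-free windows of all sequences.
// Canonical form = lexicographic min of the k-mer and its reverse complement;
// k must be odd (enforced in R) so no k-mer is its own reverse complement.
// [[Rcpp::export]]
IntegerVector cpp_count_kmers(CharacterVector seqs, int k) {
    std::unordered_map<std::string, int> counts;
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        std::string seq = as<std::string>(seqs[s]);
        int n = (int)seq.size();
        if (n < k) continue;
        std::string rc = vt_revcomp(seq);
        // last position (0-based, inclusive) of an invalid base seen so far
        int last_bad = -1;
        for (int i = 0; i < n; ++i) {
            char c = seq[i];
            if (c != 'A' && c != 'C' && c != 'G' && c != 'T') last_bad = i;
            int start = i - k + 1;
            if (start < 0 || last_bad >= start) continue;
            // window seq[start, i]; its rc is rc[n-1-i, n-1-i+k-1]
            const char *fwd = seq.data() + start;
            const char *rev = rc.data() + (n - 1 - i);
            int cmp = std::memcmp(fwd, rev, k);
            std::string canon(cmp <= 0 ? fwd : rev, k);
            ++counts[canon];
        }
    }
    IntegerVector out(counts.size());
    CharacterVector nm(counts.size());
    R_xlen_t j = 0;
    for (auto &kv : counts) {
        nm[j] = kv.first;
        out[j] = kv.second;
        ++j;
    }
    out.attr("names") = nm;
    return out;
}

// Per-read counts of flagged and usable (N-free) k-mer windows.
// Returns an integer matrix with columns (flagged, usable).
// [[Rcpp::export]]
IntegerMatrix cpp_flagged_window_stats(CharacterVector seqs,
                                       CharacterVector flagged, int k) {
    std::unordered_set<std::string> flag;
    flag.reserve(flagged.size() * 2 + 1);
    for (R_xlen_t i = 0; i < flagged.size(); ++i)
        flag.insert(as<std::string>(flagged[i]));
    IntegerMatrix out(seqs.size(), 2);
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        std::string seq = as<std::string>(seqs[s]);
        int n = (int)seq.size();
        int nflag = 0, nuse = 0;
        if (n >= k) {
            std::string rc = vt_revcomp(seq);
            int last_bad = -1;
            for (int i = 0; i < n; ++i) {
                char c = seq[i];
                if (c != 'A' && c != 'C' && c != 'G' && c != 'T') last_bad = i;
                int start = i - k + 1;
                if (start < 0 || last_bad >= start) continue;
                ++nuse;
                if (flag.empty()) continue;
                const char *fwd = seq.data() + start;
                const char *rev = rc.data() + (n - 1 - i);
                int cmp = std::memcmp(fwd, rev, k);
                std::string canon(cmp <= 0 ? fwd : rev, k);
                if (flag.count(canon)) ++nflag;
            }
        }
        out(s, 0) = nflag;
        out(s, 1) = nuse;
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i)
        out[i] = vt_revcomp(as<std::string>(seqs[i]));
    return out;
}

// Minimum phred score per phred+33 quality string (NA for empty strings).
// [[Rcpp::export]]
IntegerVector cpp_min_phred(CharacterVector quals) {
    IntegerVector out(quals.size());
    for (R_xlen_t i = 0; i < quals.size(); ++i) {
        std::string q = as<std::string>(quals[i]);
        if (q.empty()) {
            out[i] = NA_INTEGER;
            continue;
        }
        int m = 1000;
        for (char c : q) m = std::min(m, (int)c - 33);
        out[i] = m;
    }
    return out;
}

// Greedy seed acceptance scan: seqs are candidate reads in (already
// randomized) draw order; a candidate is accepted unless any of its
// length-k windows (either strand) matches a window already contributed
// by an accepted candidate. Stops after n_target acceptances.
// [[Rcpp::export]]
LogicalVector cpp_select_seeds_scan(CharacterVector seqs, int k, int n_target) {
    std::unordered_set<std::string> used;
    LogicalVector out(seqs.size(), false);
    int accepted = 0;
    for (R_xlen_t s = 0; s < seqs.size() && accepted < n_target; ++s) {
        std::string seq = as<std::string>(seqs[s]);
        int n = (int)seq.size();
        if (n < k || !vt_acgt_only(seq)) continue;
        bool clash = false;
        for (int i = 0; i + k <= n && !clash; ++i)
            if (used.count(seq.substr(i, k))) clash = true;
        if (clash) continue;
        out[s] = true;
        ++accepted;
        std::string rc = vt_revcomp(seq);
        for (int i = 0; i + k <= n; ++i) {
            used.insert(seq.substr(i, k));
            used.insert(rc.substr(i, k));
        }
    }
    return out;
}
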