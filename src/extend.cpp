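#include "venomtx.h"
using namespace Rcpp;

// Overlap index for seed-and-extend assembly. Each eligible read is stored
// in both orientations; entries are keyed by the oriented read's 5'
// terminal overlap_len-mer. Candidate search slides that key over the
// contig's terminal region, which enumerates exactly the reads with a
// mismatch-free overlap >= overlap_len that protrude beyond the contig
// end (verified base-by-base over the full overlap).
struct OverlapIndex {
    std::vector<std::string> oriented;  // 2 entries per read: fwd, rc
    std::unordered_map<std::string, std::vector<int>> pref;
    int k;
    int maxlen;
    int nreads;
};

// [[Rcpp::export]]
SEXP cpp_build_overlap_index(CharacterVector seqs, int k) {
    OverlapIndex *idx = new OverlapIndex();
    idx->k = k;
    idx->maxlen = 0;
    idx->nreads = (int)seqs.size();
    idx->oriented.resize(2 * seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        if ((int)s.size() < k || !vt_acgt_only(s)) continue;  // never candidates
        idx->maxlen = std::max(idx->maxlen, (int)s.size());
        std::string rc = vt_revcomp(s);
        idx->oriented[2 * i] = s;
        idx->oriented[2 * i + 1] = rc;
        idx->pref[s.substr(0, k)].push_back(2 * (int)i);
        idx->pref[rc.substr(0, k)].push_back(2 * (int)i + 1);
    }
    XPtr<OverlapIndex> p(idx, true);
    return p;
}

// [[Rcpp::export]]
int cpp_index_size(SEXP xp) {
    XPtr<OverlapIndex> idx(xp);
    return (int)idx->pref.size();
}

struct Cand {
    int oi;       // oriented entry index
    int overlap;  // overlap length (>= k)
};

// Candidates extending `contig` to the right: oriented reads whose prefix
// of length (L - p) equals contig[p..L) for some p with L - p >= k, and
// which protrude at least one base.
static void right_candidates(const OverlapIndex &idx, const std::string &contig,
                             std::vector<Cand> &out) {
    int L = (int)contig.size();
    int k = idx.k;
    int pmin = std::max(0, L - idx.maxlen + 1);
    for (int p = L - k; p >= pmin; --p) {
        auto it = idx.pref.find(contig.substr(p, k));
        if (it == idx.pref.end()) continue;
        int o = L - p;
        for (int oi : it->second) {
            const std::string &s = idx.oriented[oi];
            if ((int)s.size() <= o) continue;  // must protrude
            if (o > k && s.compare(k, o - k, contig, p + k, o - k) != 0)
                continue;
            out.push_back({oi, o});
        }
    }
}

// One extension attempt: uniform choice among candidates in `direction`
// (0 = right, 1 = left). Left extension works on the reverse complement
// of the contig. Returns the addition (already in contig orientation),
// the 1-based source read index and its strand, or an empty list.
// [[Rcpp::export]]
List cpp_extend_once(SEXP xp, std::string contig, int direction) {
    XPtr<OverlapIndex> idx(xp);
    std::string work = direction == 0 ? contig : vt_revcomp(contig);
    if ((int)work.size() < idx->k) return List::create();
    std::vector<Cand> cand;
    right_candidates(*idx, work, cand);
    if (cand.empty()) return List::create();
    int pick = (int)(unif_rand() * cand.size());
    if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
    const Cand &c = cand[pick];
    const std::string &s = idx->oriented[c.oi];
    std::string add = s.substr(c.overlap);
    if (direction == 1) add = vt_revcomp(add);
    bool rc_entry = (c.oi % 2) == 1;
    bool minus = direction == 0 ? rc_entry : !rc_entry;
    return List::create(_["addition"] = add, _["read"] = c.oi / 2 + 1,
                        _["strand"] = minus ? "-" : "+",
                        _["overlap"] = c.overlap);
}

// One replicate: repeated uniform-random perfect-overlap extension in one
// direction until no candidate remains or the contig reaches max_len.
// Returns the bases added beyond the seed (contig orientation) and the
// number of reads incorporated.
// [[Rcpp::export]]
List cpp_run_replicate(SEXP xp, std::string seed, int direction, int max_len) {
    XPtr<OverlapIndex> idx(xp);
    std::string work = direction == 0 ? seed : vt_revcomp(seed);
    int steps = 0;
    size_t seedlen = work.size();
    if ((int)seedlen >= idx->k) {
        std::vector<Cand> cand;
        while ((int)work.size() < max_len) {
            cand.clear();
            right_candidates(*idx, work, cand);
            if (cand.empty()) break;
            int pick = (int)(unif_rand() * cand.size());
            if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
            const Cand &c = cand[pick];
            work += idx->oriented[c.oi].substr(c.overlap);
            ++steps;
        }
    }
    std::string ext = work.substr(seedlen);
    if (direction == 1) ext = vt_revcomp(ext);
    return List::create(_["extension"] = ext, _["steps"] = steps);
}

// All candidate additions for the current contig end, for tests and the
// exported extend_once wrapper's candidate introspection.
// [[Rcpp::export]]
List cpp_extend_candidates(SEXP xp, std::string contig, int direction) {
    XPtr<OverlapIndex> idx(xp);
    std::string work = direction == 0 ? contig : vt_revcomp(contig);
    std::vector<Cand> cand;
    if ((int)work.size() >= idx->k) right_candidates(*idx, work, cand);
    CharacterVector add(cand.size()), strand(cand.size());
    IntegerVector read(cand.size()), overlap(cand.size());
    for (size_t i = 0; i < cand.size(); ++i) {
        std::string a = idx->oriented[cand[i].oi].substr(cand[i].overlap);
        if (direction == 1) a = vt_revcomp(a);
        add[i] = a;
        read[i] = cand[i].oi / 2 + 1;
        bool rc_entry = (cand[i].oi % 2) == 1;
        bool minus = direction == 0 ? rc_entry : !rc_entry;
        strand[i] = minus ? "-" : "+";
        overlap[i] = cand[i].overlap;
    }
    return List::create(_["addition"] = add, _["read"] = read,
                        _["strand"] = strand, _["overlap"] = overlap);
}
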