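#include "venomtx.h"
using namespace Rcpp;

// Needleman-Wunsch global alignment under unit scoring (match +1,
// mismatch -1, gap -1); identity = matches / alignment columns along an
// optimal path (ties broken diagonal > up > left).
// [[Rcpp::export]]
double cpp_global_identity(std::string a, std::string b) {
    int m = (int)a.size(), n = (int)b.size();
    if (m == 0 || n == 0) stop("global_identity: empty sequence");
    std::vector<int> prev(n + 1), cur(n + 1);
    // traceback: 0 diag, 1 up (gap in b), 2 left (gap in a)
    std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1));
    for (int j = 0; j <= n; ++j) {
        prev[j] = -j;
        tb[j] = 2;
    }
    for (int i = 1; i <= m; ++i) {
        cur[0] = -i;
        tb[(size_t)i * (n + 1)] = 1;
        for (int j = 1; j <= n; ++j) {
            int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 1 : -1);
            int u = prev[j] - 1;
            int l = cur[j - 1] - 1;
            int best = d;
            unsigned char t = 0;
            if (u > best) { best = u; t = 1; }
            if (l > best) { best = l; t = 2; }
            cur[j] = best;
            tb[(size_t)i * (n + 1) + j] = t;
        }
        std::swap(prev, cur);
    }
    int i = m, j = n;
    long matches = 0, cols = 0;
    while (i > 0 || j > 0) {
        unsigned char t = tb[(size_t)i * (n + 1) + j];
        if (i > 0 && j > 0 && t == 0) {
            if (a[i - 1] == b[j - 1]) ++matches;
            --i; --j;
        } else if (i > 0 && (t == 1 || j == 0)) {
            --i;
        } else {
            --j;
        }
        ++cols;
    }
    return (double)matches / (double)cols;
}

// Semi-global ("glocal") alignment: the reference is aligned end-to-end,
// the contig contributes a local window (free leading/trailing contig
// bases). Unit scoring as above. Identity counts matches over all columns
// of the aligned region, including gap columns against either sequence
// inside the region (so a contig covering half the reference pays for the
// missing half). Returns identity plus the 0-based half-open contig span.
// [[Rcpp::export]]
List cpp_glocal_identity(std::string ref, std::string contig) {
    int m = (int)ref.size(), n = (int)contig.size();
    if (m == 0 || n == 0) stop("glocal alignment: empty sequence");
    std::vector<int> prev(n + 1), cur(n + 1);
    std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1));
    for (int j = 0; j <= n; ++j) {
        prev[j] = 0;  // free contig prefix
        tb[j] = 2;
    }
    for (int i = 1; i <= m; ++i) {
        cur[0] = -i;
        tb[(size_t)i * (n + 1)] = 1;
        for (int j = 1; j <= n; ++j) {
            int d = prev[j - 1] + (ref[i - 1] == contig[j - 1] ? 1 : -1);
            int u = prev[j] - 1;
            int l = cur[j - 1] - 1;
            int best = d;
            unsigned char t = 0;
            if (u > best) { best = u; t = 1; }
            if (l > best) { best = l; t = 2; }
            cur[j] = best;
            tb[(size_t)i * (n + 1) + j] = t;
        }
        std::swap(prev, cur);
    }
    int jend = 0, bestscore = prev[0];
    for (int j = 1; j <= n; ++j)
        if (prev[j] > bestscore) { bestscore = prev[j]; jend = j; }
    // traceback from (m, jend) until the reference is fully consumed
    int i = m, j = jend;
    long matches = 0, cols = 0;
    while (i > 0) {
        unsigned char t = tb[(size_t)i * (n + 1) + j];
        if (j > 0 && t == 0) {
            if (ref[i - 1] == contig[j - 1]) ++matches;
            --i; --j;
        } else if (t == 1 || j == 0) {
            --i;
        } else {
            --j;
        }
        ++cols;
    }
    return List::create(_["identity"] = (double)matches / (double)cols,
                        _["start"] = j, _["end"] = jend,
                        _["score"] = bestscore);
}

// All zero-mismatch, full-length occurrences of each read in cds, both
// strands. Reads containing non-ACGT characters never map. Returns
// parallel vectors: read index (1-based), 0-based start, strand ("+"/"-").
// [[Rcpp::export]]
List cpp_map_exact(CharacterVector reads, std::string cds) {
    std::vector<int> ridx, starts;
    std::vector<std::string> strands;
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        if (s.empty() || s.size() > cds.size() || !vt_acgt_only(s)) continue;
        size_t pos = cds.find(s, 0);
        while (pos != std::string::npos) {
            ridx.push_back((int)r + 1);
            starts.push_back((int)pos);
            strands.push_back("+");
            pos = cds.find(s, pos + 1);
        }
        std::string rc = vt_revcomp(s);
        if (rc != s) {
            pos = cds.find(rc, 0);
            while (pos != std::string::npos) {
                ridx.push_back((int)r + 1);
                starts.push_back((int)pos);
                strands.push_back("-");
                pos = cds.find(rc, pos + 1);
            }
        }
    }
    return List::create(_["read"] = ridx, _["start"] = starts,
                        _["strand"] = strands);
}
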