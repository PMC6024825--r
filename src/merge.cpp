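#include "venomtx.h"
using namespace Rcpp;

// Merge overlapping read pairs. r2 is reverse-complemented, then every
// overlap of length >= min_overlap between r1's 3' end and rc(r2)'s 5'
// end with mismatch fraction <= max_mm is scored (matches - mismatches,
// ties -> longest overlap). Disagreeing overlap columns take the base
// with the higher quality; merged quality is the columnwise max.
// Returns NA for pairs with no admissible overlap.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector s1, CharacterVector q1,
                     CharacterVector s2, CharacterVector q2,
                     int min_overlap, double max_mm) {
    R_xlen_t n = s1.size();
    CharacterVector mseq(n), mqual(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string a = as<std::string>(s1[i]);
        std::string qa = as<std::string>(q1[i]);
        std::string b = vt_revcomp(as<std::string>(s2[i]));
        std::string qb = as<std::string>(q2[i]);
        std::reverse(qb.begin(), qb.end());
        int la = (int)a.size(), lb = (int)b.size();
        int best_o = -1, best_score = INT_MIN;
        int omax = std::min(la, lb);
        for (int o = omax; o >= min_overlap; --o) {
            int allowed = (int)std::floor(max_mm * o);
            int mm = 0;
            const char *pa = a.data() + (la - o);
            for (int j = 0; j < o; ++j) {
                if (pa[j] != b[j] && ++mm > allowed) break;
            }
            if (mm > allowed) continue;
            int score = (o - mm) - mm;
            if (score > best_score) {  // strict: earlier (longer) o wins ties
                best_score = score;
                best_o = o;
            }
        }
        if (best_o < 0) {
            mseq[i] = NA_STRING;
            mqual[i] = NA_STRING;
            continue;
        }
        int o = best_o;
        std::string seq = a.substr(0, la - o);
        std::string qual = qa.substr(0, la - o);
        for (int j = 0; j < o; ++j) {
            char ca = a[la - o + j], cb = b[j];
            char qca = qa[la - o + j], qcb = qb[j];
            seq += (ca == cb || qca >= qcb) ? ca : cb;
            qual += std::max(qca, qcb);
        }
        seq += b.substr(o);
        qual += qb.substr(o);
        mseq[i] = seq;
        mqual[i] = qual;
    }
    return List::create(_["seq"] = mseq, _["qual"] = mqual);
}
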