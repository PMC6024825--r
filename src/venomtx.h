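#pragma once

#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

inline char vt_comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

inline std::string vt_revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) c = vt_comp(c);
    return r;
}

inline bool vt_acgt_only(const std::string &s) {
    for (char c : s)
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
    return true;
}
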