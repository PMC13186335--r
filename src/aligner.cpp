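#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Ungapped exact-k-mer seed-and-extend alignment of reads against a small
// locus reference. Seeds are non-overlapping k-mers of the read (plus the
// final k-mer); each seed hit proposes a (locus, diagonal) placement, the
// full read is then compared base-by-base on that diagonal, clipped to the
// locus boundaries. The best placement per locus is kept; a read whose best
// identity is tied across two or more distinct loci is flagged ambiguous.
//
// Status codes: 0 = aligned, 1 = read shorter than seed, 2 = no seed hit,
// 3 = ambiguous best (tied identity across distinct loci).
// [[Rcpp::export]]
DataFrame cpp_align_reads(CharacterVector reads, CharacterVector locus_seqs,
                          int k) {
    const int nloc = locus_seqs.size();
    std::vector<std::string> refs(nloc);
    for (int i = 0; i < nloc; ++i) refs[i] = as<std::string>(locus_seqs[i]);

    std::unordered_map<std::string, std::vector<std::pair<int, int> > > idx;
    for (int i = 0; i < nloc; ++i) {
        const std::string& s = refs[i];
        if ((int)s.size() < k) continue;
        for (int p = 0; p + k <= (int)s.size(); ++p)
            idx[s.substr(p, k)].push_back(std::make_pair(i, p));
    }

    const int n = reads.size();
    IntegerVector locus(n), start(n), alen(n), matches(n), status(n);

    for (int r = 0; r < n; ++r) {
        locus[r] = NA_INTEGER;
        start[r] = NA_INTEGER;
        alen[r] = NA_INTEGER;
        matches[r] = NA_INTEGER;
        const std::string q = as<std::string>(reads[r]);
        const int L = (int)q.size();
        if (L < k) { status[r] = 1; continue; }

        std::vector<std::pair<int, int> > cands;  // (locus, diagonal)
        for (int o = 0; o + k <= L; o += k) {
            std::unordered_map<std::string,
                std::vector<std::pair<int, int> > >::const_iterator it =
                idx.find(q.substr(o, k));
            if (it == idx.end()) continue;
            for (size_t h = 0; h < it->second.size(); ++h)
                cands.push_back(std::make_pair(it->second[h].first,
                                               it->second[h].second - o));
        }
        {   // final k-mer, so a read whose tail is error-free still seeds
            const int o = L - k;
            std::unordered_map<std::string,
                std::vector<std::pair<int, int> > >::const_iterator it =
                idx.find(q.substr(o, k));
            if (it != idx.end())
                for (size_t h = 0; h < it->second.size(); ++h)
                    cands.push_back(std::make_pair(it->second[h].first,
                                                   it->second[h].second - o));
        }
        if (cands.empty()) { status[r] = 2; continue; }
        std::sort(cands.begin(), cands.end());
        cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

        double best_ident = -1.0;
        int best_loc = -1, best_start = 0, best_alen = 0, best_m = 0;
        bool tie = false;
        for (size_t c = 0; c < cands.size(); ++c) {
            const std::string& s = refs[cands[c].first];
            const int d = cands[c].second;
            const int qs = d < 0 ? -d : 0;
            const int rs = d < 0 ? 0 : d;
            const int len = std::min(L - qs, (int)s.size() - rs);
            if (len < k) continue;
            int m = 0;
            for (int j = 0; j < len; ++j)
                if (q[qs + j] == s[rs + j]) ++m;
            const double ident = 100.0 * m / len;
            if (ident > best_ident + 1e-12) {
                best_ident = ident; best_loc = cands[c].first;
                best_start = rs; best_alen = len; best_m = m;
                tie = false;
            } else if (std::fabs(ident - best_ident) <= 1e-12 &&
                       cands[c].first != best_loc) {
                tie = true;
            }
        }
        if (best_loc < 0) { status[r] = 2; continue; }
        if (tie) { status[r] = 3; continue; }
        status[r] = 0;
        locus[r] = best_loc + 1;  // 1-based index into locus_seqs
        start[r] = best_start;    // 0-based offset within locus
        alen[r] = best_alen;
        matches[r] = best_m;
    }

    return DataFrame::create(_["locus"] = locus, _["start"] = start,
                             _["aligned_length"] = alen,
                             _["matches"] = matches, _["status"] = status);
}
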