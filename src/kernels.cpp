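#include <Rcpp.h>
using namespace Rcpp;

// Hamming distance between two equal-length strings.
// [[Rcpp::export]]
int hamming_cpp(std::string a, std::string b) {
    if (a.size() != b.size()) stop("hamming_cpp: unequal lengths");
    int d = 0;
    for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
    return d;
}

// Distances from one query to a set of same-length references; -1 where the
// reference length differs from the query's.
// [[Rcpp::export]]
IntegerVector dist_to_set_cpp(std::string q, CharacterVector refs) {
    int n = refs.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string r = as<std::string>(refs[i]);
        if (r.size() != q.size()) { out[i] = -1; continue; }
        int d = 0;
        for (size_t k = 0; k < r.size(); ++k) if (r[k] != q[k]) ++d;
        out[i] = d;
    }
    return out;
}

// Best ungapped overlap merge of trimmed mate templates. t1 is the forward
// template, t2rc the reverse-complemented reverse template, with phred+33
// quality strings. Scans overlap sizes o = min_overlap..min(len1,len2),
// aligning the suffix of t1 against the prefix of t2rc; picks the o with the
// lowest mismatch fraction (ties -> larger overlap) subject to fraction <=
// max_mm_frac. Disagreements resolve to the higher-quality base; agreements
// keep the max quality. Returns status 0 = merged, 1 = no_overlap (templates
// shorter than min_overlap), 2 = excess_mismatch.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector t1, CharacterVector q1,
                     CharacterVector t2rc, CharacterVector q2rc,
                     int min_overlap, double max_mm_frac) {
    int n = t1.size();
    IntegerVector status(n), overlap(n), mism(n);
    CharacterVector merged(n), mqual(n);
    for (int i = 0; i < n; ++i) {
        std::string a = as<std::string>(t1[i]),  qa = as<std::string>(q1[i]);
        std::string b = as<std::string>(t2rc[i]), qb = as<std::string>(q2rc[i]);
        int la = a.size(), lb = b.size();
        int omax = std::min(la, lb);
        if (omax < min_overlap) { status[i] = 1; merged[i] = ""; mqual[i] = ""; continue; }
        int best_o = -1, best_mm = -1;
        double best_frac = 2.0;
        for (int o = min_overlap; o <= omax; ++o) {
            int mm = 0;
            const char* pa = a.data() + (la - o);
            const char* pb = b.data();
            for (int k = 0; k < o; ++k) if (pa[k] != pb[k]) ++mm;
            double frac = (double)mm / o;
            if (frac <= max_mm_frac &&
                (frac < best_frac || (frac == best_frac && o > best_o))) {
                best_frac = frac; best_o = o; best_mm = mm;
            }
        }
        if (best_o < 0) { status[i] = 2; merged[i] = ""; mqual[i] = ""; continue; }
        int o = best_o;
        std::string ms = a.substr(0, la - o);
        std::string qs = qa.substr(0, la - o);
        for (int k = 0; k < o; ++k) {
            char ca = a[la - o + k], cb = b[k];
            char qca = qa[la - o + k], qcb = qb[k];
            if (ca == cb) { ms += ca; qs += std::max(qca, qcb); }
            else if (qca >= qcb) { ms += ca; qs += qca; }
            else { ms += cb; qs += qcb; }
        }
        ms += b.substr(o); qs += qb.substr(o);
        status[i] = 0; overlap[i] = o; mism[i] = best_mm;
        merged[i] = ms; mqual[i] = qs;
    }
    return List::create(_["status"] = status, _["merged"] = merged,
                        _["quality"] = mqual, _["overlap"] = overlap,
                        _["mismatches"] = mism);
}

// Longest common prefix / suffix lengths of a query against each reference
// (equal lengths assumed), used by the bimera test: q is a chimera of refs
// (i, j) iff lcp(q, ref_i) + lcs(q, ref_j) >= len.
// [[Rcpp::export]]
List lcp_lcs_cpp(std::string q, CharacterVector refs) {
    int n = refs.size(), L = q.size();
    IntegerVector lcp(n), lcs(n);
    for (int i = 0; i < n; ++i) {
        std::string r = as<std::string>(refs[i]);
        if ((int)r.size() != L) { lcp[i] = -1; lcs[i] = -1; continue; }
        int p = 0; while (p < L && q[p] == r[p]) ++p;
        int s = 0; while (s < L && q[L - 1 - s] == r[L - 1 - s]) ++s;
        lcp[i] = p; lcs[i] = s;
    }
    return List::create(_["lcp"] = lcp, _["lcs"] = lcs);
}
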