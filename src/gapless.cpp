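#include <Rcpp.h>
using namespace Rcpp;

// Maximal-scoring ungapped local alignment between every pair (s_i, e_j):
// the maximum, over all equal-length contiguous substring pairs (length >= 1),
// of the summed substitution scores. Implemented per diagonal with a
// maximum-subarray scan, which enumerates exactly the ungapped alignments.
// [[Rcpp::export]]
IntegerMatrix cppGaplessScores(CharacterVector s, CharacterVector e,
                               IntegerMatrix mat, std::string alphabet) {
    const int ns = s.size(), ne = e.size(), na = alphabet.size();
    if (mat.nrow() != na || mat.ncol() != na)
        stop("substitution matrix does not match the alphabet");
    int code[256];
    for (int i = 0; i < 256; ++i) code[i] = -1;
    for (int i = 0; i < na; ++i) code[(unsigned char)alphabet[i]] = i;

    std::vector<std::vector<int> > senc(ns), eenc(ne);
    for (int i = 0; i < ns; ++i) {
        std::string x = as<std::string>(s[i]);
        senc[i].resize(x.size());
        for (size_t p = 0; p < x.size(); ++p) {
            int c = code[(unsigned char)x[p]];
            if (c < 0) stop("character '%s' outside the matrix alphabet",
                            std::string(1, x[p]).c_str());
            senc[i][p] = c;
        }
    }
    for (int j = 0; j < ne; ++j) {
        std::string x = as<std::string>(e[j]);
        eenc[j].resize(x.size());
        for (size_t p = 0; p < x.size(); ++p) {
            int c = code[(unsigned char)x[p]];
            if (c < 0) stop("character '%s' outside the matrix alphabet",
                            std::string(1, x[p]).c_str());
            eenc[j][p] = c;
        }
    }

    IntegerMatrix out(ns, ne);
    for (int i = 0; i < ns; ++i) {
        const std::vector<int>& a = senc[i];
        const int la = a.size();
        for (int j = 0; j < ne; ++j) {
            const std::vector<int>& b = eenc[j];
            const int lb = b.size();
            int best = INT_MIN;
            for (int d = -(la - 1); d <= lb - 1; ++d) {
                // s position p aligns with e position p + d
                int p0 = d < 0 ? -d : 0;
                int p1 = std::min(la - 1, lb - 1 - d);
                int run = 0;
                for (int p = p0; p <= p1; ++p) {
                    int sc = mat(a[p], b[p + d]);
                    run = run > 0 ? run + sc : sc;
                    if (run > best) best = run;
                }
            }
            out(i, j) = best;
        }
    }
    return out;
}
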