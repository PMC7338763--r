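#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Deterministic traceback: on score ties prefer diagonal, then up
// (consume a), then left (consume b).
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = 0.0,
                  double gap = -1.0) {
    const int n = a.size(), m = b.size();
    NumericMatrix S(n + 1, m + 1);
    IntegerMatrix P(n + 1, m + 1);   // 0 diag, 1 up, 2 left
    for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; P(i, 0) = 1; }
    for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; P(0, j) = 2; }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double d = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
            double u = S(i - 1, j) + gap;
            double l = S(i, j - 1) + gap;
            double best = d; int ptr = 0;
            if (u > best) { best = u; ptr = 1; }
            if (l > best) { best = l; ptr = 2; }
            S(i, j) = best; P(i, j) = ptr;
        }
    }
    std::string ra, rb;
    ra.reserve(n + m); rb.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        int ptr = P(i, j);
        if (i > 0 && j > 0 && ptr == 0) {
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
        } else if (i > 0 && (ptr == 1 || j == 0)) {
            ra.push_back(a[i - 1]); rb.push_back('-'); --i;
        } else {
            ra.push_back('-'); rb.push_back(b[j - 1]); --j;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    int matches = 0;
    for (size_t k = 0; k < ra.size(); ++k) {
        if (ra[k] == rb[k] && ra[k] != '-') ++matches;
    }
    return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                        _["score"] = S(n, m), _["matches"] = matches,
                        _["length"] = (int)ra.size());
}
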