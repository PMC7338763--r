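#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive tandem decomposition of one sequence at fixed unit length u:
// over all start offsets, take the longest run of consecutive copies whose
// per-copy mismatch against the positionwise-majority consensus (ties to
// the alphabetically first residue) stays within max_mismatch. Returns the
// run covering the most residues; ties go to the earliest start.
// x: residue codes 0..25.
// [[Rcpp::export(name = ".best_run_cpp")]]
List best_run_cpp(IntegerVector x, int u, int max_mismatch) {
    const int n = x.size();
    int best_cov = 0, best_k = 0, best_s = NA_INTEGER;
    if (n >= 2 * u) {
        std::vector<int> counts(26 * u);
        for (int s = 0; s + 2 * u <= n; ++s) {
            int kmax = (n - s) / u;
            for (int k = kmax; k >= 2; --k) {
                if (k * u <= best_cov && best_s != NA_INTEGER) {
                    // cannot beat the incumbent from this (s, k) downwards
                    if (k * u < best_cov) break;
                }
                std::fill(counts.begin(), counts.end(), 0);
                for (int c = 0; c < k; ++c)
                    for (int j = 0; j < u; ++j)
                        ++counts[j * 26 + x[s + c * u + j]];
                bool ok = true;
                std::vector<int> cons(u);
                for (int j = 0; j < u; ++j) {
                    int bi = 0, bc = -1;
                    for (int a = 0; a < 26; ++a) {
                        if (counts[j * 26 + a] > bc) { bc = counts[j * 26 + a]; bi = a; }
                    }
                    cons[j] = bi;
                }
                for (int c = 0; c < k && ok; ++c) {
                    int mm = 0;
                    for (int j = 0; j < u; ++j)
                        if (x[s + c * u + j] != cons[j]) ++mm;
                    if (mm > max_mismatch) ok = false;
                }
                if (ok) {
                    if (k * u > best_cov) {
                        best_cov = k * u; best_k = k; best_s = s + 1;
                    }
                    break;   // longest passing run at this offset found
                }
            }
        }
    }
    return List::create(_["covered"] = best_cov, _["copies"] = best_k,
                        _["start"] = best_s);
}
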