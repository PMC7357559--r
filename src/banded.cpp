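#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Banded global alignment of two equal-ish length sequences, maximising the
// number of matched columns. Gap columns are scored as mismatches, so the
// percent identity reported downstream is 100 * matches / alignment_columns
// with alignment_columns = len(a) + gaps inserted into a.
//
// Band constraint: |i - j| <= band. Ties between equal-match paths are broken
// toward fewer gap columns, so an ungapped alignment is preferred when it
// attains the same match count.

static const int NEG = -1000000;

// [[Rcpp::export]]
List banded_align_cpp(std::string a, std::string b, int band) {
    int m = a.size(), n = b.size();
    if (m == 0 || n == 0) stop("empty sequence in banded alignment");
    if (std::abs(m - n) > band) stop("length difference exceeds band");
    int w = 2 * band + 1;
    // M[i][k]: best matches aligning a[1..i] with b[1..j], j = i + (k - band)
    std::vector<std::vector<int> > M(m + 1, std::vector<int>(w, NEG));
    std::vector<std::vector<int> > G(m + 1, std::vector<int>(w, 0)); // gap cols on best path
    M[0][band] = 0;
    for (int k = band + 1; k < w; ++k) { // leading gaps in a (j > i = 0)
        int j = k - band;
        if (j > n) break;
        M[0][k] = 0; G[0][k] = j;
    }
    for (int i = 1; i <= m; ++i) {
        for (int k = 0; k < w; ++k) {
            int j = i + (k - band);
            if (j < 0 || j > n) continue;
            if (j == 0) { M[i][k] = 0; G[i][k] = i; continue; }
            int bestM = NEG, bestG = 0;
            // diagonal: consume a[i], b[j]
            if (M[i - 1][k] > NEG) {
                int mm = M[i - 1][k] + (a[i - 1] == b[j - 1] ? 1 : 0);
                if (mm > bestM || (mm == bestM && G[i - 1][k] < bestG)) {
                    bestM = mm; bestG = G[i - 1][k];
                }
            }
            // gap in b: consume a[i] (k decreases by 1 relative to i-1)
            if (k + 1 < w && M[i - 1][k + 1] > NEG) {
                int mm = M[i - 1][k + 1];
                int gg = G[i - 1][k + 1] + 1;
                if (mm > bestM || (mm == bestM && gg < bestG)) { bestM = mm; bestG = gg; }
            }
            // gap in a: consume b[j]
            if (k - 1 >= 0 && M[i][k - 1] > NEG) {
                int mm = M[i][k - 1];
                int gg = G[i][k - 1] + 1;
                if (mm > bestM || (mm == bestM && gg < bestG)) { bestM = mm; bestG = gg; }
            }
            M[i][k] = bestM; G[i][k] = bestG;
        }
    }
    int kend = band + (n - m);
    if (kend < 0 || kend >= w) stop("band too narrow for endpoint");
    int matches = M[m][kend], gaps = G[m][kend];
    int cols = m + (gaps + (n - m)) / 2 + std::max(0, n - m); // columns = m + gaps-in-a
    // gaps-in-a = (gaps + (n - m)) / 2 when counting both sides; derive directly:
    // g_a - g_b = n - m and g_a + g_b = gaps  =>  g_a = (gaps + n - m) / 2
    cols = m + (gaps + n - m) / 2;
    double ident = 100.0 * matches / cols;
    return List::create(_["matches"] = matches, _["gaps"] = gaps,
                        _["columns"] = cols, _["identity"] = ident);
}

// Identity of a banded alignment between `ref` and the window of `subject`
// starting at every position (1-based), window width = len(ref).
// [[Rcpp::export]]
NumericVector slide_banded_identity_cpp(std::string ref, std::string subject, int band) {
    int m = ref.size(), n = subject.size();
    if (m > n) return NumericVector(0);
    int nstart = n - m + 1;
    NumericVector out(nstart);
    for (int s = 0; s < nstart; ++s) {
        std::string win = subject.substr(s, m);
        List r = banded_align_cpp(ref, win, band);
        out[s] = as<double>(r["identity"]);
    }
    return out;
}

// Hamming mismatch count of `ref` against the subject window starting at
// every position; -1 where the window runs off the end.
// [[Rcpp::export]]
IntegerVector slide_hamming_cpp(std::string ref, std::string subject) {
    int m = ref.size(), n = subject.size();
    if (m > n) return IntegerVector(0);
    int nstart = n - m + 1;
    IntegerVector out(nstart);
    for (int s = 0; s < nstart; ++s) {
        int mm = 0;
        for (int i = 0; i < m; ++i) if (ref[i] != subject[s + i]) ++mm;
        out[s] = mm;
    }
    return out;
}
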