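#include <Rcpp.h>
using namespace Rcpp;

// Symmetric-step DTW (steps: diagonal, horizontal, vertical; unit weights),
// absolute-difference local cost, no warping window.
static double dtw_cost(const double* a, int n, const double* b, int m) {
    std::vector<double> prev(m + 1, R_PosInf), cur(m + 1);
    prev[0] = 0.0;
    for (int i = 1; i <= n; ++i) {
        cur[0] = R_PosInf;
        for (int j = 1; j <= m; ++j) {
            double d = std::abs(a[i - 1] - b[j - 1]);
            double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
            cur[j] = d + best;
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

// [[Rcpp::export(name = ".dtw_pair")]]
double dtw_pair(NumericVector a, NumericVector b) {
    if (a.size() == 0 || b.size() == 0)
        stop("DTW requires nonempty contours");
    return dtw_cost(a.begin(), a.size(), b.begin(), b.size());
}

// contours as rows of a matrix (equal length); returns full symmetric matrix
// [[Rcpp::export(name = ".dtw_matrix")]]
NumericMatrix dtw_matrix(NumericMatrix x) {
    int n = x.nrow(), m = x.ncol();
    if (m == 0) stop("DTW requires nonempty contours");
    NumericMatrix out(n, n);
    std::vector<double> row_i(m), row_j(m);
    for (int i = 0; i < n; ++i) {
        for (int k = 0; k < m; ++k) row_i[k] = x(i, k);
        for (int j = i + 1; j < n; ++j) {
            for (int k = 0; k < m; ++k) row_j[k] = x(j, k);
            double d = dtw_cost(row_i.data(), m, row_j.data(), m);
            out(i, j) = d;
            out(j, i) = d;
        }
    }
    return out;
}
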