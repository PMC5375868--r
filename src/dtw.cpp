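#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Classic dynamic-time-warping alignment cost between two multichannel
// sequences (rows = time frames, columns = channels).  Local cost is the
// Euclidean distance between frames; step set {(1,0),(0,1),(1,1)};
// boundary-anchored; no warping window; cost not normalized by path length.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(const arma::mat& a, const arma::mat& b) {
    const arma::uword n = a.n_rows, m = b.n_rows;
    if (n == 0 || m == 0)
        Rcpp::stop("dtw: empty sequence");
    if (a.n_cols != b.n_cols)
        Rcpp::stop("dtw: frame dimensionality differs");

    // local cost matrix via the |a|^2 + |b|^2 - 2 a.b expansion (BLAS-bound)
    arma::vec an = arma::sum(arma::square(a), 1);
    arma::rowvec bn = arma::sum(arma::square(b), 1).t();
    arma::mat C = -2.0 * (a * b.t());
    C.each_col() += an;
    C.each_row() += bn;
    C.transform([](double v) { return v > 0.0 ? std::sqrt(v) : 0.0; });

    arma::vec prev(m), cur(m);
    prev(0) = C(0, 0);
    for (arma::uword j = 1; j < m; ++j) prev(j) = prev(j - 1) + C(0, j);
    for (arma::uword i = 1; i < n; ++i) {
        cur(0) = prev(0) + C(i, 0);
        for (arma::uword j = 1; j < m; ++j) {
            double best = prev(j);                      // (1,0)
            if (cur(j - 1) < best) best = cur(j - 1);   // (0,1)
            if (prev(j - 1) < best) best = prev(j - 1); // (1,1)
            cur(j) = C(i, j) + best;
        }
        prev = cur;
    }
    return prev(m - 1);
}
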