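#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Cyclic coordinate descent for  min_z ||V z - y||^2 + lambda ||z||_1,
// parameterized by the Gram matrix G = V'V and b = V'y.  Soft threshold
// at lambda/2 (the subgradient step for the un-halved objective).
// [[Rcpp::export(name = ".lasso_cd_gram")]]
arma::vec lasso_cd_gram(const arma::mat& G, const arma::vec& b,
                        double lambda, arma::vec z,
                        double tol, int max_iter) {
    const arma::uword p = b.n_elem;
    const double thr = lambda / 2.0;
    for (int it = 0; it < max_iter; ++it) {
        double delta = 0.0;
        for (arma::uword j = 0; j < p; ++j) {
            const double gjj = G(j, j);
            if (gjj <= 0.0) { z(j) = 0.0; continue; }
            const double rho = b(j) - arma::dot(G.col(j), z) + gjj * z(j);
            double znew = 0.0;
            if (rho > thr) znew = (rho - thr) / gjj;
            else if (rho < -thr) znew = (rho + thr) / gjj;
            const double d = std::abs(znew - z(j));
            if (d > delta) delta = d;
            z(j) = znew;
        }
        if (delta < tol) break;
    }
    return z;
}
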