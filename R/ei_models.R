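# One-dimensional evaluation-indicator models.  Each per-task feature
# matrix V (one row per repetition, 19 columns) is factorized as
# V ~ W H with the reduced dimension fixed at 1, so that each row maps to a
# single raw score.  Unsupervised routes: PCA (leading eigenvector of the
# covariance of the centered matrix), metric MDS under Sammon's stress
# criterion, and NMF with multiplicative updates.  Supervised route: LASSO
# regression of the FMUE-related item scores on the features.

#' Fixed feature-column schema of the per-task feature matrix
#'
#' Seven preliminary indicators followed by the twelve supplementary
#' features, in the documented order.
#' @return character vector of 19 column names.
#' @export
feature_columns <- function() c(
    "pcc", "dtw", "eucl_emg_power", "eucl_acc1", "eucl_acc2",
    "eucl_gyro1", "eucl_gyro2", "duration", "extremum_count",
    "acc_ratio", "gyro_ratio", "mean_acc1", "mean_acc2",
    "mean_gyro1", "mean_gyro2", "max_acc1", "max_acc2",
    "max_gyro1", "max_gyro2")

.check_feature_matrix <- function(v) {
    v <- as.matrix(v)
    if (!identical(colnames(v), feature_columns()))
        stop("feature matrix must have the 19 documented columns in order")
    if (anyNA(v)) stop("NaN/NA in feature matrix")
    v
}

#' Leading-component PCA factorization
#'
#' Centers the matrix and extracts the leading eigenvector of its covariance
#' matrix; scores are the projections of the centered rows.
#'
#' @param v numeric matrix, rows = observations.
#' @return list with `transform` (unit n-vector), `center`, `scores`,
#'   `eigenvalue`.
#' @export
fit_pca <- function(v) {
    v <- as.matrix(v)
    if (nrow(v) < 2L) stop("PCA needs at least 2 rows")
    mu <- colMeans(v)
    vc <- sweep(v, 2, mu)
    cv <- stats::cov(vc)
    if (all(abs(cv) < 1e-300)) stop("zero-variance matrix")
    e <- eigen(cv, symmetric = TRUE)
    h <- e$vectors[, 1]
    list(transform = h, center = mu, scores = drop(vc %*% h),
         eigenvalue = e$values[1])
}

#' Sammon stress of a 1-D (or k-D) embedding
#'
#' `Stress = (1 / sum d*) * sum (d* - d)^2 / d*` over all pairs `i < j`,
#' where `d*` are the original and `d` the embedded distances.
#'
#' @param dstar `dist` (or vector) of original pairwise distances.
#' @param d `dist` (or vector) of embedded pairwise distances.
#' @return scalar stress (0 for a perfect embedding).
#' @export
sammon_stress <- function(dstar, d) {
    dstar <- as.numeric(dstar); d <- as.numeric(d)
    sum((dstar - d)^2 / dstar) / sum(dstar)
}

#' Metric MDS with Sammon's criterion, 1-D
#'
#' Embeds the rows in one dimension by iterative minimization of Sammon's
#' stress, starting from both the PCA projection and a seeded jittered
#' start, keeping the better solution.  Because the embedding alone gives no
#' out-of-sample rule, an ordinary least-squares linear map from the feature
#' space to the embedding is fitted and stored as the transform.
#'
#' @param v numeric matrix, rows = observations (duplicate rows are
#'   perturbed by a seeded 1e-9 jitter before distances are computed).
#' @param seed integer seed for the jittered start.
#' @param tol relative stress-change tolerance.
#' @param max_iter maximum optimizer iterations.
#' @return list with `transform` (n-vector), `offset`, `embedding`, `stress`,
#'   `stress_pca_start` and `converged`.
#' @export
fit_mds <- function(v, seed = 1L, tol = 1e-8, max_iter = 2000L) {
    v <- as.matrix(v)
    m <- nrow(v)
    if (m < 3L) stop("MDS needs at least 3 rows")
    dstar <- stats::dist(v)
    if (any(dstar == 0)) {
        set.seed(seed)
        v <- v + matrix(rnorm(length(v), sd = 1e-9), nrow(v))
        dstar <- stats::dist(v)
    }
    init <- matrix(fit_pca(v)$scores, ncol = 1)
    if (sd(init) == 0) init <- init + seq_len(m) * 1e-9
    run <- function(y0) tryCatch(
        MASS::sammon(dstar, y = y0, k = 1, niter = max_iter, tol = tol,
                     trace = FALSE),
        error = function(e) NULL)
    set.seed(seed)
    jit <- init + matrix(rnorm(m, sd = 0.1 * max(sd(init), 1e-6)), ncol = 1)
    cands <- Filter(Negate(is.null), list(run(init), run(jit)))
    stress_pca <- sammon_stress(dstar, stats::dist(init))
    if (length(cands) == 0L) {
        emb <- drop(init)
        stress <- stress_pca
        warning("Sammon optimizer failed; PCA start retained (stress ",
                signif(stress, 4), ")")
    } else {
        st <- vapply(cands, function(cc) sammon_stress(dstar, stats::dist(cc$points)), 0)
        best <- which.min(st)
        emb <- drop(cands[[best]]$points)
        stress <- st[best]
        if (stress > stress_pca + 1e-12) { # optimizer sanity fallback
            emb <- drop(init)
            stress <- stress_pca
        }
    }
    fit <- stats::lm.fit(cbind(1, v), emb)
    list(transform = fit$coefficients[-1], offset = fit$coefficients[1],
         embedding = emb, stress = stress, stress_pca_start = stress_pca,
         converged = length(cands) > 0L)
}

#' Rank-1 NMF by multiplicative updates
#'
#' Factorizes a non-negative matrix as `V ~ W H` with `W` (m x 1) and `H`
#' (1 x n) non-negative, using the multiplicative Frobenius update rules
#' with a per-sweep normalization of the `W` column (compensated in `H` so
#' the product, and hence the reconstruction error, is unchanged).
#'
#' @param v non-negative numeric matrix.
#' @param seed integer seed for the random initialization.
#' @param sweeps number of update sweeps (default 200).
#' @return list with `w` (m-vector), `h` (n-vector), `errors` (Frobenius
#'   reconstruction error after each sweep).
#' @export
fit_nmf <- function(v, seed = 1L, sweeps = 200L) {
    v <- as.matrix(v)
    if (any(v < 0)) stop("NMF input must be non-negative")
    if (all(v == 0)) stop("zero matrix")
    m <- nrow(v); n <- ncol(v)
    set.seed(seed)
    w <- matrix(runif(m, 0.1, 1), m, 1)
    h <- matrix(runif(n, 0.1, 1), 1, n)
    eps <- 1e-12
    errors <- numeric(sweeps)
    for (it in seq_len(sweeps)) {
        w <- w * (v %*% t(h)) / (w %*% (h %*% t(h)) + eps)
        h <- h * (t(w) %*% v) / ((t(w) %*% w) %*% h + eps)
        nw <- sqrt(sum(w^2))
        if (nw > 0) { w <- w / nw; h <- h * nw }
        errors[it] <- sqrt(sum((v - w %*% h)^2))
    }
    list(w = drop(w), h = drop(h), errors = errors)
}

# soft-threshold coordinate-descent solver for  ||Vz - y||^2 + lambda ||z||_1
.lasso_cd <- function(v, y, lambda, tol = 1e-12, max_iter = 100000L,
                      z0 = NULL) {
    v <- as.matrix(v)
    if (is.null(z0)) z0 <- numeric(ncol(v))
    drop(.lasso_cd_gram(crossprod(v), drop(crossprod(v, y)), lambda,
                        z0, tol, as.integer(max_iter)))
}

#' LASSO factorization of the feature matrix against item scores
#'
#' Solves `min_z ||V z - y||^2 + lambda ||z||_1` by coordinate descent.
#' When `lambda` is `NULL` it is selected by seeded 5-fold cross-validation
#' over a logarithmic grid.  An optional unpenalized intercept is handled by
#' centering.
#'
#' @param v numeric matrix (rows = repetitions).
#' @param y numeric vector of observations (FMUE-related item scores).
#' @param lambda penalty weight; `NULL` for cross-validated selection.
#' @param intercept include an unpenalized intercept (default `FALSE`).
#' @param seed seed for the cross-validation folds.
#' @param n_lambda,lambda_min_ratio grid size and lower end relative to the
#'   smallest penalty that zeroes all coefficients.
#' @return list with `transform` (z), `offset`, `lambda`, `fitted`.
#' @export
fit_lasso <- function(v, y, lambda = NULL, intercept = FALSE, seed = 1L,
                      n_lambda = 20L, lambda_min_ratio = 1e-3) {
    v <- as.matrix(v); y <- as.numeric(y)
    if (nrow(v) != length(y)) stop("y must align with the rows of v")
    if (sd(y) == 0) stop("all observations equal: no signal to fit")
    mu_v <- if (intercept) colMeans(v) else numeric(ncol(v))
    mu_y <- if (intercept) mean(y) else 0
    vc <- sweep(v, 2, mu_v); yc <- y - mu_y
    if (is.null(lambda)) {
        lmax <- 2 * max(abs(crossprod(vc, yc)))
        grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                        length.out = n_lambda))
        set.seed(seed)
        fold <- sample(rep_len(1:5, nrow(vc)))
        cv_err <- matrix(0, 5, n_lambda)
        for (k in 1:5) {   # warm starts down the path within each fold
            vt <- vc[fold != k, , drop = FALSE]; yt <- yc[fold != k]
            vv <- vc[fold == k, , drop = FALSE]; yv <- yc[fold == k]
            G <- crossprod(vt); b <- drop(crossprod(vt, yt))
            z <- numeric(ncol(vc))
            for (g in seq_along(grid)) {
                z <- drop(.lasso_cd_gram(G, b, grid[g], z, 1e-6, 2000L))
                cv_err[k, g] <- mean((yv - vv %*% z)^2)
            }
        }
        lambda <- grid[which.min(colMeans(cv_err))]
    }
    z <- .lasso_cd(vc, yc, lambda)
    offset <- mu_y - sum(mu_v * z)
    list(transform = z, offset = offset, lambda = lambda,
         fitted = drop(v %*% z) + offset)
}
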