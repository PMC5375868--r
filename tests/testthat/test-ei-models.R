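test_that("PCA factorization matches the closed-form and eigen oracles", {
    v <- cbind(c(1, 2, 3), c(1, 2, 3))
    f <- fit_pca(v)
    expect_equal(abs(f$scores), c(sqrt(2), 0, sqrt(2)), tolerance = 1e-12)
    expect_equal(var(f$scores), f$eigenvalue)   # score variance = eigenvalue
    expect_equal(f$eigenvalue, 2)
    # one informative column: transform is the unit vector on that column
    v2 <- cbind(rnorm(10), 0)
    f2 <- fit_pca(v2)
    expect_equal(abs(f2$transform), c(1, 0), tolerance = 1e-12)
    set.seed(41)
    v3 <- matrix(rnorm(100), 20, 5)
    f3 <- fit_pca(v3)
    pr <- prcomp(v3, center = TRUE, scale. = FALSE)
    s <- sign(sum(f3$transform * pr$rotation[, 1]))
    expect_equal(f3$scores, s * pr$x[, 1], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_error(fit_pca(matrix(1, 5, 3)), "zero-variance")
})

test_that("Sammon embedding honors the stress criterion", {
    # collinear points embed perfectly in 1-D
    line <- cbind(1:8, 2 * (1:8) + 3)
    f <- fit_mds(line, seed = 1)
    expect_lt(f$stress, 1e-6)
    # an equilateral triangle cannot: stress strictly positive
    tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
    expect_gt(fit_mds(tri, seed = 1)$stress, 1e-4)
    # optimizer is never worse than its PCA start
    set.seed(43)
    v <- matrix(rnorm(10 * 4), 10, 4)
    f2 <- fit_mds(v, seed = 2)
    expect_lte(f2$stress, f2$stress_pca_start + 1e-12)
    # the OLS out-of-sample map reproduces the training embedding closely
    pred <- drop(v %*% f2$transform) + f2$offset
    expect_gt(cor(pred, f2$embedding), 0.9)
})

test_that("NMF multiplicative updates converge with monotone error", {
    set.seed(47)
    w <- runif(12); h <- runif(5)
    f <- fit_nmf(outer(w, h), seed = 3, sweeps = 300)
    expect_lt(tail(f$errors, 1), 1e-8)
    expect_equal(abs(cor(f$w, w)), 1, tolerance = 1e-6)
    expect_true(all(f$w >= 0) && all(f$h >= 0))
    # independently recomputed Frobenius error is non-increasing
    v <- matrix(runif(15 * 6), 15, 6)
    f2 <- fit_nmf(v, seed = 5, sweeps = 200)
    expect_true(all(diff(f2$errors) <= 1e-10))
    expect_error(fit_nmf(matrix(0, 3, 3)), "zero matrix")
    expect_error(fit_nmf(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("LASSO solves the L1-penalized objective exactly", {
    # unpenalized square full-rank system: the exact linear solve
    set.seed(53)
    v <- matrix(rnorm(16), 4, 4); y <- rnorm(4)
    f0 <- fit_lasso(v, y, lambda = 0)
    expect_equal(f0$transform, drop(solve(v, y)), tolerance = 1e-8)
    # orthonormal design: closed-form soft thresholding at lambda/2
    f1 <- fit_lasso(diag(2), c(3, 1), lambda = 1)
    expect_equal(f1$transform, c(2.5, 0.5), tolerance = 1e-10)
    # total shrinkage at huge lambda
    f2 <- fit_lasso(v, y, lambda = 1e6)
    expect_equal(f2$transform, rep(0, 4))
    # orthonormal design: coefficients shrink monotonically along the path
    y8 <- rnorm(8)
    path <- sapply(c(0, 0.5, 1, 2, 4, 8), function(l)
        abs(fit_lasso(diag(8), y8, lambda = l)$transform))
    expect_true(all(apply(path, 1, function(r) all(diff(r) <= 1e-12))))
    expect_error(fit_lasso(v, rep(2, 4)), "no signal")
})

test_that("coordinate descent agrees with glmnet on random problems", {
    library(glmnet)
    set.seed(59)
    v <- scale(matrix(rnorm(60 * 6), 60, 6)); y <- rnorm(60)
    lam <- 3
    ours <- fit_lasso(v, y, lambda = lam)$transform
    # glmnet minimizes (1/2n)||y-Vz||^2 + lg||z||_1  =>  lg = lam / (2n)
    g <- glmnet(v, y, lambda = lam / (2 * nrow(v)), standardize = FALSE,
                intercept = FALSE, thresh = 1e-14)
    expect_equal(ours, as.numeric(g$beta), tolerance = 1e-5)
})

test_that("ei_model orients, normalizes to the full score and is consistent", {
    set.seed(61)
    v <- random_feature_matrix(60, seed = 61)
    healthy <- rep(c(TRUE, FALSE), 30)
    v[healthy, "pcc"] <- v[healthy, "pcc"] + 2   # healthy-high pcc structure
    v[, "dtw"] <- -2 * v[, "pcc"] + rnorm(60, sd = 0.1)
    for (m in c("pca", "nmf", "lasso")) {
        y <- if (m == "lasso") 4 + v[, "pcc"] + rnorm(60, sd = 0.2) else NULL
        fm <- ei_model(v, m, healthy = healthy, y = y, full_score = 8, seed = 9)
        ei <- predict(fm)
        # orientation: higher pcc rows score at least as well on average
        expect_gt(cor(ei, v[, "pcc"]), 0)
        # consistency: scoring a training row reproduces its training EI
        expect_equal(score_task(fm, v[7, , drop = FALSE]), ei[7])
        # the healthy-mean feature row maps to the full score
        centroid_raw <- mean(predict(fm, v[healthy, , drop = FALSE]))
        expect_true(all(ei >= 0 & ei <= 8))
        expect_gt(centroid_raw, 0)
    }
    fm <- ei_model(v, "pca", healthy = healthy, full_score = 8)
    bad <- v[1:3, 1:5]
    expect_error(score_task(fm, bad), "19")
})

test_that("a row at the healthy raw-score mean maps exactly to the full score", {
    set.seed(67)
    v <- random_feature_matrix(50, seed = 67)
    healthy <- rep(c(TRUE, FALSE), 25)
    v[healthy, "pcc"] <- v[healthy, "pcc"] + 3
    fm <- ei_model(v, "pca", healthy = healthy, full_score = 6)
    # construct a probe row whose raw score equals the healthy training
    # mean: the mean healthy feature row (linear transform => mean raw)
    probe <- matrix(colMeans(v[healthy, , drop = FALSE]), 1,
                    dimnames = list(NULL, feature_columns()))
    expect_equal(score_task(fm, probe), 6, tolerance = 1e-9)
})

test_that("validation metrics match their closed forms", {
    expect_equal(ndvr(c(8, 10, 12)), 39.2)
    expect_equal(ndvr(rep(5, 6)), 0)
    set.seed(71)
    x <- runif(20, 5, 10)
    expect_equal(ndvr(3 * x), ndvr(x))           # scale invariance
    expect_error(ndvr(c(-2, 1)), "positive")
    expect_equal(normal_range(rep(3, 4)), c(low = 3, high = 3))
    nr <- normal_range(x)
    expect_equal(unname(mean(nr)), mean(x))      # symmetric about the mean
    expect_equal(unname(nr["high"] - nr["low"]), 2 * 1.96 * sd(x))
    expect_equal(determination_coefficient(1:10, 2 * (1:10) + 3), 1.0)
    expect_equal(determination_coefficient(c(1, 2, 3), c(1, 2, 2)), 0.75)
    expect_equal(determination_coefficient(5 * x + 1, 2 * x - 7),
                 determination_coefficient(x, x))  # affine invariance
    flat <- determination_coefficient(rep(1, 5), 1:5)
    expect_equal(as.numeric(flat), 0)
    expect_true(isTRUE(attr(flat, "degenerate")))
})
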