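# Front end tying a factorization route to the per-task scoring contract:
# training-fold standardization (z-scores for PCA/MDS/LASSO, min-max for
# NMF), a deterministic orientation of the 1-D component (positive
# correlation with the pcc feature, a known higher-is-better column), and
# normalization of the raw score to the task's full score via the healthy
# training mean.

#' Fit a one-dimensional evaluation-indicator model for one task
#'
#' @param v per-task feature matrix: one row per repetition, the 19 columns
#'   of [feature_columns()] in order.
#' @param method `"pca"`, `"mds"`, `"nmf"` or `"lasso"`.
#' @param healthy logical vector, one entry per row of `v`: does the row
#'   come from a healthy subject?  The healthy training mean anchors the
#'   full-score normalization.
#' @param y FMUE-related item scores per row, required for `"lasso"`.
#' @param full_score the task's full score in points (default 2).
#' @param seed seed for the stochastic fits (MDS start, NMF initialization,
#'   LASSO CV folds).
#' @param config pipeline configuration, see [pipeline_config()].
#' @return an object of class `ei_model` with `print`, `coef` and `predict`
#'   methods.  `predict` returns component EIs in points on the task scale.
#' @examples
#' set.seed(7)
#' v <- matrix(rnorm(40 * 19), 40, 19, dimnames = list(NULL, feature_columns()))
#' m <- ei_model(v, "pca", healthy = rep(c(TRUE, FALSE), 20), full_score = 8)
#' head(predict(m, v))
#' @export
ei_model <- function(v, method = c("pca", "mds", "nmf", "lasso"),
                     healthy = NULL, y = NULL, full_score = 2,
                     seed = 1L, config = pipeline_config()) {
    method <- match.arg(method)
    v <- .check_feature_matrix(v)
    m <- nrow(v)
    if (is.null(healthy)) healthy <- rep(TRUE, m)
    if (length(healthy) != m) stop("healthy must have one entry per row")
    if (!any(healthy)) stop("at least one healthy training row is required")

    if (method == "nmf") {
        lo <- apply(v, 2, min); rg <- apply(v, 2, max) - lo
        rg[rg == 0] <- 1
        std <- list(kind = "minmax", lo = lo, rg = rg)
    } else {
        mu <- colMeans(v); sdv <- apply(v, 2, sd)
        sdv[sdv == 0] <- 1
        std <- list(kind = "z", mu = mu, sd = sdv)
    }
    vs <- .standardize(v, std)

    fit <- switch(method,
        pca = fit_pca(vs),
        mds = fit_mds(vs, seed = seed, tol = config$models$mds_tol,
                      max_iter = config$models$mds_max_iter),
        nmf = fit_nmf(vs, seed = seed, sweeps = config$models$nmf_sweeps),
        lasso = {
            if (is.null(y)) stop("lasso requires per-row item scores y")
            fit_lasso(vs, y, intercept = TRUE, seed = seed,
                      lambda = config$models$lambda)
        })

    model <- structure(
        list(method = method, std = std, fit = fit, full_score = full_score,
             seed = seed),
        class = "ei_model")
    raw <- .raw_scores(model, vs)

    # orientation: make the component correlate positively with pcc
    flip <- !is.na(cor(raw, v[, "pcc"])) && cor(raw, v[, "pcc"]) < 0
    if (flip) {
        if (method == "nmf") {
            model$reflect <- max(raw) + min(raw)   # raw' = reflect - raw
        } else {
            model$flip <- TRUE
        }
        raw <- .orient(model, raw)
    }
    m_h <- mean(raw[healthy])
    if (is.finite(m_h) && m_h <= 0) {
        # degenerate small fits can centre the healthy rows at or below
        # zero; shift the raw scale so the training minimum sits at zero
        model$shift <- -min(raw)
        raw <- raw + model$shift
        m_h <- mean(raw[healthy])
    }
    if (!is.finite(m_h) || m_h <= 0)
        stop("healthy training mean of the raw score is not positive; ",
             "cannot anchor the full-score normalization")
    model$healthy_mean <- m_h
    model$diagnostics <- switch(method,
        pca = list(eigenvalue = fit$eigenvalue),
        mds = list(stress = fit$stress, stress_pca_start = fit$stress_pca_start),
        nmf = list(reconstruction_error = tail(fit$errors, 1)),
        lasso = list(lambda = fit$lambda, n_active = sum(fit$transform != 0)))
    model$training_ei <- score_task(model, v)
    model
}

.standardize <- function(v, std) {
    if (std$kind == "z")
        sweep(sweep(v, 2, std$mu), 2, std$sd, "/")
    else {
        vs <- sweep(sweep(v, 2, std$lo), 2, std$rg, "/")
        pmin(pmax(vs, 0), 1)    # clip out-of-range test rows for NMF
    }
}

.raw_scores <- function(model, vs) {
    fit <- model$fit
    switch(model$method,
        pca = drop(sweep(vs, 2, fit$center) %*% fit$transform),
        mds = drop(vs %*% fit$transform) + fit$offset,
        nmf = pmax(0, drop(vs %*% fit$h) / sum(fit$h^2)),
        lasso = drop(vs %*% fit$transform) + fit$offset)
}

.orient <- function(model, raw) {
    if (isTRUE(model$flip)) raw <- -raw
    if (!is.null(model$reflect)) raw <- model$reflect - raw
    raw
}

#' Score feature rows on the task's point scale
#'
#' Applies the model's training standardization and transform, orients the
#' raw score, and normalizes it so that the healthy training mean maps to
#' the task's full score; the result is clipped to `[0, full_score]`.
#'
#' @param model an [ei_model()].
#' @param rows feature matrix in the documented 19-column schema.
#' @return numeric vector of component EIs (points).
#' @export
score_task <- function(model, rows) {
    if (!inherits(model, "ei_model")) stop("model must be an ei_model")
    rows <- .check_feature_matrix(rows)
    raw <- .orient(model, .raw_scores(model, .standardize(rows, model$std)))
    if (!is.null(model$shift)) raw <- raw + model$shift
    ei <- model$full_score * raw / model$healthy_mean
    pmin(pmax(ei, 0), model$full_score)
}

#' @rdname score_task
#' @param object an `ei_model`.
#' @param newdata feature matrix to score; defaults to the training scores.
#' @param ... unused.
#' @export
predict.ei_model <- function(object, newdata = NULL, ...) {
    if (is.null(newdata)) return(object$training_ei)
    score_task(object, newdata)
}

#' @export
coef.ei_model <- function(object, ...) {
    tr <- switch(object$method,
        pca = object$fit$transform,
        mds = object$fit$transform,
        nmf = object$fit$h,
        lasso = object$fit$transform)
    names(tr) <- feature_columns()
    tr
}

#' @export
print.ei_model <- function(x, ...) {
    cat(sprintf("ei_model (%s), full score %g points\n", x$method, x$full_score))
    cat(sprintf("  healthy raw-score mean: %.4g\n", x$healthy_mean))
    d <- x$diagnostics
    cat("  diagnostics:",
        paste(names(d), signif(unlist(d), 4), sep = " = ", collapse = ", "),
        "\n")
    invisible(x)
}
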