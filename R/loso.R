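# Cohort preparation and the leave-one-subject-out (LOSO) evaluation
# harness.  prepare_cohort() runs the signal-processing stages once per
# trial (filter, segment, MDP + supplementary features) and caches the
# pairwise PCC/DTW/Euclidean quantities between every segment and every
# healthy segment; per-fold preliminary indicators are then exact
# max/min reductions over the fold's bank columns, identical to
# recomputing them against the reduced bank.

#' Run the signal-processing stages over a whole cohort
#'
#' @param x either a list of per-subject records (elements `meta`, `trials`,
#'   as returned by [generate_cohort()] or [read_session()]) or a session
#'   directory path.
#' @param config pipeline configuration, see [pipeline_config()].
#' @return an object of class `prepared_cohort`: per-subject metadata, the
#'   per-subject-task FMUE-related item scores, one record per detected
#'   repetition segment (motion data profile + supplementary features), and
#'   the pairwise similarity cache.
#' @export
prepare_cohort <- function(x, config = pipeline_config()) {
    records <- if (is.character(x)) read_session(x) else x
    task_set <- load_task_set(config$task_set)
    meta_rows <- list(); segments <- list()
    items <- matrix(NA_integer_, length(records), nrow(task_set),
                    dimnames = list(NULL, task_set$task_id))
    levels <- rep(NA_real_, length(records))
    for (i in seq_along(records)) {
        rec <- records[[i]]
        meta <- rec$meta
        meta_rows[[i]] <- data.frame(
            subject_id = meta$subject_id, group = meta$group,
            fmue_total = meta$fmue_total, age = meta$age, sex = meta$sex,
            stringsAsFactors = FALSE)
        items[i, names(meta$fmue_item_scores)] <- meta$fmue_item_scores
        if (!is.null(attr(meta, "impairment_level")))
            levels[i] <- attr(meta, "impairment_level")
        for (tr in rec$trials) {
            ptr <- preprocess_trial(tr, config)
            for (seg in segment_trial(ptr, config)) {
                segments[[length(segments) + 1L]] <- list(
                    subject_id = seg$subject_id, group = meta$group,
                    task_id = seg$task_id, repetition = seg$repetition,
                    onset_imu = seg$onset_imu, offset_imu = seg$offset_imu,
                    mdp = compute_mdp(seg, config),
                    features = supplementary_features(seg, config))
            }
        }
    }
    meta_df <- do.call(rbind, meta_rows)
    meta_df$impairment_level <- levels
    rownames(items) <- meta_df$subject_id
    prep <- structure(
        list(meta = meta_df, item_scores = items, segments = segments,
             task_set = task_set, config = config),
        class = "prepared_cohort")
    prep$cache <- .pairwise_cache(prep)
    prep
}

#' @export
print.prepared_cohort <- function(x, ...) {
    cat(sprintf("prepared_cohort: %d subjects (%d healthy), %d segments, %d tasks\n",
                nrow(x$meta), sum(x$meta$group == "healthy"),
                length(x$segments), nrow(x$task_set)))
    invisible(x)
}

# Euclidean cross-distance between rows of a and rows of b
.cross_dist <- function(a, b) {
    a <- as.matrix(a); b <- as.matrix(b)
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
}

# Per task: pairwise quantities between every segment (rows) and every
# healthy segment (columns).  DTW exploits symmetry among healthy pairs.
.pairwise_cache <- function(prep) {
    seg_task <- vapply(prep$segments, `[[`, 0L, "task_id")
    out <- list()
    for (t in prep$task_set$task_id) {
        idx <- which(seg_task == t)
        segs <- prep$segments[idx]
        subj <- vapply(segs, `[[`, "", "subject_id")
        healthy <- vapply(segs, function(s) s$group == "healthy", TRUE)
        hidx <- which(healthy)
        flat <- vapply(segs, function(s) as.numeric(s$mdp),
                       numeric(length(segs[[1]]$mdp)))
        pcc <- suppressWarnings(cor(flat, flat[, hidx, drop = FALSE]))
        pcc[is.na(pcc)] <- -Inf   # zero-variance pair: skipped in max
        dtw <- matrix(0, length(idx), length(hidx))
        hpos <- match(seq_along(idx), hidx) # row -> bank column (NA if stroke)
        for (r in seq_along(idx)) {
            sa <- t(segs[[r]]$mdp)
            for (cc in seq_along(hidx)) {
                hr <- hidx[cc]      # bank column cc is segment row hr
                if (!is.na(hpos[r]) && hr < r) {
                    dtw[r, cc] <- dtw[hr, hpos[r]]   # symmetric pair
                } else if (hr == r) {
                    dtw[r, cc] <- 0
                } else {
                    dtw[r, cc] <- .dtw_cost(sa, t(segs[[hr]]$mdp))
                }
            }
        }
        feat <- function(f) do.call(rbind, lapply(segs, f))
        ep <- feat(function(s) s$features$emg_power)
        out[[as.character(t)]] <- list(
            seg_index = idx, subjects = subj, bank_cols = hidx,
            bank_subjects = subj[hidx],
            pcc = pcc, dtw = dtw,
            e_emg = .cross_dist(ep, ep[hidx, , drop = FALSE]),
            e_acc1 = .cross_dist(feat(function(s) s$features$imu_power$acc1),
                                 feat(function(s) s$features$imu_power$acc1)[hidx, , drop = FALSE]),
            e_acc2 = .cross_dist(feat(function(s) s$features$imu_power$acc2),
                                 feat(function(s) s$features$imu_power$acc2)[hidx, , drop = FALSE]),
            e_gyro1 = .cross_dist(feat(function(s) s$features$imu_power$gyro1),
                                  feat(function(s) s$features$imu_power$gyro1)[hidx, , drop = FALSE]),
            e_gyro2 = .cross_dist(feat(function(s) s$features$imu_power$gyro2),
                                  feat(function(s) s$features$imu_power$gyro2)[hidx, , drop = FALSE]),
            supplementary = feat(function(s) c(
                duration = s$features$duration,
                extremum_count = s$features$extremum_count,
                s$features$intensity_ratios,
                s$features$magnitude_stats[c("mean_acc1", "mean_acc2",
                                             "mean_gyro1", "mean_gyro2",
                                             "max_acc1", "max_acc2",
                                             "max_gyro1", "max_gyro2")]))
        )
    }
    out
}

#' Assemble the per-task feature matrix for one LOSO fold
#'
#' Builds the m x 19 feature matrix of one task, with the seven preliminary
#' indicator columns computed against the fold's reference bank: the
#' held-out subject is excluded everywhere, and each healthy row's own
#' subject is additionally excluded from its bank (the self-exclusion rule).
#'
#' @param prep a `prepared_cohort`.
#' @param task_id task to assemble.
#' @param heldout subject id excluded from every bank (`NULL` for none).
#' @return list with `v` (feature matrix), `subjects`, `healthy` (logical),
#'   `repetition`.
#' @export
assemble_features <- function(prep, task_id, heldout = NULL) {
    ca <- prep$cache[[as.character(task_id)]]
    if (is.null(ca)) stop("no segments for task ", task_id)
    m <- length(ca$seg_index)
    healthy_subjects <- unique(ca$bank_subjects)
    v <- matrix(NA_real_, m, 19, dimnames = list(NULL, feature_columns()))
    for (r in seq_len(m)) {
        banned <- heldout
        if (ca$subjects[r] %in% healthy_subjects)
            banned <- c(banned, ca$subjects[r])
        cols <- which(!(ca$bank_subjects %in% banned))
        if (length(cols) == 0L)
            stop("empty reference bank for a row of task ", task_id)
        v[r, 1:7] <- c(max(ca$pcc[r, cols]),
                       min(ca$dtw[r, cols]),
                       min(ca$e_emg[r, cols]),
                       min(ca$e_acc1[r, cols]),
                       min(ca$e_acc2[r, cols]),
                       min(ca$e_gyro1[r, cols]),
                       min(ca$e_gyro2[r, cols]))
    }
    v[, 8:19] <- ca$supplementary
    if (anyNA(v)) stop("missing indicator in feature matrix for task ", task_id)
    list(v = v, subjects = ca$subjects,
         healthy = ca$subjects %in% healthy_subjects,
         repetition = vapply(prep$segments[ca$seg_index], `[[`, 0L, "repetition"))
}

#' Normal data variation rate
#'
#' `100 * 1.96 * SD / mean` of the healthy subjects' EIs (percent); lower
#' values indicate a more consistent indicator across healthy subjects.
#'
#' @param healthy_eis numeric vector of healthy subjects' EIs.
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return NDVR in percent.
#' @export
ndvr <- function(healthy_eis, sd_convention = c("sample", "population")) {
    sd_convention <- match.arg(sd_convention)
    m <- mean(healthy_eis)
    if (m <= 0) stop("mean of healthy EIs must be positive")
    s <- .sd_conv(healthy_eis, sd_convention)
    100 * 1.96 * s / m
}

.sd_conv <- function(x, convention) {
    if (convention == "sample") sd(x)
    else sqrt(mean((x - mean(x))^2))
}

#' Normal range of healthy EIs
#'
#' @inheritParams ndvr
#' @return numeric 2-vector `(mean - 1.96 SD, mean + 1.96 SD)`.
#' @export
normal_range <- function(healthy_eis, sd_convention = c("sample", "population")) {
    sd_convention <- match.arg(sd_convention)
    m <- mean(healthy_eis); s <- .sd_conv(healthy_eis, sd_convention)
    c(low = m - 1.96 * s, high = m + 1.96 * s)
}

#' Determination coefficient between EIs and clinical scores
#'
#' R-squared of the ordinary least-squares simple linear regression of the
#' clinical scores on the EIs.
#'
#' @param eis numeric vector of evaluation indicators.
#' @param fmue_scores numeric vector of clinical (FMUE) scores.
#' @return R-squared in \[0, 1\]; a zero-variance predictor yields 0 with
#'   attribute `degenerate = TRUE`.
#' @export
determination_coefficient <- function(eis, fmue_scores) {
    if (sd(eis) == 0 || sd(fmue_scores) == 0)
        return(structure(0, degenerate = TRUE))
    suppressWarnings(summary(lm(fmue_scores ~ eis))$r.squared)
}

.fold_seed <- function(master_seed, fold, task) {
    as.integer((as.numeric(master_seed) * 7919 + fold * 131 + task * 17) %%
                   2147483647)
}

#' Leave-one-subject-out cohort evaluation
#'
#' Runs the full evaluation protocol: for each held-out subject, the
#' reference bank and (for the factorization methods) the per-task models
#' are rebuilt without any of that subject's data; the subject's component
#' EIs are the repetition-averaged test scores, and the global EI is their
#' sum over the 11 tasks.  Global EIs are then scaled by one cohort
#' expansion factor (66 divided by the healthy mean) so the healthy mean
#' lands on the 66-point FMUE scale, and the normal range, normal data
#' variation rate (NDVR) and determination coefficient (DC) are computed.
#'
#' @param prep a `prepared_cohort`.
#' @param method `"pcc"`, `"dtw"` (preliminary indicators) or `"pca"`,
#'   `"mds"`, `"nmf"`, `"lasso"` (factorization models).
#' @param master_seed master seed; per-fold, per-task seeds are derived from
#'   it.
#' @param config pipeline configuration.
#' @return an object of class `ei_cohort`: a per-subject results table
#'   (component EIs per task, global EI in FMUE-comparable points,
#'   `in_normal_range` flag) with the expansion factor, normal range, NDVR
#'   and DC as attributes.
#' @export
loso_evaluate <- function(prep, method = c("pcc", "dtw", "pca", "mds",
                                           "nmf", "lasso"),
                          master_seed = 1L, config = prep$config) {
    method <- match.arg(method)
    meta <- prep$meta
    n <- nrow(meta)
    if (sum(meta$group == "healthy") < 2L)
        stop("LOSO needs at least 2 healthy subjects")
    tasks <- prep$task_set$task_id
    comp <- matrix(NA_real_, n, length(tasks),
                   dimnames = list(meta$subject_id, paste0("task", tasks)))
    learned <- method %in% c("pca", "mds", "nmf", "lasso")
    for (j in seq_len(n)) {
        sid <- meta$subject_id[j]
        for (t in tasks) {
            af <- assemble_features(prep, t, heldout = sid)
            test <- af$subjects == sid
            if (!any(test)) next
            if (learned) {
                train <- !test
                if (length(unique(af$subjects[train & af$healthy])) < 2L)
                    stop("fold with fewer than 2 healthy training subjects")
                y <- if (method == "lasso")
                    prep$item_scores[af$subjects[train], as.character(t)]
                else NULL
                fm <- ei_model(af$v[train, , drop = FALSE], method,
                               healthy = af$healthy[train], y = y,
                               full_score = prep$task_set$full_score[
                                   prep$task_set$task_id == t],
                               seed = .fold_seed(master_seed, j, t),
                               config = config)
                comp[j, paste0("task", t)] <-
                    mean(score_task(fm, af$v[test, , drop = FALSE]))
            } else {
                comp[j, paste0("task", t)] <- mean(af$v[test, method])
            }
        }
    }
    global <- rowSums(comp)
    healthy <- meta$group == "healthy"
    expansion <- 66 / mean(global[healthy])
    scaled <- global * expansion
    conv <- config$models$sd_convention
    nr <- normal_range(scaled[healthy], conv)
    res <- data.frame(subject_id = meta$subject_id, group = meta$group,
                      fmue_total = meta$fmue_total,
                      comp, global_ei = scaled,
                      in_normal_range = scaled >= nr["low"] & scaled <= nr["high"],
                      stringsAsFactors = FALSE, row.names = NULL)
    structure(res, class = c("ei_cohort", "data.frame"),
              method = method, master_seed = master_seed,
              expansion_factor = expansion,
              normal_range = nr,
              ndvr = ndvr(scaled[healthy], conv),
              dc = determination_coefficient(scaled, meta$fmue_total),
              impairment_level = meta$impairment_level)
}

#' @export
print.ei_cohort <- function(x, ...) {
    cat(sprintf("ei_cohort: %d subjects, method %s\n", nrow(x), attr(x, "method")))
    cat(sprintf("  NDVR %.2f%%  DC %.4f  normal range [%.2f, %.2f]  expansion %.4g\n",
                attr(x, "ndvr"), attr(x, "dc"),
                attr(x, "normal_range")["low"], attr(x, "normal_range")["high"],
                attr(x, "expansion_factor")))
    print.data.frame(head(as.data.frame(x)[, c("subject_id", "group",
                                               "fmue_total", "global_ei",
                                               "in_normal_range")]))
    invisible(x)
}

#' @export
summary.ei_cohort <- function(object, ...) {
    out <- list(method = attr(object, "method"),
                ndvr = attr(object, "ndvr"),
                dc = attr(object, "dc"),
                normal_range = attr(object, "normal_range"),
                expansion_factor = attr(object, "expansion_factor"),
                n_subjects = nrow(object),
                n_healthy = sum(object$group == "healthy"),
                n_outside_range = sum(!object$in_normal_range))
    class(out) <- "summary.ei_cohort"
    out
}

#' @export
print.summary.ei_cohort <- function(x, ...) {
    cat(sprintf("Method: %s\n", x$method))
    cat(sprintf("Subjects: %d (%d healthy), %d outside the normal range\n",
                x$n_subjects, x$n_healthy, x$n_outside_range))
    cat(sprintf("NDVR: %.2f%%\nDC: %.4f\n", x$ndvr, x$dc))
    cat(sprintf("Normal range: [%.2f, %.2f] points (expansion factor %.4g)\n",
                x$normal_range["low"], x$normal_range["high"],
                x$expansion_factor))
    invisible(x)
}

#' Scatter plot of clinical score versus global EI
#'
#' Reproduces the standard result view: one point per subject in the
#' (EI, FMUE) plane, with the healthy normal range marked by dashed
#' vertical lines.
#'
#' @param x an `ei_cohort`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ei_cohort <- function(x, ...) {
    nr <- attr(x, "normal_range")
    pch <- ifelse(x$group == "healthy", 1, 2)
    graphics::plot(x$global_ei, x$fmue_total, pch = pch,
                   xlab = "global EI (points)", ylab = "FMUE score", ...)
    graphics::abline(v = nr, lty = 2)
    graphics::abline(v = mean(x$global_ei[x$group == "healthy"]), lty = 4)
    graphics::legend("bottomright", legend = c("healthy", "stroke"),
                     pch = c(1, 2), bty = "n")
    invisible(x)
}
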