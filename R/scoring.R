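# Preliminary evaluation indicators: similarity of a test repetition to the
# healthy reference bank.  The motion data profile is compared by Pearson
# correlation (max over the bank) and by DTW distance (min over the bank);
# the EMG and per-device IMU power distributions are compared by Euclidean
# distance (min over the bank).  Per-task indicators are the means over the
# available repetitions; seven components per task in total.

#' Dynamic time warping distance
#'
#' Boundary-anchored dynamic-programming alignment cost with step set
#' \{(1,0), (0,1), (1,1)\} and Euclidean frame distance; the cost is not
#' normalized by path length and no warping window is applied.
#'
#' @param a,b numeric vectors (univariate series) or matrices with one time
#'   frame per row; frame dimensionality must agree.
#' @return the alignment cost (0 for identical sequences).
#' @export
dtw_distance <- function(a, b) {
    if (is.null(dim(a))) a <- matrix(as.numeric(a), ncol = 1)
    if (is.null(dim(b))) b <- matrix(as.numeric(b), ncol = 1)
    if (nrow(a) == 0L || nrow(b) == 0L) stop("dtw: empty sequence")
    .dtw_cost(a, b)
}

#' Build a healthy reference bank for one task
#'
#' Collects the motion data profiles and power-distribution features of all
#' healthy repetitions of one task, optionally excluding subjects (the
#' leave-one-subject-out rule: a healthy test subject's own repetitions are
#' never part of their reference).
#'
#' @param prep a `prepared_cohort` from [prepare_cohort()].
#' @param task_id task to collect.
#' @param exclude character vector of subject ids to exclude.
#' @return an object of class `reference_bank` with elements `subject_ids`,
#'   `mdps` (list), `emg_power` (entries x 10), `acc1`, `acc2`, `gyro1`,
#'   `gyro2` (entries x 3).
#' @export
build_reference_bank <- function(prep, task_id, exclude = character()) {
    sel <- vapply(prep$segments, function(s)
        s$task_id == task_id && s$group == "healthy" &&
            !(s$subject_id %in% exclude), TRUE)
    segs <- prep$segments[sel]
    if (length(segs) == 0L) stop("empty reference bank for task ", task_id)
    structure(list(
        task_id = task_id,
        subject_ids = vapply(segs, `[[`, "", "subject_id"),
        mdps = lapply(segs, `[[`, "mdp"),
        emg_power = do.call(rbind, lapply(segs, function(s) s$features$emg_power)),
        acc1 = do.call(rbind, lapply(segs, function(s) s$features$imu_power$acc1)),
        acc2 = do.call(rbind, lapply(segs, function(s) s$features$imu_power$acc2)),
        gyro1 = do.call(rbind, lapply(segs, function(s) s$features$imu_power$gyro1)),
        gyro2 = do.call(rbind, lapply(segs, function(s) s$features$imu_power$gyro2))
    ), class = "reference_bank")
}

#' Pearson-correlation similarity to the reference bank
#'
#' Maximum Pearson correlation between the flattened test profile and each
#' flattened bank profile.  Pairs where either flattened vector has zero
#' variance are skipped; an error is raised if no valid pair remains.
#'
#' @param test_mdp 22 x 256 motion data profile.
#' @param bank a `reference_bank`, or a plain list of profiles.
#' @return maximum correlation, in \[-1, 1\].
#' @export
pcc_similarity <- function(test_mdp, bank) {
    mdps <- if (inherits(bank, "reference_bank")) bank$mdps else bank
    x <- as.numeric(test_mdp)
    if (sd(x) == 0) stop("zero-variance test profile")
    vals <- vapply(mdps, function(m) {
        y <- as.numeric(m)
        if (sd(y) == 0) NA_real_ else cor(x, y)
    }, 0)
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) stop("no valid bank entry for PCC")
    max(vals)
}

#' DTW similarity (distance) to the reference bank
#'
#' Minimum DTW distance between the test profile and the bank profiles,
#' treating the profile as a 22-channel sequence of 256 time frames.
#'
#' @inheritParams pcc_similarity
#' @return minimum DTW distance (>= 0).
#' @export
dtw_similarity <- function(test_mdp, bank) {
    mdps <- if (inherits(bank, "reference_bank")) bank$mdps else bank
    min(vapply(mdps, function(m) dtw_distance(t(test_mdp), t(m)), 0))
}

#' Euclidean distance from a power-distribution vector to the bank
#'
#' @param test_vec fraction vector (sums to 1).
#' @param bank_vecs matrix with one bank distribution per row.
#' @return minimum Euclidean distance over the bank.
#' @export
power_distance <- function(test_vec, bank_vecs) {
    bank_vecs <- as.matrix(bank_vecs)
    min(sqrt(colSums((t(bank_vecs) - as.numeric(test_vec))^2)))
}

#' Preliminary evaluation indicators for one subject-task
#'
#' Scores each available repetition against the reference bank and averages:
#' PCC (max over bank) and DTW (min over bank) on the motion data profile,
#' and Euclidean distances (min over bank) for the EMG power distribution
#' and the four per-device IMU power distributions.
#'
#' @param segments list of per-repetition records, each with elements `mdp`
#'   and `features` (as produced by [prepare_cohort()]); 1--3 repetitions
#'   (fewer than 3 raises a warning).
#' @param bank a `reference_bank` for the same task.
#' @return named 7-vector: `pcc`, `dtw`, `eucl_emg_power`, `eucl_acc1`,
#'   `eucl_acc2`, `eucl_gyro1`, `eucl_gyro2`.
#' @export
preliminary_ei <- function(segments, bank) {
    if (length(segments) == 0L) stop("no repetitions to score")
    if (length(segments) < 3L)
        warning("fewer than 3 repetitions available (", length(segments), ")")
    per_rep <- vapply(segments, function(s) c(
        pcc = pcc_similarity(s$mdp, bank),
        dtw = dtw_similarity(s$mdp, bank),
        eucl_emg_power = power_distance(s$features$emg_power, bank$emg_power),
        eucl_acc1 = power_distance(s$features$imu_power$acc1, bank$acc1),
        eucl_acc2 = power_distance(s$features$imu_power$acc2, bank$acc2),
        eucl_gyro1 = power_distance(s$features$imu_power$gyro1, bank$gyro1),
        eucl_gyro2 = power_distance(s$features$imu_power$gyro2, bank$gyro2)
    ), numeric(7))
    rowMeans(per_rep)
}

#' Global preliminary evaluation indicator
#'
#' Direct sum of one indicator component over the 11 tasks, evaluating the
#' motor function of the entire upper limb.
#'
#' @param per_task matrix of per-task indicator vectors (tasks x components)
#'   or a data.frame with the indicator columns.
#' @param method which component to sum: `"pcc"` or `"dtw"`.
#' @return scalar sum over tasks.
#' @export
global_preliminary_ei <- function(per_task, method = c("pcc", "dtw")) {
    method <- match.arg(method)
    sum(as.data.frame(per_task)[[method]])
}
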