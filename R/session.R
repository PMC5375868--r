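#' Subject metadata record
#'
#' @param subject_id character id, unique within a session.
#' @param group `"healthy"` or `"stroke"`.
#' @param tested_side `"left"` or `"right"`.
#' @param fmue_total integer, total FMUE score on the 0--66 scale.
#' @param fmue_item_scores named integer vector of per-task FMUE-related item
#'   scores; names are task ids.  Each entry must not exceed the task's full
#'   score.
#' @param age years.
#' @param sex `"F"` or `"M"`.
#' @param task_set task set the item scores refer to (default [load_task_set()]).
#' @return an object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, group, tested_side, fmue_total,
                         fmue_item_scores, age, sex,
                         task_set = load_task_set()) {
    group <- match.arg(group, c("healthy", "stroke"))
    tested_side <- match.arg(tested_side, c("left", "right"))
    sex <- match.arg(sex, c("F", "M"))
    fmue_total <- as.integer(fmue_total)
    if (fmue_total < 0L || fmue_total > 66L)
        stop("fmue_total must lie in [0, 66]")
    items <- as.integer(fmue_item_scores)
    names(items) <- names(fmue_item_scores)
    idx <- match(as.integer(names(items)), task_set$task_id)
    if (anyNA(idx))
        stop("fmue_item_scores has task ids outside the task set")
    if (any(items < 0L) || any(items > task_set$full_score[idx]))
        stop("item scores must lie in [0, full_score] for each task")
    if (group == "healthy") {
        if (fmue_total != 66L || !all(items == task_set$full_score[idx]))
            stop("healthy subjects must have fmue_total 66 and full item scores")
    }
    structure(
        list(subject_id = as.character(subject_id), group = group,
             tested_side = tested_side, fmue_total = fmue_total,
             fmue_item_scores = items, age = as.numeric(age), sex = sex),
        class = "subject_meta"
    )
}

#' Single-trial multi-channel recording
#'
#' One continuous recording of a subject performing one task (nominally three
#' repetitions).  Channel conventions are fixed: EMG channels 1--8 form the
#' forearm ring, 9 is biceps, 10 is triceps; IMU1 sits on the forearm and
#' IMU2 on the upper arm.  Units: EMG in millivolts, accelerometer in g,
#' gyroscope in degrees/second.
#'
#' @param subject_id,task_id identifiers.
#' @param emg numeric matrix, samples x 10 channels, sampled at `emg_rate`.
#' @param acc1,acc2,gyro1,gyro2 numeric matrices, samples x 3 axes, sampled
#'   at `imu_rate`.
#' @param emg_rate,imu_rate sampling rates in Hz; the EMG/IMU sample-count
#'   ratio must equal `emg_rate / imu_rate`.
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, task_id, emg, acc1, gyro1, acc2, gyro2,
                            emg_rate = 1000, imu_rate = 100) {
    emg <- as.matrix(emg)
    acc1 <- as.matrix(acc1); acc2 <- as.matrix(acc2)
    gyro1 <- as.matrix(gyro1); gyro2 <- as.matrix(gyro2)
    if (ncol(emg) != 10L) stop("emg must have 10 channels")
    for (m in list(acc1, acc2, gyro1, gyro2))
        if (ncol(m) != 3L) stop("IMU component matrices must have 3 axes")
    n_imu <- nrow(acc1)
    if (!all(vapply(list(acc2, gyro1, gyro2), nrow, 0L) == n_imu))
        stop("all IMU components must share one length")
    ratio <- emg_rate / imu_rate
    if (nrow(emg) != n_imu * ratio)
        stop(sprintf("EMG length (%d) must equal %g x IMU length (%d)",
                     nrow(emg), ratio, n_imu))
    if (!all(vapply(list(emg, acc1, acc2, gyro1, gyro2),
                    function(m) all(is.finite(m)), TRUE)))
        stop("non-finite samples in trial recording")
    structure(
        list(subject_id = as.character(subject_id),
             task_id = as.integer(task_id),
             emg = emg, acc1 = acc1, gyro1 = gyro1, acc2 = acc2, gyro2 = gyro2,
             emg_rate = emg_rate, imu_rate = imu_rate),
        class = "trial_recording"
    )
}
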