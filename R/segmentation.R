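# Repetition segmentation from gyroscope activity.  The activity series
# S(t) is the sum of the two gyroscopes' instantaneous 3-axis vector
# magnitudes (deg/s).  Onset is the first sample with S(t) strictly above
# the threshold (default 3 deg/s); the repetition ends at the last
# above-threshold sample that is followed by a sub-threshold run of at
# least the hold time (default 2 s).  Shorter sub-threshold dips are
# bridged: a momentary drop does not interrupt a task performance.

#' Summed gyroscope vector-magnitude activity
#'
#' @param gyro1,gyro2 numeric matrices, samples x 3 axes, in deg/s.
#' @return numeric vector `S(t) = ||gyro1(t)|| + ||gyro2(t)||`, in deg/s.
#' @export
gyro_magnitude_sum <- function(gyro1, gyro2) {
    gyro1 <- as.matrix(gyro1); gyro2 <- as.matrix(gyro2)
    if (nrow(gyro1) != nrow(gyro2))
        stop("gyroscope series length mismatch")
    sqrt(rowSums(gyro1^2)) + sqrt(rowSums(gyro2^2))
}

#' Detect task-repetition boundaries in an activity series
#'
#' @param s activity series in deg/s (non-negative), sampled at `rate` Hz.
#' @param threshold detection threshold in deg/s (default 3).
#' @param hold_s required sub-threshold time after a repetition, in seconds
#'   (default 2); shorter dips are bridged.
#' @param min_segment_s minimum kept segment length in seconds (default 0.3);
#'   shorter bursts are discarded as twitches.
#' @param rate sampling rate in Hz (default 100).
#' @return integer matrix with columns `onset`, `offset` (1-based sample
#'   indices, inclusive) and attribute `open_ended`: logical per segment,
#'   `TRUE` when the record ended before a full hold could be observed.
#' @export
detect_segments <- function(s, threshold = 3, hold_s = 2, min_segment_s = 0.3,
                            rate = 100) {
    if (threshold <= 0) stop("threshold must be positive")
    s <- as.numeric(s)
    above <- s > threshold
    empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("onset", "offset")))
    if (!any(above)) return(structure(empty, open_ended = logical(0)))
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on_i <- which(r$values)
    onsets <- starts[on_i]
    offsets <- ends[on_i]
    hold_n <- round(hold_s * rate)
    # bridge above-runs separated by sub-hold dips
    keep_on <- onsets[1]; out_on <- integer(0); out_off <- integer(0)
    open_ended <- logical(0)
    cur_off <- offsets[1]
    if (length(on_i) > 1L) {
        for (k in 2:length(on_i)) {
            gap <- onsets[k] - cur_off - 1L
            if (gap >= hold_n) {
                out_on <- c(out_on, keep_on); out_off <- c(out_off, cur_off)
                open_ended <- c(open_ended, FALSE)
                keep_on <- onsets[k]
            }
            cur_off <- offsets[k]
        }
    }
    tail_gap <- length(s) - cur_off
    out_on <- c(out_on, keep_on); out_off <- c(out_off, cur_off)
    open_ended <- c(open_ended, tail_gap < hold_n)
    keep <- (out_off - out_on + 1L) >= round(min_segment_s * rate)
    structure(cbind(onset = out_on[keep], offset = out_off[keep]),
              open_ended = open_ended[keep])
}

#' Map segment boundaries between sample clocks
#'
#' Boundary indices detected on the IMU clock are carried to the EMG clock by
#' pure ratio scaling (the contract is stated on 0-based sample offsets:
#' `emg = imu * rate_ratio`).
#'
#' @param idx integer vector of 0-based boundary offsets on the IMU clock.
#' @param rate_ratio integer EMG/IMU rate ratio (default 10).
#' @return integer vector of 0-based offsets on the EMG clock.
#' @export
map_boundaries <- function(idx, rate_ratio = 10L) {
    idx <- as.integer(idx)
    if (any(idx < 0L)) stop("negative boundary index")
    idx * as.integer(rate_ratio)
}

#' Cut one trial into repetition segments
#'
#' Computes the gyroscope activity series from the (already filtered) trial,
#' detects repetition boundaries and restricts all 22 channels to each
#' repetition.  A well-formed repetition block yields 3 segments.
#'
#' @param trial a filtered [trial_recording()].
#' @param config pipeline configuration, see [pipeline_config()].
#' @return list of `segment` objects, each holding the 22 channel views
#'   (`emg`, `acc1`, `acc2`, `gyro1`, `gyro2`), boundary indices on both
#'   clocks and the sampling rates.  Warns when 0 or more than 3 segments
#'   are found.
#' @export
segment_trial <- function(trial, config = pipeline_config()) {
    sg <- config$segmentation
    s <- gyro_magnitude_sum(trial$gyro1, trial$gyro2)
    b <- detect_segments(s, threshold = sg$threshold_deg_per_s,
                         hold_s = sg$hold_s, min_segment_s = sg$min_segment_s,
                         rate = trial$imu_rate)
    n <- nrow(b)
    tid <- sprintf("subject %s task %d", trial$subject_id, trial$task_id)
    if (n == 0L) {
        warning("no segments detected for ", tid)
        return(list())
    }
    if (n > 3L) warning(n, " segments detected for ", tid, "; all kept")
    ratio <- trial$emg_rate / trial$imu_rate
    lapply(seq_len(n), function(k) {
        on <- unname(b[k, "onset"]); off <- unname(b[k, "offset"])
        # 0-based contract, then back to 1-based inclusive R slices
        on_e <- map_boundaries(on - 1L, ratio) + 1L
        off_e <- map_boundaries(off, ratio)
        structure(
            list(subject_id = trial$subject_id, task_id = trial$task_id,
                 repetition = k,
                 onset_imu = on, offset_imu = off,
                 onset_emg = on_e, offset_emg = off_e,
                 emg = trial$emg[on_e:off_e, , drop = FALSE],
                 acc1 = trial$acc1[on:off, , drop = FALSE],
                 acc2 = trial$acc2[on:off, , drop = FALSE],
                 gyro1 = trial$gyro1[on:off, , drop = FALSE],
                 gyro2 = trial$gyro2[on:off, , drop = FALSE],
                 emg_rate = trial$emg_rate, imu_rate = trial$imu_rate,
                 open_ended = attr(b, "open_ended")[k]),
            class = "segment"
        )
    })
}
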