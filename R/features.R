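# Feature extraction from one repetition segment: the 22 x 256 motion data
# profile (MDP) plus the supplementary scalar features (duration, IMU
# extremum count, EMG/IMU power distributions, intensity ratios, magnitude
# statistics).  RMS-based features are computed on the filtered,
# unnormalized signals so they retain intensity information that the MDP's
# normalization removes.

#' Moving-average EMG envelope
#'
#' Mean of the rectified signal over a sliding window (default 256 ms window,
#' 8 ms increment at 1000 Hz).
#'
#' @param x numeric vector, one filtered EMG channel restricted to a segment.
#' @param rate sampling rate in Hz.
#' @param window_ms,step_ms window length and increment in milliseconds.
#' @return envelope vector with `floor((N - W)/S) + 1` points for `N >= W`;
#'   a segment shorter than one window yields a single whole-segment window
#'   (attribute `short = TRUE`).
#' @export
emg_envelope <- function(x, rate = 1000, window_ms = 256, step_ms = 8) {
    x <- abs(as.numeric(x))
    n <- length(x)
    w <- round(window_ms * rate / 1000)
    s <- round(step_ms * rate / 1000)
    if (n < w)
        return(structure(mean(x), short = TRUE))
    cs <- c(0, cumsum(x))
    starts <- seq.int(1L, n - w + 1L, by = s)
    (cs[starts + w] - cs[starts]) / w
}

# linear-interpolation resampling of each column to m uniformly spaced points
.resample_cols <- function(m, n_out) {
    m <- as.matrix(m)
    if (nrow(m) == 1L) return(matrix(m, n_out, ncol(m), byrow = TRUE))
    grid <- seq(1, nrow(m), length.out = n_out)
    apply(m, 2, function(col) approx(seq_len(nrow(m)), col, xout = grid)$y)
}

# scale a row-group by one joint constant; all-zero groups are left alone
.group_scale <- function(m, value) {
    if (value > 0) m / value else m
}

#' Motion data profile of a segment
#'
#' Builds the 22 x 256 normalized representation of one repetition: rows
#' 1--10 are EMG envelopes jointly normalized by their maximum across the 10
#' channels (range 0..1), rows 11--16 the accelerometer axes (acc1.xyz,
#' acc2.xyz) and rows 17--22 the gyroscope axes (gyro1.xyz, gyro2.xyz), each
#' 6-row group jointly normalized by its maximal absolute value (range
#' -1..1).  Every row is resampled to 256 time points by linear
#' interpolation; amplitude normalization is applied after time
#' normalization so the extreme value 1 is attained exactly.
#'
#' @param segment a `segment` from [segment_trial()].
#' @param config pipeline configuration, see [pipeline_config()].
#' @return 22 x 256 numeric matrix.
#' @export
compute_mdp <- function(segment, config = pipeline_config()) {
    fc <- config$features
    np <- fc$mdp_time_points
    env <- lapply(seq_len(ncol(segment$emg)), function(j)
        emg_envelope(segment$emg[, j], rate = segment$emg_rate,
                     window_ms = fc$envelope_window_ms,
                     step_ms = fc$envelope_step_ms))
    env <- do.call(cbind, lapply(env, as.numeric))
    emg_rows <- t(.resample_cols(env, np))
    emg_rows <- .group_scale(emg_rows, max(emg_rows))
    acc_rows <- t(.resample_cols(cbind(segment$acc1, segment$acc2), np))
    acc_rows <- .group_scale(acc_rows, max(abs(acc_rows)))
    gyr_rows <- t(.resample_cols(cbind(segment$gyro1, segment$gyro2), np))
    gyr_rows <- .group_scale(gyr_rows, max(abs(gyr_rows)))
    mdp <- rbind(emg_rows, acc_rows, gyr_rows)
    rownames(mdp) <- c(paste0("emg", 1:10), .imu_cols[1:6], .imu_cols[7:12])
    mdp
}

#' Segment duration
#'
#' @param segment a `segment`.
#' @return duration in seconds, `(offset - onset) / rate`.
#' @export
segment_duration <- function(segment) {
    d <- (segment$offset_imu - segment$onset_imu) / segment$imu_rate
    if (d <= 0) stop("degenerate segment: onset must precede offset")
    d
}

# strict local extrema of one series; a plateau (run of equal values)
# flanked by opposite slopes counts as one extremum
.count_extrema <- function(x) {
    d <- diff(x)
    sgn <- sign(d)
    sgn <- sgn[sgn != 0]
    if (length(sgn) < 2L) return(0L)
    sum(sgn[-1] != sgn[-length(sgn)])
}

#' Summed IMU extremum count
#'
#' Number of strict interior local minima and maxima, summed over the 12
#' filtered IMU axes (6 accelerometer + 6 gyroscope).
#'
#' @param segment a `segment`.
#' @return non-negative integer.
#' @export
extremum_count <- function(segment) {
    axes <- cbind(segment$acc1, segment$acc2, segment$gyro1, segment$gyro2)
    sum(apply(axes, 2, .count_extrema))
}

.rms <- function(x) sqrt(mean(x^2))

#' EMG power distribution across the 10 channels
#'
#' @param segment a `segment`.
#' @return 10-vector of per-channel RMS fractions, summing to 1.
#' @export
emg_power_distribution <- function(segment) {
    r <- apply(segment$emg, 2, .rms)
    r / sum(r)
}

#' IMU power distribution across axes, per device
#'
#' @param segment a `segment`.
#' @return list of four 3-vectors (`acc1`, `acc2`, `gyro1`, `gyro2`), each
#'   the per-axis RMS fractions summing to 1.
#' @export
imu_power_distribution <- function(segment) {
    one <- function(m) { r <- apply(m, 2, .rms); r / sum(r) }
    list(acc1 = one(segment$acc1), acc2 = one(segment$acc2),
         gyro1 = one(segment$gyro1), gyro2 = one(segment$gyro2))
}

.mag_rms <- function(m) .rms(sqrt(rowSums(as.matrix(m)^2)))

#' Accelerometer and gyroscope intensity ratios (forearm / upper arm)
#'
#' RMS of the 3-axis vector-magnitude series of IMU1 divided by that of
#' IMU2, separately for the accelerometers and the gyroscopes.
#'
#' @param segment a `segment`.
#' @param cap value reported when the denominator is zero (flagged).
#' @return named 2-vector `c(acc_ratio, gyro_ratio)`.
#' @export
intensity_ratios <- function(segment, cap = 1e6) {
    ratio <- function(a, b) {
        den <- .mag_rms(b)
        if (den == 0) structure(cap, capped = TRUE) else .mag_rms(a) / den
    }
    c(acc_ratio = as.numeric(ratio(segment$acc1, segment$acc2)),
      gyro_ratio = as.numeric(ratio(segment$gyro1, segment$gyro2)))
}

#' Magnitude statistics of the four IMU devices
#'
#' @param segment a `segment`.
#' @return named 8-vector: mean and max of the vector-magnitude series for
#'   acc1, acc2, gyro1, gyro2.
#' @export
magnitude_stats <- function(segment) {
    one <- function(m) {
        mag <- sqrt(rowSums(as.matrix(m)^2))
        c(mean = mean(mag), max = max(mag))
    }
    v <- c(one(segment$acc1), one(segment$acc2),
           one(segment$gyro1), one(segment$gyro2))
    names(v) <- c("mean_acc1", "max_acc1", "mean_acc2", "max_acc2",
                  "mean_gyro1", "max_gyro1", "mean_gyro2", "max_gyro2")
    v
}

#' All supplementary features of a segment
#'
#' @param segment a `segment`.
#' @param config pipeline configuration.
#' @return list with elements `duration`, `extremum_count`, `emg_power`
#'   (10-vector), `imu_power` (list of four 3-vectors), `intensity_ratios`
#'   (2-vector) and `magnitude_stats` (8-vector).
#' @export
supplementary_features <- function(segment, config = pipeline_config()) {
    list(duration = segment_duration(segment),
         extremum_count = extremum_count(segment),
         emg_power = emg_power_distribution(segment),
         imu_power = imu_power_distribution(segment),
         intensity_ratios = intensity_ratios(segment),
         magnitude_stats = magnitude_stats(segment))
}
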