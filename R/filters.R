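# Noise-reduction front end.  EMG: 2nd-order Butterworth band-pass,
# nominally 20-500 Hz at 1000 Hz sampling; since the 500 Hz upper edge sits
# on Nyquist (unrealizable), the band is designed as 20-495 Hz, which is
# indistinguishable at envelope scale.  IMU: 2nd-order Butterworth low-pass
# at 20 Hz (100 Hz sampling).  Both are applied zero-phase
# (forward-backward) with odd-reflection edge padding so segment boundaries
# are not phase-shifted between the two sample clocks.

.zero_phase <- function(x, flt, pad) {
    n <- length(x)
    pad <- min(pad, n - 1L)
    # odd (point-symmetric) reflection around the end samples
    pre  <- 2 * x[1] - x[(pad + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - pad)]
    y <- c(pre, x, post)
    y <- signal::filter(flt, y)
    y <- rev(signal::filter(flt, rev(y)))
    y[(pad + 1):(pad + n)]
}

.check_series <- function(x) {
    x <- as.numeric(x)
    if (length(x) < 2L) stop("series too short to filter")
    if (!all(is.finite(x))) stop("non-finite input series")
    x
}

#' Band-pass filter one EMG channel
#'
#' @param x numeric vector, one EMG channel sampled at `rate` Hz.
#' @param rate sampling rate in Hz (default 1000).
#' @param band band edges in Hz; default `c(20, 495)` (the design band for a
#'   nominal 20--500 Hz specification at 1000 Hz sampling).  Supplying a
#'   single value gives a pure high-pass.
#' @param order Butterworth order (default 2).
#' @return filtered vector, same length as `x`.
#' @export
filter_emg <- function(x, rate = 1000, band = c(20, 495), order = 2) {
    x <- .check_series(x)
    nyq <- rate / 2
    if (any(band <= 0) || any(band >= nyq))
        stop("band edges must lie strictly inside (0, rate/2)")
    flt <- if (length(band) == 2L)
        signal::butter(order, band / nyq, type = "pass")
    else
        signal::butter(order, band / nyq, type = "high")
    .zero_phase(x, flt, pad = as.integer(3 * rate / min(band)))
}

#' Low-pass filter one IMU axis
#'
#' @param x numeric vector, one accelerometer or gyroscope axis at `rate` Hz.
#' @param rate sampling rate in Hz (default 100).
#' @param cutoff cut-off frequency in Hz (default 20).
#' @param order Butterworth order (default 2).
#' @return filtered vector, same length as `x`.
#' @export
filter_imu <- function(x, rate = 100, cutoff = 20, order = 2) {
    x <- .check_series(x)
    if (cutoff <= 0 || cutoff >= rate / 2)
        stop("cutoff must lie strictly inside (0, rate/2)")
    flt <- signal::butter(order, cutoff / (rate / 2), type = "low")
    .zero_phase(x, flt, pad = as.integer(3 * rate / cutoff))
}

# Filter every channel of a trial, returning a trial_recording with the same
# shape.  Used by segment_trial()/prepare_cohort(); exported for pipelines
# that segment manually.

#' Apply the standard filter front end to a whole trial
#'
#' @param trial a [trial_recording()].
#' @param config pipeline configuration, see [pipeline_config()].
#' @return a `trial_recording` with all 22 channels filtered.
#' @export
preprocess_trial <- function(trial, config = pipeline_config()) {
    f <- config$filters
    emg <- apply(trial$emg, 2, filter_emg, rate = trial$emg_rate,
                 band = f$emg_band, order = f$order)
    flt1 <- function(m) apply(m, 2, filter_imu, rate = trial$imu_rate,
                              cutoff = f$imu_cutoff, order = f$order)
    out <- trial_recording(trial$subject_id, trial$task_id, emg,
                           flt1(trial$acc1), flt1(trial$gyro1),
                           flt1(trial$acc2), flt1(trial$gyro2),
                           emg_rate = trial$emg_rate, imu_rate = trial$imu_rate)
    attr(out, "ground_truth") <- attr(trial, "ground_truth")
    out
}
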