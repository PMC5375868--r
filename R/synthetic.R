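# Synthetic-cohort generator.  Emulates the study conditions: 16 healthy +
# 18 hemiparetic subjects, 11 tasks, one trial per task holding three
# repetitions separated by rest.  Movement is synthesized as smooth
# bell-shaped angular-velocity pulses on task-specific gyroscope axis
# weights, with derived accelerometer profiles and envelope-modulated
# band-limited EMG carriers.  Impairment is expressed as slowing, amplitude
# reduction, additive 5 Hz tremor on the gyroscopes and agonist-to-
# antagonist EMG co-contraction; FMUE-like item scores are tied to the
# impairment level.  The generator makes no attempt at biomechanical
# realism beyond the statistical structure the pipeline assumes.

#' Impairment profile of a synthetic subject
#'
#' @param level impairment severity in \[0, 1\]; 0 reproduces the healthy
#'   template family up to sampled noise.
#' @param slowing per-unit-level duration multiplier slope (duration gain is
#'   `1 + slowing * level`).
#' @param weakness per-unit-level amplitude reduction slope (amplitude gain
#'   is `1 - weakness * level`).
#' @param tremor_amp tremor amplitude on the gyroscopes at full impairment,
#'   deg/s (injected at `tremor_freq`).
#' @param tremor_freq tremor frequency in Hz (default 5, inside the 20 Hz
#'   IMU passband so it survives preprocessing).
#' @param cocontraction fraction of the agonist EMG envelope mixed into the
#'   antagonist channel at full impairment.
#' @return list of class `impairment_profile`.
#' @export
impairment_profile <- function(level = 0, slowing = 0.6, weakness = 0.5,
                               tremor_amp = 8, tremor_freq = 5,
                               cocontraction = 0.6) {
    if (level < 0 || level > 1) stop("level must lie in [0, 1]")
    structure(list(level = level,
                   slowing_gain = 1 + slowing * level,
                   amplitude_gain = 1 - weakness * level,
                   tremor_amp = tremor_amp * level,
                   tremor_freq = tremor_freq,
                   cocontraction = cocontraction * level),
              class = "impairment_profile")
}

# Deterministic per-task constants: nominal repetition duration and channel
# weight patterns.  Weights are fixed functions of the task id so every
# session shares one template library.
#' Movement template for one canonical task
#'
#' @param task_id integer 1--11.
#' @return list with the nominal repetition duration (s) and the gyroscope,
#'   accelerometer and EMG channel weight patterns.
#' @export
task_template <- function(task_id) {
    k <- as.integer(task_id)
    durations <- c(2.5, 2.5, 3.0, 3.0, 3.2, 3.5, 3.5, 3.0, 2.5, 3.0, 1.8)
    if (k < 1L || k > 11L) stop("task_id must lie in 1..11")
    unitize <- function(w, s) s * w / sqrt(sum(w^2))
    w_g1 <- unitize(0.25 + abs(sin(k * c(1.3, 2.1, 3.7) + 0.5)), 1.0)
    w_g2 <- unitize(0.25 + abs(sin(k * c(2.9, 1.7, 0.9) + 1.1)), 0.8)
    w_a1 <- unitize(0.25 + abs(cos(k * c(0.8, 1.9, 2.6) + 0.3)), 1.0)
    w_a2 <- unitize(0.25 + abs(cos(k * c(2.2, 1.1, 3.1) + 0.9)), 0.7)
    sgn <- function(off) (-1)^((k + off + 0:2) %% 2)
    w_emg <- 0.15 + 0.85 * abs(sin(k * (1:10) * 0.7 + 0.2 * k))
    w_emg[9] <- 0.9    # biceps agonist
    w_emg[10] <- 0.12  # triceps antagonist: quiet unless co-contraction
    list(task_id = k, duration_s = durations[k],
         gyro_amp = 120, acc_amp = 0.35,
         w_gyro1 = w_g1 * sgn(0), w_gyro2 = w_g2 * sgn(1),
         w_acc1 = w_a1 * sgn(2), w_acc2 = w_a2 * sgn(1),
         gravity1 = c(0.06, 0.10, 0.98), gravity2 = c(0.10, 0.05, 0.97),
         w_emg = w_emg)
}

.bandlimited_carrier <- function(n, rate = 1000, band = c(20, 450)) {
    x <- rnorm(n)
    flt <- signal::butter(2, band / (rate / 2), type = "pass")
    y <- as.numeric(signal::filter(flt, x))
    y / sqrt(mean(y^2))
}

#' Generate one synthetic trial recording
#'
#' Emits a continuous recording holding three repetitions separated by at
#' least 2.5 s of rest, with the impairment transforms applied
#' (time-stretch, amplitude scaling, gyroscope tremor, EMG co-contraction).
#' The noiseless threshold crossings of the activity series are stored as
#' the `ground_truth` attribute (1-based IMU sample indices).
#'
#' @param template a [task_template()].
#' @param impairment an [impairment_profile()].
#' @param seed integer seed; the same seed reproduces the trial exactly.
#' @param subject_id subject identifier stored in the recording.
#' @param warp,amp per-subject duration and amplitude jitter factors
#'   (healthy inter-subject variability; defaults 1).
#' @param threshold segmentation threshold used for the stored ground truth,
#'   deg/s.
#' @return a [trial_recording()] with attribute `ground_truth`.
#' @export
generate_trial <- function(template, impairment = impairment_profile(0),
                           seed = 1L, subject_id = "S", warp = 1, amp = 1,
                           threshold = 3) {
    set.seed(seed)
    imu_rate <- 100; emg_rate <- 1000
    lead <- 1.5; gap <- 3.0; trail <- 2.5
    dur <- template$duration_s * impairment$slowing_gain * warp *
        runif(3, 0.97, 1.03)
    starts <- lead + cumsum(c(0, head(dur, -1) + gap))
    total_s <- lead + sum(dur) + 2 * gap + trail
    n_imu <- ceiling(total_s * imu_rate)
    t_imu <- (seq_len(n_imu) - 1) / imu_rate

    pulse <- numeric(n_imu)      # normalized movement intensity, 0..1
    for (r in 1:3) {
        inside <- t_imu >= starts[r] & t_imu <= starts[r] + dur[r]
        tau <- (t_imu[inside] - starts[r]) / dur[r]
        pulse[inside] <- sin(pi * tau)^2
    }
    a_gain <- impairment$amplitude_gain * amp
    gyro_amp <- template$gyro_amp * a_gain
    tremor <- impairment$tremor_amp *
        sin(2 * pi * impairment$tremor_freq * t_imu + runif(1, 0, 2 * pi)) *
        pulse
    mk_gyro <- function(w) {
        clean <- outer(pulse, w * gyro_amp) + outer(tremor, abs(w))
        list(clean = clean,
             noisy = clean + matrix(rnorm(3 * n_imu, sd = 0.05), n_imu))
    }
    g1 <- mk_gyro(template$w_gyro1); g2 <- mk_gyro(template$w_gyro2)
    s_clean <- gyro_magnitude_sum(g1$clean, g2$clean)

    gt <- do.call(rbind, lapply(1:3, function(r) {
        win <- which(t_imu >= starts[r] - 1 & t_imu <= starts[r] + dur[r] + 1)
        above <- win[s_clean[win] > threshold]
        c(onset = min(above), offset = max(above))
    }))

    dpulse <- c(0, diff(pulse)) * imu_rate
    dmax <- max(abs(dpulse)); if (dmax > 0) dpulse <- dpulse / dmax
    mk_acc <- function(w, gvec) {
        sweep(outer(dpulse, w * template$acc_amp * a_gain) +
                  matrix(rnorm(3 * n_imu, sd = 0.01), n_imu),
              2, gvec, "+")
    }
    acc1 <- mk_acc(template$w_acc1, template$gravity1)
    acc2 <- mk_acc(template$w_acc2, template$gravity2)

    n_emg <- n_imu * 10
    t_emg <- (seq_len(n_emg) - 1) / emg_rate
    env_imu <- outer(pulse, template$w_emg * a_gain)
    env_imu[, 10] <- env_imu[, 10] +
        impairment$cocontraction * env_imu[, 9]
    emg <- vapply(1:10, function(ch) {
        e <- approx(t_imu, env_imu[, ch], xout = t_emg, rule = 2)$y
        0.5 * (0.03 + e) * .bandlimited_carrier(n_emg)
    }, numeric(n_emg))

    out <- trial_recording(subject_id, template$task_id, emg,
                           acc1 = acc1, gyro1 = g1$noisy,
                           acc2 = acc2, gyro2 = g2$noisy)
    attr(out, "ground_truth") <- gt
    out
}

#' Map an impairment level to FMUE-like scores
#'
#' Item score for a task is `round(full_score * (1 - level) + noise)`,
#' clipped to `[0, full_score]`; the reported total adds a rescaled residual
#' so it lies on the 0--66 FMUE scale.  Monotone non-increasing in `level`
#' in expectation.
#'
#' @param level impairment level in \[0, 1\].
#' @param task_set task set (default [load_task_set()]).
#' @param noise_sd item noise, as a fraction of the full score (default
#'   0.1; 0 gives the deterministic mapping).
#' @param seed integer seed.
#' @return list with `items` (named integer vector) and `total` (0--66).
#' @export
impairment_to_fmue <- function(level, task_set = load_task_set(),
                               noise_sd = 0.1, seed = 1L) {
    set.seed(seed)
    full <- task_set$full_score
    items <- round(full * (1 - level) + rnorm(length(full), 0, noise_sd * full))
    items <- as.integer(pmin(pmax(items, 0L), full))
    names(items) <- task_set$task_id
    resid_full <- 66 - sum(full)
    resid <- round(resid_full * (1 - level) + rnorm(1, 0, noise_sd * resid_full))
    total <- as.integer(min(max(sum(items) + max(min(resid, resid_full), 0), 0L), 66L))
    list(items = items, total = total)
}

#' Generate a synthetic evaluation cohort
#'
#' @param n_healthy number of healthy subjects (>= 2; default 16).
#' @param n_stroke number of impaired subjects (default 18).
#' @param impairment_range range over which the impaired subjects' levels
#'   are spread (default `c(0.05, 0.8)`).
#' @param master_seed master seed; all per-subject and per-trial seeds are
#'   derived from it.
#' @param task_set task set (default [load_task_set()]).
#' @return list of per-subject records (elements `meta`, `trials`), directly
#'   consumable by [prepare_cohort()] or [write_session()].  Each `meta`
#'   carries the generating impairment level as attribute
#'   `impairment_level`.
#' @export
generate_cohort <- function(n_healthy = 16, n_stroke = 18,
                            impairment_range = c(0.05, 0.8),
                            master_seed = 1L, task_set = load_task_set()) {
    if (n_healthy < 2) stop("n_healthy must be at least 2")
    if (length(impairment_range) != 2L || any(impairment_range < 0) ||
        any(impairment_range > 1) || diff(impairment_range) < 0)
        stop("impairment_range must be an increasing pair inside [0, 1]")
    set.seed(master_seed)
    lvl_h <- pmin(abs(rnorm(n_healthy, 0, 0.015)), 0.05)
    lvl_s <- if (n_stroke > 0)
        pmin(pmax(seq(impairment_range[1], impairment_range[2],
                      length.out = n_stroke) +
                      rnorm(n_stroke, 0, 0.01), 0), 1)
    else numeric(0)
    ids <- c(sprintf("H%02d", seq_len(n_healthy)),
             sprintf("S%02d", seq_len(n_stroke)))
    groups <- c(rep("healthy", n_healthy), rep("stroke", n_stroke))
    levels <- c(lvl_h, lvl_s)
    warps <- runif(n_healthy + n_stroke, 0.9, 1.1)
    amps <- runif(n_healthy + n_stroke, 0.9, 1.1)
    ages <- round(c(runif(n_healthy, 24, 63), runif(n_stroke, 30, 81)))
    sexes <- sample(c("F", "M"), n_healthy + n_stroke, replace = TRUE)
    sides <- sample(c("left", "right"), n_healthy + n_stroke, replace = TRUE)

    records <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        sseed <- .fold_seed(master_seed, i, 0L)
        if (groups[i] == "healthy") {
            items <- task_set$full_score
            names(items) <- task_set$task_id
            total <- 66L
        } else {
            fm <- impairment_to_fmue(levels[i], task_set, seed = sseed)
            items <- fm$items; total <- fm$total
        }
        meta <- subject_meta(ids[i], groups[i], sides[i], total, items,
                             ages[i], sexes[i], task_set)
        attr(meta, "impairment_level") <- levels[i]
        imp <- impairment_profile(levels[i])
        trials <- lapply(task_set$task_id, function(t)
            generate_trial(task_template(t), imp,
                           seed = .fold_seed(master_seed, i, t),
                           subject_id = ids[i],
                           warp = warps[i], amp = amps[i]))
        records[[i]] <- list(meta = meta, trials = trials)
    }
    records
}
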