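test_that("EMG envelope is a windowed rectified mean with the documented count", {
    expect_equal(unique(round(emg_envelope(rep(2.5, 1000)), 12)), 2.5)
    expect_equal(unique(round(emg_envelope(rep(c(-3, 3), 500)), 12)), 3)
    expect_length(emg_envelope(rnorm(1000)), 94L)  # floor((1000-256)/8)+1
    short <- emg_envelope(rnorm(100))
    expect_length(short, 1L)
    expect_true(isTRUE(attr(short, "short")))
})

test_that("the motion data profile is 22 x 256 with joint group normalization", {
    seg <- random_segment(300, seed = 5)
    mdp <- compute_mdp(seg)
    expect_equal(dim(mdp), c(22L, 256L))
    expect_true(all(mdp[1:10, ] >= 0 & mdp[1:10, ] <= 1))
    expect_equal(max(mdp[1:10, ]), 1)
    expect_equal(max(abs(mdp[11:16, ])), 1)
    expect_equal(max(abs(mdp[17:22, ])), 1)
    # sign-preserving max-abs scaling: a -2 g peak maps to -1
    seg2 <- random_segment(300, seed = 6)
    seg2$acc1 <- seg2$acc1 * 0.1
    seg2$acc2 <- seg2$acc2 * 0.1
    seg2$acc1[, 1] <- sin(seq(0, 2 * pi, length.out = 300))
    seg2$acc1[150, 1] <- -2     # smooth row: survives resampling as the peak
    mdp2 <- compute_mdp(seg2)
    expect_equal(min(mdp2[11, ]), -1)
})

test_that("the profile is amplitude-scale invariant per sensor group", {
    seg <- random_segment(280, seed = 8)
    seg2 <- seg
    seg2$emg <- seg$emg * 7
    seg2$acc1 <- seg$acc1 * 0.3; seg2$acc2 <- seg$acc2 * 0.3
    seg2$gyro1 <- seg$gyro1 * 5; seg2$gyro2 <- seg$gyro2 * 5
    expect_equal(compute_mdp(seg2), compute_mdp(seg), tolerance = 1e-12)
})

test_that("a time-stretched copy yields nearly the same profile", {
    n <- 300
    t <- seq(0, 1, length.out = n)
    smooth <- function(k) sin(2 * pi * k * t) + 0.5 * cos(2 * pi * t)
    acc <- sapply(1:3, smooth)
    seg <- make_segment(emg = matrix(abs(smooth(2)) %x% rep(1, 10), ncol = 1)[, rep(1, 10)],
                        acc1 = acc, acc2 = acc * 0.5,
                        gyro1 = acc * 30, gyro2 = acc * 20)
    t2 <- seq(0, 1, length.out = 2 * n)
    acc2x <- sapply(1:3, function(k) sin(2 * pi * k * t2) + 0.5 * cos(2 * pi * t2))
    emg2 <- matrix(abs(sin(2 * pi * 2 * t2) + 0.5 * cos(2 * pi * t2)) %x% rep(1, 10),
                   ncol = 1)[, rep(1, 10)]
    seg2 <- make_segment(emg = emg2, acc1 = acc2x, acc2 = acc2x * 0.5,
                         gyro1 = acc2x * 30, gyro2 = acc2x * 20)
    d <- abs(compute_mdp(seg) - compute_mdp(seg2))
    # IMU rows are exactly stretch-invariant up to resampling error; EMG
    # rows keep their fixed 256 ms window, so relative smoothing differs
    expect_lt(max(d[11:22, ]), 1e-3)
    expect_lt(max(d[1:10, ]), 0.25)
})

test_that("duration is offset minus onset over the rate", {
    seg <- random_segment(300)
    seg$onset_imu <- 100L; seg$offset_imu <- 400L
    expect_equal(segment_duration(seg), 3.0)
    seg$offset_imu <- 100L
    expect_error(segment_duration(seg), "degenerate")
})

test_that("extremum count sums strict interior extrema over the 12 axes", {
    z <- matrix(0, 200, 3)
    flat <- make_segment(matrix(0, 2000, 10), z, z, z, z)
    expect_equal(extremum_count(flat), 0L)
    one <- z; one[, 1] <- sin(2 * pi * seq(0, 1, length.out = 200))
    expect_equal(extremum_count(make_segment(matrix(0, 2000, 10), one, z, z, z)), 2L)
    set.seed(12)
    seg <- make_segment(matrix(0, 2000, 10),
                        matrix(cumsum(rnorm(600)), 200),
                        matrix(cumsum(rnorm(600)), 200),
                        matrix(cumsum(rnorm(600)), 200),
                        matrix(cumsum(rnorm(600)), 200))
    oracle <- sum(sapply(list(seg$acc1, seg$acc2, seg$gyro1, seg$gyro2),
                         function(m) sum(apply(m, 2, extrema_scan))))
    expect_equal(extremum_count(seg), oracle)
})

test_that("power distributions are RMS fractions that sum to one", {
    seg <- random_segment(250, seed = 3)
    p <- emg_power_distribution(seg)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    rms <- function(x) sqrt(mean(x^2))
    expect_equal(p, apply(seg$emg, 2, rms) / sum(apply(seg$emg, 2, rms)))
    # single active channel
    seg$emg[] <- 0; seg$emg[, 3] <- rnorm(nrow(seg$emg))
    expect_equal(unname(emg_power_distribution(seg)),
                 as.numeric(3 == 1:10))
    # identical channels split evenly
    seg$emg <- matrix(rep(rnorm(nrow(seg$emg)), 10), ncol = 10)
    expect_equal(unname(emg_power_distribution(seg)), rep(0.1, 10))
    ip <- imu_power_distribution(random_segment(250, seed = 3))
    for (d in ip) expect_equal(sum(d), 1, tolerance = 1e-9)
    # power distributions are gain invariant
    s1 <- random_segment(250, seed = 14); s2 <- s1
    s2$gyro1 <- s1$gyro1 * 9
    expect_equal(imu_power_distribution(s2)$gyro1,
                 imu_power_distribution(s1)$gyro1, tolerance = 1e-12)
})

test_that("intensity ratios and magnitude stats follow the vector magnitudes", {
    n <- 100
    const <- matrix(rep(c(0, 3, 4), each = n), n)
    seg <- make_segment(matrix(0, 10 * n, 10), const, const, const, const)
    expect_equal(unname(magnitude_stats(seg)),
                 rep(5, 8))  # constant magnitude 5 everywhere
    expect_equal(unname(intensity_ratios(seg)), c(1, 1))
    seg$acc1 <- 2 * seg$acc1
    expect_equal(unname(intensity_ratios(seg))[1], 2)
    set.seed(6)
    seg2 <- random_segment(120, seed = 6)
    mag <- sqrt(rowSums(seg2$gyro1^2))
    ms <- magnitude_stats(seg2)
    expect_equal(unname(ms["mean_gyro1"]), mean(mag))
    expect_equal(unname(ms["max_gyro1"]), max(mag))
    rms <- function(x) sqrt(mean(x^2))
    expect_equal(unname(intensity_ratios(seg2))[2],
                 rms(sqrt(rowSums(seg2$gyro1^2))) /
                     rms(sqrt(rowSums(seg2$gyro2^2))))
})
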