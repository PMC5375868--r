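test_that("gyro activity is the sum of the two vector magnitudes", {
    z <- matrix(0, 5, 3)
    expect_equal(gyro_magnitude_sum(z, z), rep(0, 5))
    expect_equal(gyro_magnitude_sum(matrix(c(3, 4, 0), 1),
                                    matrix(c(0, 0, 12), 1)), 17)
    set.seed(9)
    g1 <- matrix(rnorm(300), 100); g2 <- matrix(rnorm(300), 100)
    oracle <- vapply(1:100, function(t)
        sqrt(sum(g1[t, ]^2)) + sqrt(sum(g2[t, ]^2)), 0)
    expect_equal(gyro_magnitude_sum(g1, g2), oracle)
})

test_that("sub-hold dips are bridged and long rests split segments", {
    sec <- function(s, v) rep(v, s * 100)
    expect_equal(nrow(detect_segments(sec(10, 1))), 0L)
    # 1 s rest, 3 s active, 0.5 s dip, 1 s active, 3 s rest: one segment
    s <- c(sec(1, 0), sec(3, 10), sec(0.5, 0), sec(1, 10), sec(3, 0))
    b <- detect_segments(s)
    expect_equal(nrow(b), 1L)
    expect_equal(unname(b[1, ]), c(101L, 550L))
    # lengthening the dip to 3 s splits it into two segments
    s2 <- c(sec(1, 0), sec(3, 10), sec(3, 0), sec(1, 10), sec(3, 0))
    expect_equal(nrow(detect_segments(s2)), 2L)
})

test_that("hold-rule automaton matches a hand simulation on random bursts", {
    # random 0/10 telegraph signals: merge above-runs separated by < 2 s
    set.seed(21)
    for (rep in 1:20) {
        runs <- pmax(10, rpois(9, 120))
        lvl <- rep(c(0, 10), length.out = 9)
        s <- rep(lvl, runs)
        got <- detect_segments(s, min_segment_s = 0)
        # hand simulation
        on <- which(lvl > 3)
        ends <- cumsum(runs); starts <- ends - runs + 1
        segs <- list(); cur_on <- NA; cur_off <- NA
        for (k in seq_along(lvl)) {
            if (lvl[k] > 3) {
                if (is.na(cur_on)) cur_on <- starts[k]
                cur_off <- ends[k]
            } else if (!is.na(cur_on) && runs[k] >= 200) {
                segs[[length(segs) + 1]] <- c(cur_on, cur_off)
                cur_on <- NA
            }
        }
        if (!is.na(cur_on)) segs[[length(segs) + 1]] <- c(cur_on, cur_off)
        want <- do.call(rbind, segs)
        expect_equal(unname(got), unname(want), ignore_attr = TRUE)
    }
})

test_that("boundary indices map between clocks by the rate ratio", {
    expect_equal(map_boundaries(150L), 1500L)
    expect_equal(map_boundaries(0L), 0L)
    expect_equal(map_boundaries(7L, 1L), 7L)
    expect_error(map_boundaries(-1L), "negative")
})

test_that("raising the threshold never increases above-threshold time", {
    set.seed(4)
    s <- abs(rnorm(2000, sd = 4))
    prev <- Inf
    for (tr in c(1, 2, 4, 8)) {
        b <- detect_segments(s, threshold = tr, min_segment_s = 0)
        tot <- if (nrow(b)) sum(s[unlist(mapply(seq, b[, 1], b[, 2],
                                                SIMPLIFY = FALSE))] > tr) else 0
        expect_lte(tot, prev)
        prev <- tot
    }
})

test_that("segment_trial recovers three constructed repetitions", {
    tr <- generate_trial(task_template(2), impairment_profile(0), seed = 31,
                         subject_id = "A")
    segs <- segment_trial(preprocess_trial(tr))
    expect_length(segs, 3L)
    gt <- attr(tr, "ground_truth")
    for (k in 1:3) {
        expect_lte(abs(segs[[k]]$onset_imu - gt[k, "onset"]), 1)
        expect_lte(abs(segs[[k]]$offset_imu - gt[k, "offset"]), 1)
        # boundaries applied to all 22 channels
        expect_equal(nrow(segs[[k]]$emg), 10 * nrow(segs[[k]]$acc1))
    }
    # pure rest: no segments, with a warning
    quiet <- trial_recording("A", 1,
                             emg = matrix(rnorm(5000, sd = 1e-3), 500, 10),
                             acc1 = matrix(0, 50, 3), gyro1 = matrix(0, 50, 3),
                             acc2 = matrix(0, 50, 3), gyro2 = matrix(0, 50, 3))
    expect_warning(expect_length(segment_trial(preprocess_trial(quiet)), 0L),
                   "no segments")
})
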