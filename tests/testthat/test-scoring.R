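test_that("DTW distance matches exhaustive path enumeration", {
    expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(dtw_distance(c(1, 2, 3), c(1, 3)), 1)
    set.seed(17)
    for (k in 1:60) {
        n <- sample(2:6, 1); m <- sample(2:6, 1); d <- sample(1:3, 1)
        a <- matrix(rnorm(n * d), n, d)
        b <- matrix(rnorm(m * d), m, d)
        expect_equal(dtw_distance(a, b), dtw_exhaustive(a, b),
                     tolerance = 1e-10)
    }
    expect_error(dtw_distance(numeric(0), 1:3), "empty")
})

test_that("PCC similarity takes the maximum over the bank", {
    set.seed(23)
    bank <- lapply(1:5, function(i) matrix(rnorm(22 * 256), 22))
    test <- bank[[3]]
    expect_equal(pcc_similarity(test, bank), 1.0)
    expect_equal(pcc_similarity(3 * test + 2, bank), 1.0)  # affine invariance
    probe <- matrix(rnorm(22 * 256), 22)
    oracle <- max(vapply(bank, function(m)
        pcc_textbook(as.numeric(probe), as.numeric(m)), 0))
    expect_equal(pcc_similarity(probe, bank), oracle, tolerance = 1e-12)
    expect_error(pcc_similarity(matrix(1, 22, 256), bank), "zero-variance")
})

test_that("DTW similarity takes the minimum over the bank", {
    set.seed(29)
    bank <- lapply(1:5, function(i) matrix(rnorm(22 * 8), 22))
    expect_equal(dtw_similarity(bank[[2]], bank), 0, tolerance = 1e-5)
    probe <- matrix(rnorm(22 * 8), 22)
    expect_equal(dtw_similarity(probe, bank[1]),
                 dtw_distance(t(probe), t(bank[[1]])))
    oracle <- min(vapply(bank, function(m)
        dtw_exhaustive(t(probe)[1:5, ], t(m)[1:5, ]), 0))
    short_bank <- lapply(bank, function(m) m[, 1:5])
    expect_equal(dtw_similarity(probe[, 1:5], short_bank), oracle,
                 tolerance = 1e-10)
})

test_that("power distances are minimal Euclidean distances to the bank", {
    v <- c(1, rep(0, 9))
    w <- c(0, 1, rep(0, 8))
    expect_equal(power_distance(v, rbind(v)), 0)
    expect_equal(power_distance(v, rbind(w)), sqrt(2))
    set.seed(31)
    bank <- matrix(runif(50), 5, 10)
    probe <- runif(10)
    oracle <- min(apply(bank, 1, function(r) sqrt(sum((r - probe)^2))))
    expect_equal(power_distance(probe, bank), oracle)
})

test_that("preliminary indicators average repetitions and detect leakage", {
    prep <- small_prep()
    task <- 1L
    segs_of <- function(id) Filter(function(s)
        s$subject_id == id && s$task_id == task, prep$segments)
    # leakage canary: an unpurged bank containing the subject's own
    # repetitions returns a perfect correlation
    bank_all <- build_reference_bank(prep, task)
    own <- preliminary_ei(segs_of("H01"), bank_all)
    expect_equal(unname(own["pcc"]), 1.0)
    expect_equal(unname(own["dtw"]), 0.0, tolerance = 1e-5)
    # purged bank: strictly imperfect similarity
    bank_purged <- build_reference_bank(prep, task, exclude = "H01")
    expect_false("H01" %in% bank_purged$subject_ids)
    purged <- preliminary_ei(segs_of("H01"), bank_purged)
    expect_lt(unname(purged["pcc"]), 1.0)
    expect_gt(unname(purged["dtw"]), 0.0)
    expect_length(purged, 7L)
    # the per-task component is the mean of per-repetition scores
    reps <- segs_of("S02")
    per_rep <- vapply(reps, function(s)
        pcc_similarity(s$mdp, bank_all), 0)
    expect_equal(unname(preliminary_ei(reps, bank_all)["pcc"]),
                 mean(per_rep))
})

test_that("healthy subjects sit closer to the reference than impaired ones", {
    prep <- small_prep()
    task <- 6L
    ei_for <- function(id) {
        bank <- build_reference_bank(prep, task, exclude = id)
        segs <- Filter(function(s)
            s$subject_id == id && s$task_id == task, prep$segments)
        preliminary_ei(segs, bank)
    }
    ids <- prep$meta$subject_id
    eis <- vapply(ids, ei_for, numeric(7))
    healthy <- prep$meta$group == "healthy"
    expect_gt(mean(eis["pcc", healthy]), mean(eis["pcc", !healthy]))
    expect_lt(mean(eis["dtw", healthy]), mean(eis["dtw", !healthy]))
})

test_that("the global preliminary indicator is a direct sum over tasks", {
    pt <- data.frame(pcc = rep(1, 11), dtw = rep(0, 11))
    expect_equal(global_preliminary_ei(pt, "pcc"), 11)
    expect_equal(global_preliminary_ei(pt, "dtw"), 0)
    set.seed(2)
    pt2 <- data.frame(pcc = runif(11), dtw = runif(11))
    expect_equal(global_preliminary_ei(pt2, "dtw"), sum(pt2$dtw))
})
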