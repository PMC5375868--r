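# Shared fixtures: built lazily once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fixture_env))
        assign(name, builder(), envir = .fixture_env)
    get(name, envir = .fixture_env)
}

# A compact 2-task configuration for fast end-to-end tests.
mini_config <- function() {
    pipeline_config(task_set = data.frame(
        task_id = c(1L, 6L),
        name = c("wrist flexion", "fetch ball"),
        full_score = c(2L, 8L)))
}

# Small mixed cohort (4 healthy + 4 impaired, 2 tasks) prepared end to end.
small_prep <- function() fixture("small_prep", function() {
    cfg <- mini_config()
    ts <- load_task_set(cfg$task_set)
    co <- generate_cohort(n_healthy = 4, n_stroke = 4,
                          master_seed = 42, task_set = ts)
    prepare_cohort(co, cfg)
})

# Hand-built segment object for direct feature-level tests.
make_segment <- function(emg, acc1, acc2, gyro1, gyro2,
                         onset_imu = 1L, imu_rate = 100, emg_rate = 1000) {
    n <- nrow(acc1)
    structure(list(
        subject_id = "T", task_id = 1L, repetition = 1L,
        onset_imu = onset_imu, offset_imu = onset_imu + n - 1L,
        onset_emg = (onset_imu - 1L) * 10L + 1L,
        offset_emg = (onset_imu + n - 1L) * 10L,
        emg = emg, acc1 = acc1, acc2 = acc2, gyro1 = gyro1, gyro2 = gyro2,
        emg_rate = emg_rate, imu_rate = imu_rate, open_ended = FALSE),
        class = "segment")
}

# Random segment with given IMU length (EMG length 10x).
random_segment <- function(n_imu = 300, seed = 1) {
    set.seed(seed)
    make_segment(
        emg = matrix(rnorm(n_imu * 10 * 10), n_imu * 10, 10),
        acc1 = matrix(rnorm(n_imu * 3), n_imu, 3),
        acc2 = matrix(rnorm(n_imu * 3), n_imu, 3),
        gyro1 = matrix(rnorm(n_imu * 3, sd = 20), n_imu, 3),
        gyro2 = matrix(rnorm(n_imu * 3, sd = 20), n_imu, 3))
}

random_feature_matrix <- function(m = 40, seed = 1) {
    set.seed(seed)
    v <- matrix(rnorm(m * 19), m, 19)
    colnames(v) <- feature_columns()
    v
}
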