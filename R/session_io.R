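# On-disk session layout: one directory per subject containing a `meta`
# key-value file and, per trial, two delimited tables: task<k>_emg.csv
# (10 columns ch1..ch10, 1000 Hz) and task<k>_imu.csv (12 columns ordered
# acc1.xyz, acc2.xyz, gyro1.xyz, gyro2.xyz, 100 Hz).  A `manifest` file at
# the session root lists subject directories.  Values are serialized with 15
# significant digits; units are fixed (EMG mV, ACC g, GYRO deg/s) and
# declared in meta.

.imu_cols <- c("acc1.x", "acc1.y", "acc1.z", "acc2.x", "acc2.y", "acc2.z",
               "gyro1.x", "gyro1.y", "gyro1.z", "gyro2.x", "gyro2.y", "gyro2.z")

#' Write a session to disk
#'
#' @param records list of per-subject records, each a list with elements
#'   `meta` ([subject_meta()]) and `trials` (list of [trial_recording()]).
#' @param path target directory (created if absent).
#' @return `path`, invisibly.
#' @seealso [read_session()] for the inverse operation.
#' @export
write_session <- function(records, path) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(path)) stop("cannot create session directory: ", path)
    ids <- vapply(records, function(r) r$meta$subject_id, "")
    for (rec in records) {
        meta <- rec$meta
        if (!inherits(meta, "subject_meta")) stop("record without subject_meta")
        sdir <- file.path(path, meta$subject_id)
        dir.create(sdir, showWarnings = FALSE)
        items <- paste(names(meta$fmue_item_scores), meta$fmue_item_scores,
                       sep = ":", collapse = ",")
        lines <- c(
            paste0("subject_id: ", meta$subject_id),
            paste0("group: ", meta$group),
            paste0("tested_side: ", meta$tested_side),
            paste0("age: ", format(meta$age, digits = 15)),
            paste0("sex: ", meta$sex),
            paste0("fmue_total: ", meta$fmue_total),
            paste0("fmue_items: ", items),
            "units.emg: mV",
            "units.acc: g",
            "units.gyro: deg/s"
        )
        writeLines(lines, file.path(sdir, "meta"))
        for (tr in rec$trials) {
            if (!inherits(tr, "trial_recording")) stop("record holds a non-trial object")
            ok <- vapply(list(tr$emg, tr$acc1, tr$acc2, tr$gyro1, tr$gyro2),
                         function(m) all(is.finite(m)), TRUE)
            if (!all(ok))
                stop(sprintf("non-finite samples in subject %s task %d",
                             tr$subject_id, tr$task_id))
            stem <- file.path(sdir, sprintf("task%02d", tr$task_id))
            emg <- tr$emg
            colnames(emg) <- paste0("ch", 1:10)
            imu <- cbind(tr$acc1, tr$acc2, tr$gyro1, tr$gyro2)
            colnames(imu) <- .imu_cols
            data.table::fwrite(as.data.frame(emg), paste0(stem, "_emg.csv"))
            data.table::fwrite(as.data.frame(imu), paste0(stem, "_imu.csv"))
        }
    }
    writeLines(sort(ids), file.path(path, "manifest"))
    invisible(path)
}

.parse_meta <- function(file) {
    lines <- readLines(file)
    kv <- regmatches(lines, regexpr("^[^:]+", lines))
    val <- sub("^[^:]+:\\s*", "", lines)
    names(val) <- trimws(kv)
    parts <- strsplit(strsplit(val[["fmue_items"]], ",")[[1]], ":")
    items <- as.integer(vapply(parts, `[`, "", 2))
    names(items) <- vapply(parts, `[`, "", 1)
    subject_meta(
        subject_id = val[["subject_id"]], group = val[["group"]],
        tested_side = val[["tested_side"]],
        fmue_total = as.integer(val[["fmue_total"]]),
        fmue_item_scores = items,
        age = as.numeric(val[["age"]]), sex = val[["sex"]]
    )
}

#' Read a session from disk
#'
#' Reads a directory written by [write_session()] and validates every record
#' (channel counts, sampling-rate ratio, finiteness).
#'
#' @param path session directory containing a `manifest` file.
#' @return list of per-subject records (elements `meta`, `trials`).
#' @export
read_session <- function(path) {
    if (!dir.exists(path)) stop("no such session directory: ", path)
    mf <- file.path(path, "manifest")
    ids <- if (file.exists(mf)) readLines(mf) else
        basename(Filter(dir.exists, list.dirs(path, recursive = FALSE)))
    ids <- ids[nzchar(ids)]
    if (length(ids) == 0L) {
        warning("empty session: ", path)
        return(list())
    }
    out <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        sdir <- file.path(path, ids[i])
        meta_file <- file.path(sdir, "meta")
        if (!file.exists(meta_file))
            stop("missing meta file for subject ", ids[i])
        meta <- .parse_meta(meta_file)
        emg_files <- sort(list.files(sdir, pattern = "^task[0-9]+_emg\\.csv$"))
        trials <- vector("list", length(emg_files))
        for (j in seq_along(emg_files)) {
            task_id <- as.integer(sub("^task([0-9]+)_emg\\.csv$", "\\1", emg_files[j]))
            imu_file <- file.path(sdir, sprintf("task%02d_imu.csv", task_id))
            if (!file.exists(imu_file))
                stop(sprintf("missing IMU file for subject %s task %d", ids[i], task_id))
            emg <- as.matrix(data.table::fread(file.path(sdir, emg_files[j])))
            imu <- as.matrix(data.table::fread(imu_file))
            if (!identical(colnames(imu), .imu_cols))
                stop("unexpected IMU column layout in ", imu_file)
            trials[[j]] <- trial_recording(
                subject_id = ids[i], task_id = task_id, emg = emg,
                acc1 = imu[, 1:3, drop = FALSE], acc2 = imu[, 4:6, drop = FALSE],
                gyro1 = imu[, 7:9, drop = FALSE], gyro2 = imu[, 10:12, drop = FALSE]
            )
        }
        out[[i]] <- list(meta = meta, trials = trials)
    }
    out
}
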