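#' Canonical upper-limb task set
#'
#' The evaluation protocol uses 11 canonical upper-limb tasks, each linked to
#' one or more items of the upper-extremity Fugl-Meyer assessment (FMUE).
#' The per-task full score is the summed score of the linked FMUE items; the
#' default set totals 42 points.
#'
#' @param config optional task-set override: a `data.frame` (or list coercible
#'   to one) with columns `task_id`, `name`, `full_score`.  `NULL` loads the
#'   default 11-task set.
#' @return a `data.frame` with columns `task_id` (integer), `name` (character)
#'   and `full_score` (integer points).
#' @examples
#' ts <- load_task_set()
#' sum(ts$full_score)  # 42
#' @export
load_task_set <- function(config = NULL) {
    if (is.null(config)) {
        ts <- data.frame(
            task_id = 1:11,
            name = c(
                "wrist flexion",
                "wrist extension",
                "shoulder flexion to 90 deg, elbow extended",
                "shoulder abduction to 90 deg, forearm pronated",
                "flip a piece of paper",
                "fetch and hold a ball on the table",
                "fetch and hold a cylindrical roll",
                "finger to nose",
                "touch the back of the shoulder",
                "forearm supination/pronation, elbow at 90 deg",
                "fast repeated elbow flexion"
            ),
            full_score = c(2L, 2L, 2L, 2L, 6L, 8L, 8L, 6L, 2L, 2L, 2L),
            stringsAsFactors = FALSE
        )
        return(ts)
    }
    ts <- as.data.frame(config, stringsAsFactors = FALSE)
    req <- c("task_id", "name", "full_score")
    if (!all(req %in% names(ts)))
        stop("task set config must provide columns: ", paste(req, collapse = ", "))
    ts <- ts[, req]
    ts$task_id <- as.integer(ts$task_id)
    ts$full_score <- as.integer(ts$full_score)
    if (anyDuplicated(ts$task_id))
        stop("duplicate task_id in task set")
    if (any(ts$full_score <= 0))
        stop("full_score must be positive")
    ts
}
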