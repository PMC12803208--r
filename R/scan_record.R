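#' Construct a scan record
#'
#' A scan record bundles one functional scan's node-by-time data matrix with
#' its labels and per-volume nuisance traces. Data are stored nodes-in-rows,
#' volumes-in-columns throughout the package; the on-disk TSV format is the
#' transpose (volumes as rows) for readability.
#'
#' @param subject_id,session_id,task Non-empty label strings.
#' @param data Numeric matrix, nodes x volumes, all entries finite.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param motion_fd Per-volume framewise displacement in mm; first entry 0
#'   (no preceding frame). Defaults to all-zero.
#' @param global_signal Per-volume mean signal across nodes. Defaults to the
#'   column means of `data`.
#' @return An object of class `scan_record`.
#' @export
scan_record <- function(subject_id, session_id, task, data, tr_seconds,
                        motion_fd = NULL, global_signal = NULL) {
  stopifnot(is.character(subject_id), nzchar(subject_id),
            is.character(session_id), nzchar(session_id),
            is.character(task), nzchar(task),
            is.matrix(data), is.numeric(data),
            is.numeric(tr_seconds), length(tr_seconds) == 1L, tr_seconds > 0)
  if (!all(is.finite(data))) stop("scan data contains non-finite entries")
  n_vol <- ncol(data)
  if (is.null(motion_fd)) motion_fd <- numeric(n_vol)
  if (is.null(global_signal)) global_signal <- colMeans(data)
  stopifnot(length(motion_fd) == n_vol, length(global_signal) == n_vol,
            all(is.finite(motion_fd)), all(is.finite(global_signal)),
            all(motion_fd >= 0))
  structure(list(
    subject_id = subject_id, session_id = session_id, task = task,
    data = data, tr_seconds = tr_seconds,
    motion_fd = as.numeric(motion_fd),
    global_signal = as.numeric(global_signal)
  ), class = "scan_record")
}

#' @export
print.scan_record <- function(x, ...) {
  cat(sprintf("<scan_record> subject=%s session=%s task=%s  %d nodes x %d volumes (TR %.3g s)\n",
              x$subject_id, x$session_id, x$task,
              nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Number of nodes / volumes of a scan record
#' @param scan A `scan_record`.
#' @return Integer count.
#' @export
n_nodes <- function(scan) nrow(scan$data)

#' @rdname n_nodes
#' @export
n_volumes <- function(scan) ncol(scan$data)

#' Keep only the first `n` volumes of a scan
#'
#' Used for task identification, where resting-state scans are truncated to
#' the task-scan length so every candidate label has equally many volumes.
#'
#' @param scan A `scan_record`.
#' @param n Number of leading volumes to keep.
#' @return A `scan_record` with `n` volumes.
#' @export
truncate_scan <- function(scan, n) {
  stopifnot(n >= 1L, n <= n_volumes(scan))
  keep <- seq_len(n)
  scan$data <- scan$data[, keep, drop = FALSE]
  scan$motion_fd <- scan$motion_fd[keep]
  scan$global_signal <- scan$global_signal[keep]
  scan
}

#' Restrict a scan to a subset of nodes
#'
#' The motion trace and the recorded global signal are scan-level
#' measurements and are kept as-is.
#'
#' @param scan A `scan_record`.
#' @param nodes Integer indices of nodes to keep.
#' @return A `scan_record` with `length(nodes)` nodes.
#' @export
subset_nodes <- function(scan, nodes) {
  stopifnot(all(nodes >= 1L), all(nodes <= n_nodes(scan)),
            !anyDuplicated(nodes))
  scan$data <- scan$data[nodes, , drop = FALSE]
  scan
}
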