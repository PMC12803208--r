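# On-disk formats: one TSV per scan (volumes as rows, nodes as columns),
# one motion TSV per scan, and a JSON cohort manifest.

scan_basename <- function(scan) {
  sprintf("%s_%s_%s", scan$subject_id, scan$session_id, scan$task)
}

node_header <- function(n) sprintf("node_%04d", seq_len(n))

#' Write a cohort to a directory
#'
#' Each scan is written as `<subject>_<session>_<task>.tsv` (volumes as
#' rows, columns `node_0001`, ...), with a companion
#' `<...>_motion.tsv` (columns `volume`, `fd_mm`, `global_signal`) and a
#' single `manifest.json` listing every scan's path, labels and TR.
#'
#' @param cohort List of [scan_record()]s.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(all(vapply(cohort, inherits, logical(1), "scan_record")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    scan <- cohort[[i]]
    base <- scan_basename(scan)
    dt <- data.table::as.data.table(t(scan$data))
    data.table::setnames(dt, node_header(n_nodes(scan)))
    data.table::fwrite(dt, file.path(dir, paste0(base, ".tsv")), sep = "\t")
    mt <- data.table::data.table(volume = seq_len(n_volumes(scan)),
                                 fd_mm = scan$motion_fd,
                                 global_signal = scan$global_signal)
    data.table::fwrite(mt, file.path(dir, paste0(base, "_motion.tsv")), sep = "\t")
    entries[[i]] <- list(path = paste0(base, ".tsv"),
                         motion_path = paste0(base, "_motion.tsv"),
                         subject = scan$subject_id, session = scan$session_id,
                         task = scan$task, tr_seconds = scan$tr_seconds)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(scans = entries), manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and the per-scan TSVs.
#' @return List of [scan_record()]s.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  lapply(manifest$scans, function(e) {
    dt <- data.table::fread(file.path(dir, e$path), sep = "\t")
    mt <- data.table::fread(file.path(dir, e$motion_path), sep = "\t")
    scan_record(e$subject, e$session, e$task,
                t(as.matrix(dt)), e$tr_seconds,
                motion_fd = mt$fd_mm, global_signal = mt$global_signal)
  })
}

#' Write an eigenvector series to TSV
#'
#' The eigenvector matrix is written volumes-as-rows
#' (`<base>_eigvec.tsv`), with a sidecar `<base>_eig.tsv` holding the
#' per-volume leading eigenvalue and variance fraction.
#'
#' @param es An `eigen_series`.
#' @param dir Output directory.
#' @return The eigenvector file path, invisibly.
#' @export
write_eigen_series <- function(es, dir) {
  stopifnot(inherits(es, "eigen_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- sprintf("%s_%s_%s", es$subject_id, es$session_id, es$task)
  dt <- data.table::as.data.table(t(es$v1))
  data.table::setnames(dt, node_header(nrow(es$v1)))
  data.table::fwrite(dt, file.path(dir, paste0(base, "_eigvec.tsv")), sep = "\t")
  side <- data.table::data.table(volume = seq_along(es$lambda1),
                                 lambda1 = es$lambda1,
                                 variance_fraction = es$variance_fraction)
  data.table::fwrite(side, file.path(dir, paste0(base, "_eig.tsv")), sep = "\t")
  invisible(file.path(dir, paste0(base, "_eigvec.tsv")))
}

#' Read an eigenvector series written by [write_eigen_series()]
#'
#' @param dir Directory holding the files.
#' @param subject_id,session_id,task Labels identifying the scan.
#' @param tr_seconds Repetition time to record on the result.
#' @return An `eigen_series`.
#' @export
read_eigen_series <- function(dir, subject_id, session_id, task,
                              tr_seconds = NA_real_) {
  base <- sprintf("%s_%s_%s", subject_id, session_id, task)
  v <- t(as.matrix(data.table::fread(file.path(dir, paste0(base, "_eigvec.tsv")))))
  side <- data.table::fread(file.path(dir, paste0(base, "_eig.tsv")))
  dimnames(v) <- NULL
  structure(list(v1 = v, lambda1 = side$lambda1,
                 variance_fraction = side$variance_fraction,
                 tr_seconds = tr_seconds, subject_id = subject_id,
                 session_id = session_id, task = task),
            class = "eigen_series")
}
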