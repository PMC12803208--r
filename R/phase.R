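# Per-volume phase-coherence connectivity and its leading-eigenvector
# representation.

#' Instantaneous phases via the Hilbert transform
#'
#' Computes, for each node, the angle of the analytic signal (the series
#' plus i times its Hilbert transform). Phases are in radians, wrapped to
#' (-pi, pi]. The input should be narrowband (band-passed first):
#' instantaneous phase is only physically meaningful for narrowband
#' signals. Node series are demeaned before the transform.
#'
#' @param scan A [scan_record()] (band-passed).
#' @return An object of class `phase_series`: list with `theta` (nodes x
#'   volumes phase matrix), `tr_seconds` and the scan's labels.
#' @export
hilbert_phase <- function(scan) {
  stopifnot(inherits(scan, "scan_record"))
  x <- scan$data
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant (zero-variance) node series: node %s",
                 paste(which(sds == 0), collapse = ", ")))
  }
  theta <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    theta[i, ] <- Arg(analytic_signal(x[i, ] - mean(x[i, ])))
  }
  # Arg() returns [-pi, pi]; map -pi to +pi so phases lie in (-pi, pi]
  theta[theta == -pi] <- pi
  structure(list(theta = theta, tr_seconds = scan$tr_seconds,
                 subject_id = scan$subject_id, session_id = scan$session_id,
                 task = scan$task),
            class = "phase_series")
}

#' Trim the Hilbert edge artifact
#'
#' The discrete Hilbert transform distorts phase estimates at the start and
#' end of a series, so the first and last `k` volumes are removed after the
#' transform. Applies to phase series, leading-eigenvector series, and
#' per-volume flag/trace vectors.
#'
#' @param x A `phase_series`, `eigen_series`, `motion_flags`, or plain
#'   per-volume vector.
#' @param k Volumes to remove at each end (default 5).
#' @return Object of the same type with `2k` fewer volumes.
#' @export
trim_edge_artifact <- function(x, k = 5L) UseMethod("trim_edge_artifact")

trim_keep <- function(t_len, k) {
  k <- as.integer(k)
  stopifnot(k >= 0)
  if (t_len <= 2L * k) stop("series too short to trim k volumes at each end")
  if (k == 0L) return(seq_len(t_len))
  (k + 1L):(t_len - k)
}

#' @export
trim_edge_artifact.phase_series <- function(x, k = 5L) {
  keep <- trim_keep(ncol(x$theta), k)
  x$theta <- x$theta[, keep, drop = FALSE]
  x
}

#' @export
trim_edge_artifact.eigen_series <- function(x, k = 5L) {
  keep <- trim_keep(ncol(x$v1), k)
  x$v1 <- x$v1[, keep, drop = FALSE]
  x$lambda1 <- x$lambda1[keep]
  x$variance_fraction <- x$variance_fraction[keep]
  x
}

#' @export
trim_edge_artifact.default <- function(x, k = 5L) {
  keep <- trim_keep(if (is.matrix(x)) ncol(x) else length(x), k)
  if (is.matrix(x)) x[, keep, drop = FALSE] else x[keep]
}

#' Phase-coherence matrix of a single volume
#'
#' Element (i, j) is `cos(theta_i - theta_j)`: 1 when the two nodes' phases
#' are aligned, 0 in quadrature, -1 in antiphase. The result is symmetric
#' with unit diagonal, positive semidefinite, has trace N, and rank at most
#' 2 (it equals `cos(theta) cos(theta)' + sin(theta) sin(theta)'`).
#'
#' @param theta_t Numeric vector of phases (radians) for one volume.
#' @return N x N coherence matrix.
#' @export
phase_coherence_volume <- function(theta_t) {
  stopifnot(is.numeric(theta_t), all(is.finite(theta_t)))
  cos(outer(theta_t, theta_t, "-"))
}

# Fix eigenvector sign: entry of largest magnitude made positive.
fix_sign <- function(v) {
  if (v[which.max(abs(v))] < 0) -v else v
}

#' Leading eigenpair of a coherence volume
#'
#' Largest-eigenvalue eigenvector of a (symmetric PSD) coherence matrix,
#' sign-fixed so its largest-magnitude entry is positive. The variance
#' fraction is the leading eigenvalue over the trace; for a phase-coherence
#' volume the trace is N and the matrix has rank at most 2, so this fraction
#' is always at least 1/2.
#'
#' @param vol Symmetric N x N matrix.
#' @return List with `v1` (unit vector), `lambda1`, `variance_fraction`.
#' @export
leading_eigenvector <- function(vol) {
  stopifnot(is.matrix(vol), nrow(vol) == ncol(vol))
  e <- eigen(vol, symmetric = TRUE)
  v1 <- fix_sign(e$vectors[, 1L])
  lambda1 <- e$values[1L]
  list(v1 = v1, lambda1 = lambda1,
       variance_fraction = lambda1 / sum(diag(vol)))
}

#' Leading-eigenvector series of a scan's phase dynamics
#'
#' Computes the per-volume leading eigenpair of the phase-coherence matrix
#' for every volume, exploiting the rank-2 structure: with
#' `c = cos(theta_t)` and `s = sin(theta_t)` the coherence matrix is
#' `c c' + s s'`, so its nonzero spectrum is that of the 2 x 2 Gram matrix
#' of `(c, s)` and the leading eigenvector lies in their span. This is
#' O(N) per volume and exact, and is cross-checked against dense
#' eigendecomposition in the test suite.
#'
#' @param phases A `phase_series` (see [hilbert_phase()]).
#' @return An object of class `eigen_series`: `v1` (nodes x volumes matrix
#'   of unit eigenvectors, sign-fixed), `lambda1`, `variance_fraction`,
#'   labels and `tr_seconds`.
#' @export
leading_eigen_series <- function(phases) {
  stopifnot(inherits(phases, "phase_series"))
  th <- phases$theta
  n <- nrow(th)
  cth <- cos(th)
  sth <- sin(th)
  a <- colSums(cth * cth)
  b <- colSums(cth * sth)
  d <- colSums(sth * sth)
  disc <- sqrt((a - d)^2 + 4 * b^2)
  lambda1 <- (a + d + disc) / 2
  # eigenvector of [[a, b], [b, d]] for lambda1; choose the formulation
  # with the larger norm for numerical stability
  u1a <- b
  u2a <- lambda1 - a
  u1b <- lambda1 - d
  u2b <- b
  use_b <- (u1b^2 + u2b^2) > (u1a^2 + u2a^2)
  u1 <- ifelse(use_b, u1b, u1a)
  u2 <- ifelse(use_b, u2b, u2a)
  # degenerate case b = 0 and a = lambda1: eigenvector is (1, 0)
  zero <- (u1^2 + u2^2) == 0
  u1[zero] <- 1
  u2[zero] <- 0
  v <- cth * rep(u1, each = n) + sth * rep(u2, each = n)
  nrm <- sqrt(colSums(v * v))
  v <- sweep(v, 2L, nrm, "/")
  for (t in seq_len(ncol(v))) v[, t] <- fix_sign(v[, t])
  structure(list(v1 = v, lambda1 = lambda1,
                 variance_fraction = lambda1 / n,
                 tr_seconds = phases$tr_seconds,
                 subject_id = phases$subject_id,
                 session_id = phases$session_id, task = phases$task),
            class = "eigen_series")
}

#' @export
print.eigen_series <- function(x, ...) {
  cat(sprintf("<eigen_series> subject=%s session=%s task=%s  %d nodes x %d volumes; min var. fraction %.3f\n",
              x$subject_id, x$session_id, x$task, nrow(x$v1), ncol(x$v1),
              min(x$variance_fraction)))
  invisible(x)
}

#' Rank-1 reconstruction of a coherence volume
#'
#' Outer product of the leading eigenvector, optionally scaled by its
#' eigenvalue. The eigenvalue-scaled form is the best rank-1 approximation
#' of the coherence matrix in Frobenius norm; the time-collapse step uses
#' it by default so that per-volume energy is preserved.
#'
#' @param v1 Unit eigenvector.
#' @param lambda1 Optional leading eigenvalue; if supplied the outer
#'   product is scaled by it.
#' @return N x N matrix.
#' @export
reconstruct_outer <- function(v1, lambda1 = NULL) {
  m <- tcrossprod(v1)
  if (!is.null(lambda1)) m <- lambda1 * m
  m
}

#' Collapse a volume series across time
#'
#' Elementwise sum over volumes of the rank-1 reconstructions. For an
#' `eigen_series` this is computed without materializing per-volume
#' matrices; `weighted = TRUE` (default) scales each outer product by its
#' leading eigenvalue. The collapsed matrix of a narrowband scan is nearly
#' perfectly correlated (off-diagonal) with the scan's static Pearson
#' network.
#'
#' @param x An `eigen_series`, or a list of N x N matrices.
#' @param weighted Scale each volume's outer product by its leading
#'   eigenvalue (ignored for a plain list of matrices).
#' @return N x N matrix.
#' @export
collapse_time <- function(x, weighted = TRUE) {
  if (inherits(x, "eigen_series")) {
    if (ncol(x$v1) < 1L) stop("empty series")
    w <- if (weighted) x$lambda1 else rep(1, ncol(x$v1))
    return(tcrossprod(sweep(x$v1, 2L, w, "*"), x$v1))
  }
  if (is.list(x)) {
    if (length(x) == 0L) stop("empty series")
    return(Reduce(`+`, x))
  }
  stop("x must be an eigen_series or a list of matrices")
}

#' Static functional network of a scan
#'
#' Pairwise Pearson correlation of the node time series: the conventional
#' scan-averaged connectivity estimate that the per-volume phase-coherence
#' description refines.
#'
#' @param scan A [scan_record()] with at least 3 volumes.
#' @return N x N correlation matrix.
#' @export
static_network <- function(scan) {
  stopifnot(inherits(scan, "scan_record"), n_volumes(scan) >= 3L)
  sds <- apply(scan$data, 1L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance node series: node %s",
                 paste(which(sds == 0), collapse = ", ")))
  }
  stats::cor(t(scan$data))
}

#' Scan to trimmed leading-eigenvector series
#'
#' Convenience composition: Hilbert phases, per-volume leading eigenpairs,
#' edge-artifact trimming.
#'
#' @param scan A preprocessed [scan_record()].
#' @param trim Volumes trimmed at each end after the Hilbert transform.
#' @return A trimmed `eigen_series`.
#' @export
eigen_series_from_scan <- function(scan, trim = 5L) {
  trim_edge_artifact(leading_eigen_series(hilbert_phase(scan)), k = trim)
}
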