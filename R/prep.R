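# Node-level preprocessing: steady-state trimming, band-pass filtering,
# confound regression, motion flagging, tSNR.

# Minimum series length for stable zero-phase Butterworth filtering. The
# 2nd-order band-pass has 5 coefficients; forward-backward filtering needs
# comfortably more samples than the filter's transient (~3x its length per
# pass). 30 volumes is the enforced floor.
min_filter_length <- function() 30L

#' Preprocessing configuration
#'
#' @param steady_state_drop Leading volumes to discard so the signal has
#'   reached equilibrium (5 at TR 2.2 s, 10 at TR 2.0 s in the presets).
#' @param band_low_hz,band_high_hz Pass band in Hz (defaults 0.009-0.08).
#' @param regress_global_mean Include the scan's global mean signal as a
#'   nuisance regressor (toggleable: the merits of global signal regression
#'   are debated, so the pipeline can run both ways).
#' @param regress_motion_spikes Include the binary high-motion volume
#'   indicator as an additional nuisance regressor.
#' @param motion_fd_threshold_mm Framewise-displacement threshold for the
#'   high-motion flag (default 0.5 mm).
#' @param bold_change_threshold_fraction Global-signal change threshold, as
#'   a fraction of the scan's mean global signal (default 0.05).
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(steady_state_drop = 5,
                           band_low_hz = 0.009, band_high_hz = 0.08,
                           regress_global_mean = TRUE,
                           regress_motion_spikes = TRUE,
                           motion_fd_threshold_mm = 0.5,
                           bold_change_threshold_fraction = 0.05) {
  stopifnot(steady_state_drop >= 0,
            band_low_hz > 0, band_low_hz < band_high_hz,
            motion_fd_threshold_mm > 0,
            bold_change_threshold_fraction > 0,
            is.logical(regress_global_mean), is.logical(regress_motion_spikes))
  structure(list(
    steady_state_drop = as.integer(steady_state_drop),
    band_low_hz = band_low_hz, band_high_hz = band_high_hz,
    regress_global_mean = regress_global_mean,
    regress_motion_spikes = regress_motion_spikes,
    motion_fd_threshold_mm = motion_fd_threshold_mm,
    bold_change_threshold_fraction = bold_change_threshold_fraction
  ), class = "preproc_config")
}

#' Drop initial (steady-state) volumes
#'
#' Removes the first `k` volumes from the data matrix and from the motion
#' and global-signal traces. The first retained volume's framewise
#' displacement is reset to 0 (it has no preceding frame).
#'
#' @param scan A [scan_record()].
#' @param k Number of volumes to drop (`k < n_volumes(scan)`).
#' @return A `scan_record` with `n_volumes - k` volumes.
#' @export
drop_initial_volumes <- function(scan, k) {
  stopifnot(inherits(scan, "scan_record"), k >= 0)
  t_len <- n_volumes(scan)
  if (k >= t_len) stop("cannot drop k >= number of volumes")
  if (k == 0L) return(scan)
  keep <- (k + 1L):t_len
  scan$data <- scan$data[, keep, drop = FALSE]
  scan$motion_fd <- scan$motion_fd[keep]
  scan$motion_fd[1L] <- 0
  scan$global_signal <- scan$global_signal[keep]
  scan
}

# Zero-phase 2nd-order Butterworth band-pass applied to each row of a
# nodes x volumes matrix. Rows are demeaned first; the pass band excludes
# DC, so output rows have (numerically) zero mean.
bp_filter_matrix <- function(x, tr_seconds, band_low_hz, band_high_hz) {
  t_len <- ncol(x)
  if (t_len < min_filter_length()) {
    stop(sprintf("need at least %d volumes for stable band-pass filtering, got %d",
                 min_filter_length(), t_len))
  }
  if (!all(is.finite(x))) stop("non-finite values in input to band-pass filter")
  nyq <- 1 / (2 * tr_seconds)
  if (band_high_hz >= nyq) stop("band_high_hz must be below the Nyquist frequency")
  bf <- signal::butter(2, c(band_low_hz, band_high_hz) / nyq, type = "pass")
  out <- x
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    f <- signal::filtfilt(bf, row - mean(row))
    # filtfilt's finite-length transients leave a tiny residual mean even
    # though the pass band excludes DC; remove it exactly
    out[i, ] <- f - mean(f)
  }
  out
}

#' Band-pass filter a scan
#'
#' Applies a zero-phase (forward-backward) 2nd-order Butterworth band-pass
#' to every node series. Zero-phase filtering matters here because the
#' instantaneous phases extracted downstream would be corrupted by filter
#' phase distortion. The raw motion and global-signal traces are preserved.
#'
#' @param scan A [scan_record()].
#' @param config A [preproc_config()].
#' @return A `scan_record` with filtered (zero-mean) node series.
#' @export
bandpass <- function(scan, config = preproc_config()) {
  stopifnot(inherits(scan, "scan_record"), inherits(config, "preproc_config"))
  scan$data <- bp_filter_matrix(scan$data, scan$tr_seconds,
                                config$band_low_hz, config$band_high_hz)
  scan
}

#' Regress confounds from every node series
#'
#' Replaces each node series by its least-squares residual against an
#' intercept plus the supplied regressor columns. Collinear columns are
#' dropped with a warning.
#'
#' @param scan A [scan_record()].
#' @param regressors Numeric matrix with `n_volumes(scan)` rows (0 or more
#'   columns); `NULL` means intercept-only (demeaning).
#' @return A `scan_record` of residual series.
#' @export
regress_confounds <- function(scan, regressors = NULL) {
  stopifnot(inherits(scan, "scan_record"))
  t_len <- n_volumes(scan)
  if (is.null(regressors)) {
    regressors <- matrix(numeric(0), nrow = t_len, ncol = 0)
  }
  regressors <- as.matrix(regressors)
  stopifnot(nrow(regressors) == t_len)
  if (!all(is.finite(regressors))) stop("non-finite regressor values")
  design <- cbind(intercept = 1, regressors)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- qrd$pivot[(qrd$rank + 1L):ncol(design)]
    warning(sprintf("dropping %d collinear regressor column(s): %s",
                    length(dropped),
                    paste(colnames(design)[dropped] %||% dropped, collapse = ", ")))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  scan$data <- t(qr.resid(qrd, t(scan$data)))
  scan
}

#' Flag high-motion volumes
#'
#' A volume is flagged if and only if both conditions hold: framewise
#' displacement at least `motion_fd_threshold_mm`, and absolute
#' global-signal change from the previous volume of at least
#' `bold_change_threshold_fraction` of the scan's mean global signal. The
#' first volume is never flagged (no previous frame).
#'
#' @param scan A [scan_record()] with motion and global-signal traces.
#' @param config A [preproc_config()].
#' @return Logical vector of length `n_volumes(scan)`, class `motion_flags`.
#' @export
flag_motion_volumes <- function(scan, config = preproc_config()) {
  stopifnot(inherits(scan, "scan_record"), inherits(config, "preproc_config"))
  g <- scan$global_signal
  fd <- scan$motion_fd
  if (is.null(g) || is.null(fd)) stop("motion and global-signal traces are required")
  ref <- abs(mean(g))
  if (ref == 0) stop("mean global signal is zero; percent change undefined")
  change <- c(0, abs(diff(g))) / ref
  flags <- fd >= config$motion_fd_threshold_mm &
    change >= config$bold_change_threshold_fraction
  flags[1L] <- FALSE
  structure(flags, class = "motion_flags")
}

#' Temporal signal-to-noise ratio per node
#'
#' tSNR is the temporal mean divided by the temporal standard deviation of
#' each node's series, conventionally computed on the raw (unfiltered,
#' unregressed) series. Zero-variance nodes are undefined and returned as
#' `NA` (excluded from any averaging).
#'
#' @param scan A [scan_record()] with at least 2 volumes.
#' @return Numeric vector of per-node tSNR values (`NA` where undefined),
#'   with attribute `undefined` listing the excluded node indices.
#' @export
compute_tsnr <- function(scan) {
  stopifnot(inherits(scan, "scan_record"), n_volumes(scan) >= 2L)
  m <- rowMeans(scan$data)
  s <- apply(scan$data, 1L, stats::sd)
  tsnr <- ifelse(s > 0, m / s, NA_real_)
  structure(tsnr, undefined = which(s == 0))
}

#' Run the full node-level preprocessing pipeline on one scan
#'
#' Fixed order: steady-state drop, motion flagging (from the raw traces),
#' band-pass filtering, confound regression (global mean signal if enabled,
#' plus the binary high-motion indicator if enabled and any volume is
#' flagged). The flags are attached to the result as `scan$motion_flags`.
#'
#' @param scan A [scan_record()].
#' @param config A [preproc_config()].
#' @return A processed `scan_record` with a `motion_flags` element.
#' @export
process_scan <- function(scan, config = preproc_config()) {
  scan <- drop_initial_volumes(scan, config$steady_state_drop)
  flags <- flag_motion_volumes(scan, config)
  scan <- bandpass(scan, config)
  regs <- NULL
  if (config$regress_global_mean) {
    regs <- cbind(regs, global = scan$global_signal - mean(scan$global_signal))
  }
  if (config$regress_motion_spikes && any(flags)) {
    regs <- cbind(regs, spikes = as.numeric(flags))
  }
  scan <- regress_confounds(scan, regs)
  scan$motion_flags <- flags
  scan
}
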