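# Shared builders for small synthetic fixtures. Everything is generated in
# code at test time; no stored data.

# A compact identity-structured cohort: subject signal vs session noise.
small_identity_config <- function(seed, n_subjects = 5, n_sessions = 3,
                                  n_nodes = 40, n_volumes = 120,
                                  subject_weight = 1,
                                  session_noise_weight = 2,
                                  n_units = max(2 * n_nodes, 100), ...) {
  cohort_config(n_subjects = n_subjects, n_sessions = n_sessions,
                n_nodes = n_nodes, n_volumes = n_volumes,
                subject_weight = subject_weight, task_weight = 0,
                subject_task_weight = 0,
                session_noise_weight = session_noise_weight,
                n_units = n_units, seed = seed, ...)
}

# Cohort -> trimmed eigen series, suppressing benign tie warnings.
quiet_pipeline <- function(cohort, ...) {
  suppressWarnings(cohort_eigen_series(cohort, ...))
}

quiet_identify <- function(series, database_size, ...) {
  suppressWarnings(run_identification(series, database_size = database_size, ...))
}

# Single-node scan holding a pure sampled sinusoid.
sinusoid_scan <- function(freq_hz, tr = 2.2, n_volumes = 400, phase = 0) {
  tt <- (seq_len(n_volumes) - 1) * tr
  scan_record("sub-01", "ses-01", "rest",
              matrix(cos(2 * pi * freq_hz * tt + phase), nrow = 1), tr)
}

# Fraction of a series' spectral power (DC excluded) inside [lo, hi] Hz.
inband_power_fraction <- function(x, tr, lo, hi) {
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2
  n <- length(x)
  fr <- (seq_len(n) - 1) / (n * tr)
  half <- 2:floor(n / 2)
  sum(p[half][fr[half] >= lo & fr[half] <= hi]) / sum(p[half])
}

# Unit vectors with a prescribed correlation to a reference, built by
# Gram-Schmidt: returns v with cor(ref, v) == rho (up to numerics).
vector_with_correlation <- function(ref, rho, seed = 1) {
  set.seed(seed)
  n <- length(ref)
  z <- stats::rnorm(n)
  refc <- scale(ref)[, 1]
  zc <- scale(stats::residuals(stats::lm(z ~ ref)))[, 1]
  rho * refc + sqrt(1 - rho^2) * zc
}

# Hand-rolled eigen series from an explicit eigenvector matrix.
manual_eigen_series <- function(v1, subject = "sub-01", session = "ses-01",
                                task = "rest", lambda1 = NULL) {
  structure(list(v1 = v1,
                 lambda1 = lambda1 %||% rep(nrow(v1), ncol(v1)),
                 variance_fraction = rep(1, ncol(v1)),
                 tr_seconds = 2.2, subject_id = subject,
                 session_id = session, task = task),
            class = "eigen_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
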