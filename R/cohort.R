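#' Configuration for a synthetic BOLD cohort
#'
#' Defines a multi-subject, multi-session, multi-task cohort of band-limited
#' node time series with a shared group component, a stable subject-specific
#' component, task and subject-by-task components, and session noise. The
#' latent signal lives on `n_units` acquisition units whose covariance for
#' subject s on task k is
#' \deqn{\Sigma(s,k) = w_G G G' + w_S S_s S_s' + w_K K_k K_k' + w_{SK} I_{sk} I_{sk}' + w_E I}
#' where each factor is an `n_units x latent_rank` standard-normal matrix
#' drawn once per cohort, and \eqn{w_E} is the session noise weight. Each
#' session is an independent Gaussian draw with that covariance.
#'
#' A parcellation of `n_nodes` nodes partitions the units into contiguous,
#' balanced blocks; a node's series is the mean of its units' series, plus
#' node-level measurement noise with fixed standard deviation
#' `node_noise_sd`, band-limited to `[band_low_hz, band_high_hz]` and
#' offset by `baseline`. Because the unit-level draws depend only on
#' `n_units` and `seed`, the same seed at two different `n_nodes` values
#' yields the same underlying cohort observed at two parcellation
#' granularities. Coarser nodes average more units, so their fluctuations
#' shrink relative to the fixed measurement noise: coarse parcellations
#' have higher temporal signal-to-noise but blur the individual signal -
#' the trade-off that node-count and node-size experiments probe.
#'
#' @param n_subjects,n_sessions,n_nodes Counts (2 <= n_nodes <= n_units).
#' @param n_volumes Volumes per resting-state scan, before any trimming.
#' @param n_task_volumes Volumes per non-rest task scan (defaults to
#'   `n_volumes`).
#' @param tr_seconds Repetition time in seconds.
#' @param tasks Character vector of task labels; the first must be "rest".
#' @param group_weight,subject_weight,task_weight,subject_task_weight,session_noise_weight
#'   Nonnegative variance weights of the covariance components.
#' @param latent_rank Rank of each low-rank covariance factor.
#' @param band_low_hz,band_high_hz Pass band; must satisfy
#'   `band_low_hz < band_high_hz < 1/(2 tr_seconds)`.
#' @param motion_spike_rate Per-volume probability of an injected motion
#'   spike (see [generate_motion()]).
#' @param baseline Mean signal level added to every node (arbitrary units;
#'   keeps global-signal percent changes and tSNR well-defined).
#' @param n_units Number of latent acquisition units (see Details).
#' @param node_noise_sd Node-level measurement noise standard deviation
#'   (does not shrink with parcellation coarseness).
#' @param steady_state_drop Volumes to discard at scan start during
#'   preprocessing (stored here so presets carry the full protocol).
#' @param seed Integer seed; identical configurations generate bit-identical
#'   cohorts.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [cohort_preset()]
#' @export
cohort_config <- function(n_subjects = 10, n_sessions = 10, n_nodes = 100,
                          n_volumes = 818, n_task_volumes = n_volumes,
                          tr_seconds = 2.2, tasks = "rest",
                          group_weight = 1, subject_weight = 1,
                          task_weight = 0.5, subject_task_weight = 0.25,
                          session_noise_weight = 1, latent_rank = 5,
                          band_low_hz = 0.009, band_high_hz = 0.08,
                          motion_spike_rate = 0, baseline = 100,
                          n_units = 1000, node_noise_sd = 0.3,
                          steady_state_drop = 5, seed = 1L) {
  w <- c(group_weight, subject_weight, task_weight, subject_task_weight,
         session_noise_weight)
  if (!all(is.finite(w)) || any(w < 0)) {
    stop("mixing weights must be finite and nonnegative")
  }
  stopifnot(n_subjects >= 1, n_sessions >= 1, n_nodes >= 2,
            latent_rank >= 1, tr_seconds > 0,
            length(tasks) >= 1, is.character(tasks),
            motion_spike_rate >= 0, motion_spike_rate <= 1,
            baseline >= 0, n_units >= n_nodes, node_noise_sd >= 0,
            steady_state_drop >= 0)
  if (tasks[1L] != "rest") stop("the first task label must be \"rest\"")
  if (anyDuplicated(tasks)) stop("task labels must be unique")
  if (!(band_low_hz < band_high_hz && band_high_hz < 1 / (2 * tr_seconds))) {
    stop("require band_low_hz < band_high_hz < Nyquist = 1/(2*tr_seconds)")
  }
  min_t <- min_filter_length()
  if (n_volumes < max(min_t, 2 * 5 + 2) || n_task_volumes < max(min_t, 12)) {
    stop(sprintf("scans need at least %d volumes for stable filtering and edge trimming",
                 max(min_t, 12)))
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_sessions = as.integer(n_sessions),
    n_nodes = as.integer(n_nodes), n_volumes = as.integer(n_volumes),
    n_task_volumes = as.integer(n_task_volumes),
    tr_seconds = tr_seconds, tasks = tasks,
    group_weight = group_weight, subject_weight = subject_weight,
    task_weight = task_weight, subject_task_weight = subject_task_weight,
    session_noise_weight = session_noise_weight,
    latent_rank = as.integer(latent_rank),
    band_low_hz = band_low_hz, band_high_hz = band_high_hz,
    motion_spike_rate = motion_spike_rate, baseline = baseline,
    n_units = as.integer(n_units), node_noise_sd = node_noise_sd,
    steady_state_drop = as.integer(steady_state_drop),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Study-shaped cohort presets
#'
#' Returns a [cohort_config()] whose dimensions mirror one of three study
#' designs so that chance-level and volume-count arithmetic match the
#' corresponding real protocols:
#' \itemize{
#'   \item `"msc"`: 10 subjects x 10 sessions, 100 nodes, 818 raw rest
#'     volumes (121 per task scan), TR 2.2 s, 5 steady-state volumes dropped.
#'   \item `"ncanda"`: 100 subjects x 6 sessions, 100 nodes, 274 raw
#'     volumes, TR 2.2 s, 5 dropped.
#'   \item `"bnet"`: 173 subjects x 2 sessions, 100 nodes, 217 raw volumes,
#'     TR 2.0 s, 10 dropped.
#' }
#' Volume counts are the raw acquisition counts; dropping the steady-state
#' volumes and trimming 5 volumes at each end after the Hilbert transform
#' yields 803 / 259 / 197 analyzed volumes (106 for MSC task scans).
#'
#' @param preset One of "msc", "ncanda", "bnet".
#' @param ... Overrides passed on to [cohort_config()] (e.g. signal weights,
#'   `tasks = c("rest", "faces", "words")`, a smaller `n_subjects`).
#' @return A `cohort_config`.
#' @export
cohort_preset <- function(preset = c("msc", "ncanda", "bnet"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    msc    = list(n_subjects = 10, n_sessions = 10, n_nodes = 100,
                  n_volumes = 818, n_task_volumes = 121, tr_seconds = 2.2,
                  steady_state_drop = 5),
    ncanda = list(n_subjects = 100, n_sessions = 6, n_nodes = 100,
                  n_volumes = 274, n_task_volumes = 274, tr_seconds = 2.2,
                  steady_state_drop = 5),
    bnet   = list(n_subjects = 173, n_sessions = 2, n_nodes = 100,
                  n_volumes = 217, n_task_volumes = 217, tr_seconds = 2.0,
                  steady_state_drop = 10)
  )
  args <- utils::modifyList(base, list(...))
  do.call(cohort_config, args)
}

subject_labels <- function(n) sprintf("sub-%02d", seq_len(n))
session_labels <- function(n) sprintf("ses-%02d", seq_len(n))

# Balanced contiguous assignment of latent units to nodes.
unit_membership <- function(n_units, n_nodes) {
  as.integer(ceiling(seq_len(n_units) * n_nodes / n_units))
}

#' Generate a synthetic cohort of scans
#'
#' Draws the unit-level covariance factors once from the configured seed,
#' then simulates every subject x session x task scan: fresh latent series
#' per component plus white session noise at the unit level, averaged into
#' nodes, plus node-level measurement noise, band-limited with the same
#' zero-phase Butterworth filter used in preprocessing, offset by the
#' baseline. A sub-threshold framewise displacement trace is attached; if
#' `motion_spike_rate > 0`, [generate_motion()] is applied to each scan.
#' The same configuration (including seed) yields a bit-identical cohort;
#' the same seed at a different `n_nodes` yields the same underlying
#' signals observed at a different parcellation granularity.
#'
#' @param config A [cohort_config()].
#' @return List of [scan_record()]s, subject-major then session then task.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_nodes
  u <- config$n_units
  r <- config$latent_rank
  subs <- subject_labels(config$n_subjects)
  sess <- session_labels(config$n_sessions)
  tasks <- config$tasks
  member <- unit_membership(u, n)
  upn <- tabulate(member, nbins = n)

  set.seed(config$seed)
  fac_g <- matrix(stats::rnorm(u * r), u, r)
  fac_s <- lapply(seq_along(subs), function(i) matrix(stats::rnorm(u * r), u, r))
  fac_k <- lapply(seq_along(tasks), function(i) matrix(stats::rnorm(u * r), u, r))
  fac_sk <- lapply(seq_along(subs), function(i) {
    lapply(seq_along(tasks), function(j) matrix(stats::rnorm(u * r), u, r))
  })

  scans <- vector("list", length(subs) * length(sess) * length(tasks))
  idx <- 0L
  for (si in seq_along(subs)) {
    for (ei in seq_along(sess)) {
      for (ki in seq_along(tasks)) {
        idx <- idx + 1L
        t_len <- if (tasks[ki] == "rest") config$n_volumes else config$n_task_volumes
        set.seed(mix_seed(config$seed, "scan", si, ei, ki))
        xu <- sqrt(config$group_weight) * (fac_g %*% matrix(stats::rnorm(r * t_len), r)) +
          sqrt(config$subject_weight) * (fac_s[[si]] %*% matrix(stats::rnorm(r * t_len), r)) +
          sqrt(config$task_weight) * (fac_k[[ki]] %*% matrix(stats::rnorm(r * t_len), r)) +
          sqrt(config$subject_task_weight) * (fac_sk[[si]][[ki]] %*% matrix(stats::rnorm(r * t_len), r)) +
          sqrt(config$session_noise_weight) * matrix(stats::rnorm(u * t_len), u)
        x <- rowsum(xu, member) / upn
        if (config$node_noise_sd > 0) {
          x <- x + matrix(stats::rnorm(n * t_len, sd = config$node_noise_sd), n)
        }
        x <- bp_filter_matrix(x, config$tr_seconds,
                              config$band_low_hz, config$band_high_hz)
        x <- x + config$baseline
        fd <- c(0, pmin(abs(stats::rnorm(t_len - 1L, 0.12, 0.06)), 0.45))
        rec <- scan_record(subs[si], sess[ei], tasks[ki], x,
                           config$tr_seconds, motion_fd = fd)
        if (config$motion_spike_rate > 0) rec <- generate_motion(config, rec)
        scans[[idx]] <- rec
      }
    }
  }
  scans
}

#' Inject motion spikes into a scan
#'
#' At each post-first volume, with probability `motion_spike_rate`, injects a
#' head-motion artifact: framewise displacement drawn in `[0.5, 1.5]` mm, a
#' global-signal step of at least 5.5% of the scan's mean signal, and
#' broadband per-node noise (3x the median node standard deviation) that
#' corrupts the volume's phase pattern. Non-spike volumes keep their
#' sub-threshold displacement. Deterministic given `seed`; the default seed
#' is derived from the cohort seed and the scan's labels, so regenerating
#' the same scan reproduces the same spikes.
#'
#' @param config A [cohort_config()].
#' @param scan A [scan_record()].
#' @param seed Integer seed; defaults to a label-derived seed.
#' @return The updated `scan_record` (with recomputed global signal).
#' @export
generate_motion <- function(config, scan, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(scan, "scan_record"))
  if (is.null(seed)) {
    seed <- mix_seed(config$seed, "motion",
                     scan$subject_id, scan$session_id, scan$task)
  }
  t_len <- n_volumes(scan)
  set.seed(seed)
  spikes <- which(stats::runif(t_len - 1L) < config$motion_spike_rate) + 1L
  if (length(spikes)) {
    mg <- abs(mean(scan$global_signal))
    if (mg == 0) mg <- 1
    node_sd <- stats::median(apply(scan$data, 1L, stats::sd))
    # each spike offsets the whole volume so that the global signal jumps
    # by at least 6% of the mean signal relative to the previous volume,
    # even when spikes are consecutive; the offset walk is steered back
    # toward zero so long spike runs do not drift
    prev_offset <- 0
    offset <- numeric(t_len)
    for (t in seq_len(t_len)) {
      if (t %in% spikes) {
        mag <- stats::runif(1L, 0.07, 0.12) * mg
        sgn <- if (abs(prev_offset) > 0.15 * mg) -sign(prev_offset)
               else sample(c(-1, 1), 1L)
        offset[t] <- prev_offset + sgn * mag
        noise <- stats::rnorm(n_nodes(scan), sd = 3 * node_sd)
        # center across nodes so the phase pattern is corrupted without
        # blurring the controlled global-signal jump
        scan$data[, t] <- scan$data[, t] + offset[t] + noise - mean(noise)
        scan$motion_fd[t] <- stats::runif(1L, 0.5, 1.5)
      }
      prev_offset <- offset[t]
    }
    scan$global_signal <- colMeans(scan$data)
  }
  scan
}

#' Assign nodes to subnetworks
#'
#' Balanced-as-possible random assignment of `n_nodes` nodes to
#' `n_subnetworks` groups (default 17, the canonical cortical subnetwork
#' count): subnetwork sizes differ by at most one, and the assignment is a
#' seeded random permutation.
#'
#' @param n_nodes Number of nodes (>= `n_subnetworks`).
#' @param n_subnetworks Number of groups.
#' @param seed Integer seed.
#' @return Integer vector of length `n_nodes` with values in
#'   `1:n_subnetworks`, class `subnetwork_map`.
#' @export
make_subnetwork_map <- function(n_nodes, n_subnetworks = 17, seed = 1L) {
  if (n_nodes < n_subnetworks) {
    stop("n_nodes must be at least n_subnetworks")
  }
  base <- rep(seq_len(n_subnetworks), length.out = n_nodes)
  set.seed(as.integer(seed))
  structure(as.integer(sample(base)), class = "subnetwork_map",
            n_subnetworks = as.integer(n_subnetworks))
}
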