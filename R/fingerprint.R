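# The identification engine: single-volume matching against a labeled
# database, scan-level voting, permutation nulls, sweeps, and the static
# baseline.

#' Similarity between two leading eigenvectors
#'
#' Absolute Pearson correlation. The absolute value is taken because an
#' eigenvector and its negation produce the identical outer-product
#' (coherence) pattern, so correlations of -1 and +1 indicate equally
#' similar volumes.
#'
#' @param v_a,v_b Numeric vectors of equal length (>= 3), non-constant.
#' @return Value in `[0, 1]`.
#' @export
similarity <- function(v_a, v_b) {
  stopifnot(length(v_a) == length(v_b), length(v_a) >= 3L)
  if (stats::sd(v_a) == 0 || stats::sd(v_b) == 0) {
    stop("similarity is undefined for a constant vector")
  }
  abs(stats::cor(v_a, v_b))
}

#' Build a database pool of eigenvector series
#'
#' Collects labeled eigenvector series to match target volumes against.
#' Entries are sorted by (subject, session, task) so that argmax ties break
#' deterministically toward the lexicographically lowest entry.
#'
#' @param series List of `eigen_series` (see [eigen_series_from_scan()]).
#' @param label_kind `"identity"` (predict the subject) or `"task"`.
#' @return Object of class `database_pool`.
#' @export
database_pool <- function(series, label_kind = c("identity", "task")) {
  label_kind <- match.arg(label_kind)
  stopifnot(length(series) >= 1L,
            all(vapply(series, inherits, logical(1), "eigen_series")))
  ord <- order(vapply(series, `[[`, character(1), "subject_id"),
               vapply(series, `[[`, character(1), "session_id"),
               vapply(series, `[[`, character(1), "task"))
  series <- series[ord]
  labels <- vapply(series, `[[`, character(1),
                   if (label_kind == "identity") "subject_id" else "task")
  structure(list(series = series, labels = labels, label_kind = label_kind),
            class = "database_pool")
}

# Standardized (zero-mean, unit-norm columns) eigenvector matrix, so that
# crossprod() of two standardized matrices is the matrix of Pearson r's.
std_v1 <- function(es) {
  standardize_columns(es$v1,
                      what = sprintf("eigenvectors of %s/%s/%s",
                                     es$subject_id, es$session_id, es$task))
}

# Per-target-volume best match against one database series. Returns the
# best |r| and the best volume index within that series; ties within a
# series resolve to the lowest volume index.
pair_best <- function(tz, dz) {
  s <- abs(crossprod(tz, dz))
  best <- max.col(s, ties.method = "first")
  list(sim = s[cbind(seq_len(nrow(s)), best)], vol = best)
}

#' Match one target volume against a database pool
#'
#' Finds the database volume with the highest absolute Pearson correlation
#' to the target eigenvector. Exact ties are broken toward the entry that
#' is lowest in (subject, session, task, volume) lexicographic order, with
#' a warning.
#'
#' @param target_v1 Numeric eigenvector (length N).
#' @param pool A [database_pool()].
#' @return List with `best_entry` (subject, session, task, volume),
#'   `similarity`, and `predicted_label`.
#' @export
match_volume <- function(target_v1, pool) {
  stopifnot(inherits(pool, "database_pool"), length(pool$series) >= 1L)
  tz <- standardize_columns(matrix(target_v1, ncol = 1L), "target eigenvector")
  best_sim <- -Inf
  best <- NULL
  tied <- FALSE
  for (j in seq_along(pool$series)) {
    pb <- pair_best(tz, std_v1(pool$series[[j]]))
    if (pb$sim > best_sim) {
      best_sim <- pb$sim
      es <- pool$series[[j]]
      best <- list(subject_id = es$subject_id, session_id = es$session_id,
                   task = es$task, volume = pb$vol, label = pool$labels[j])
      tied <- FALSE
    } else if (pb$sim == best_sim) {
      tied <- TRUE
    }
  }
  if (tied) warning("exact similarity tie; keeping the lexicographically lowest entry")
  list(best_entry = best[c("subject_id", "session_id", "task", "volume")],
       similarity = as.numeric(best_sim),
       predicted_label = best$label)
}

# Majority vote with ties broken by the larger summed similarity across the
# tied label's winning volumes (warns on a tie).
vote_label <- function(pred_labels, sims) {
  tab <- table(pred_labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    warning("scan-level vote tie; breaking by summed similarity")
    sums <- vapply(top, function(lb) sum(sims[pred_labels == lb]), numeric(1))
    top <- top[order(-sums, top)]
  }
  top[1L]
}

#' Identify the label of one target scan
#'
#' Matches every target volume against every database volume; each volume
#' votes for the label of its best match, and the scan-level prediction is
#' the majority vote (ties broken by summed similarity).
#'
#' @param target A trimmed `eigen_series`.
#' @param pool A [database_pool()]; must not contain the target scan itself
#'   unless deliberately testing self-consistency.
#' @param true_label The target's true label (defaults to its subject or
#'   task per the pool's `label_kind`).
#' @return Object of class `scan_prediction`: per-volume predicted labels,
#'   winner bookkeeping, vote counts, `predicted_label`,
#'   `n_correct_volumes`, `volume_accuracy`, and `correct`.
#' @export
identify_scan <- function(target, pool, true_label = NULL) {
  stopifnot(inherits(target, "eigen_series"), inherits(pool, "database_pool"))
  if (is.null(true_label)) {
    true_label <- if (pool$label_kind == "identity") target$subject_id else target$task
  }
  tz <- std_v1(target)
  n_vol <- ncol(tz)
  sims <- matrix(0, n_vol, length(pool$series))
  for (j in seq_along(pool$series)) {
    sims[, j] <- pair_best(tz, std_v1(pool$series[[j]]))$sim
  }
  winner <- max.col(sims, ties.method = "first")
  win_sim <- sims[cbind(seq_len(n_vol), winner)]
  pred <- pool$labels[winner]
  correct <- pred == true_label
  vote_counts <- table(factor(pred, levels = sort(unique(pool$labels))))
  predicted <- vote_label(pred, win_sim)
  structure(list(
    true_label = true_label, predicted_label = predicted,
    correct = predicted == true_label,
    vote_counts = vote_counts,
    per_volume_label = pred, per_volume_correct = correct,
    winner_entry = winner, winner_similarity = win_sim,
    n_correct_volumes = sum(correct), n_volumes = n_vol,
    volume_accuracy = mean(correct)
  ), class = "scan_prediction")
}

#' Enumerate database subsets
#'
#' All size-`k` subsets of `n` candidate database sessions, in the
#' deterministic order produced by [utils::combn()].
#'
#' @param n_candidates Number of available database sessions.
#' @param k Subset size (`1 <= k <= n_candidates`).
#' @return List of integer vectors.
#' @export
enumerate_database_subsets <- function(n_candidates, k) {
  stopifnot(k >= 1L, k <= n_candidates)
  m <- utils::combn(n_candidates, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Expected correct volumes under random guessing
#'
#' The number of target-scan volumes expected to pick the correct label by
#' chance: volumes per scan divided by the number of candidate labels.
#'
#' @param n_volumes Volumes per target scan.
#' @param n_labels Number of candidate labels.
#' @return Numeric.
#' @export
chance_expectation <- function(n_volumes, n_labels) {
  stopifnot(n_labels >= 1)
  n_volumes / n_labels
}

#' Run the full identity-fingerprinting protocol over a cohort
#'
#' For each session in turn designated as the target session, and each
#' size-`database_size` subset of the remaining sessions designated as the
#' database, every subject's target scan is matched volume-by-volume
#' against all database scans of all subjects. Accuracy is reported at the
#' single-volume level (fraction of volumes whose best match belongs to the
#' true subject) and the full-scan level (fraction of target scans whose
#' majority vote is correct).
#'
#' @param series List of trimmed `eigen_series`, one per scan (use
#'   [cohort_eigen_series()]).
#' @param database_size Number of database sessions per target.
#' @param task Which task's scans to fingerprint (default the first task
#'   present, normally "rest").
#' @return Object of class `identification_report`: `scans` (data frame of
#'   scan labels), `records` (one per target x database subset, with
#'   per-volume winner bookkeeping), and summary accuracies.
#' @export
run_identification <- function(series, database_size, task = NULL) {
  stopifnot(length(series) >= 2L,
            all(vapply(series, inherits, logical(1), "eigen_series")))
  tasks_present <- sort(unique(vapply(series, `[[`, character(1), "task")))
  if (is.null(task)) task <- if ("rest" %in% tasks_present) "rest" else tasks_present[1L]
  series <- Filter(function(es) es$task == task, series)
  if (length(series) == 0L) stop("no scans for task ", task)

  subj <- vapply(series, `[[`, character(1), "subject_id")
  sess <- vapply(series, `[[`, character(1), "session_id")
  ord <- order(subj, sess)
  series <- series[ord]; subj <- subj[ord]; sess <- sess[ord]
  sessions <- sort(unique(sess))
  if (length(sessions) < 2L) stop("identity fingerprinting needs at least 2 sessions")
  if (database_size > length(sessions) - 1L) {
    stop("database_size exceeds the number of non-target sessions")
  }

  z <- lapply(series, std_v1)
  cache <- new.env(parent = emptyenv())
  get_pair <- function(i, j) {
    key <- paste0(i, "_", j)
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- pair_best(z[[i]], z[[j]])
      cache[[key]] <- hit
    }
    hit
  }

  records <- list()
  for (target_ses in sessions) {
    candidates <- setdiff(sessions, target_ses)
    subsets <- enumerate_database_subsets(length(candidates), database_size)
    target_idx <- which(sess == target_ses)
    for (ss in subsets) {
      db_sessions <- candidates[ss]
      db_idx <- which(sess %in% db_sessions)  # already (subject, session)-sorted
      for (i in target_idx) {
        simmat <- vapply(db_idx, function(j) get_pair(i, j)$sim,
                         numeric(ncol(z[[i]])))
        if (!is.matrix(simmat)) simmat <- matrix(simmat, nrow = ncol(z[[i]]))
        wcol <- max.col(simmat, ties.method = "first")
        winner_scan <- db_idx[wcol]
        win_sim <- simmat[cbind(seq_along(wcol), wcol)]
        pred <- subj[winner_scan]
        correct <- pred == subj[i]
        predicted <- vote_label(pred, win_sim)
        records[[length(records) + 1L]] <- list(
          target = i, subject = subj[i], session = sess[i],
          db_sessions = db_sessions,
          winner_scan = winner_scan, winner_similarity = win_sim,
          n_volumes = length(wcol), n_correct = sum(correct),
          volume_accuracy = mean(correct),
          predicted_label = predicted, correct = predicted == subj[i])
      }
    }
  }
  new_identification_report(records, subj, sess,
                            vapply(series, `[[`, character(1), "task"),
                            label_kind = "identity",
                            config = list(n_nodes = nrow(series[[1]]$v1),
                                          database_size = database_size,
                                          task = task))
}

new_identification_report <- function(records, subj, sess, task, label_kind,
                                      config) {
  n_corr <- sum(vapply(records, `[[`, numeric(1), "n_correct"))
  n_vol <- sum(vapply(records, `[[`, numeric(1), "n_volumes"))
  scan_ok <- vapply(records, `[[`, logical(1), "correct")
  structure(list(
    scans = data.frame(subject = subj, session = sess, task = task,
                       stringsAsFactors = FALSE),
    records = records,
    label_kind = label_kind,
    volume_accuracy = n_corr / n_vol,
    scan_accuracy = mean(scan_ok),
    n_targets = length(records),
    config = config
  ), class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("<identification_report> %s: %d target evaluations\n",
              x$label_kind, x$n_targets))
  cat(sprintf("  volume-level accuracy: %.1f%%\n", 100 * x$volume_accuracy))
  cat(sprintf("  scan-level accuracy:   %.1f%%\n", 100 * x$scan_accuracy))
  invisible(x)
}

# True per-record label under the report's label kind.
record_truth <- function(report, rec) {
  if (report$label_kind == "identity") rec$subject else rec$task_label
}

#' Permutation null for identification accuracy
#'
#' Randomizes the labels of database scans (labels are permuted across
#' scans as a multiset; every volume keeps its scan's permuted label) and
#' recomputes both accuracy levels from the cached per-volume winners. The
#' p-value is the fraction of permutations whose accuracy is greater than
#' or equal to the observed accuracy; when that count is zero the p-value
#' is reported as "< 1/n_perm" and stored as `1/n_perm`.
#'
#' @param report An `identification_report` from [run_identification()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Object of class `permutation_result` with observed accuracies,
#'   null distributions, and p-values for both levels.
#' @export
permutation_null <- function(report, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(report, "identification_report"), n_perm >= 1)
  labels <- if (report$label_kind == "identity") report$scans$subject else report$scans$task
  n_scan <- nrow(report$scans)
  set.seed(as.integer(seed))
  null_vol <- numeric(n_perm)
  null_scan <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- labels[sample.int(n_scan)]
    n_corr <- 0; n_vol <- 0; scan_ok <- logical(length(report$records))
    for (ri in seq_along(report$records)) {
      rec <- report$records[[ri]]
      truth <- record_truth(report, rec)
      pred <- perm[rec$winner_scan]
      n_corr <- n_corr + sum(pred == truth)
      n_vol <- n_vol + rec$n_volumes
      scan_ok[ri] <- suppressWarnings(vote_label(pred, rec$winner_similarity)) == truth
    }
    null_vol[b] <- n_corr / n_vol
    null_scan[b] <- mean(scan_ok)
  }
  p_from <- function(null, obs) {
    cnt <- sum(null >= obs)
    list(p = if (cnt == 0L) 1 / n_perm else cnt / n_perm,
         label = if (cnt == 0L) sprintf("< %g", 1 / n_perm)
                 else sprintf("%g", cnt / n_perm))
  }
  pv <- p_from(null_vol, report$volume_accuracy)
  ps <- p_from(null_scan, report$scan_accuracy)
  structure(list(
    observed_volume = report$volume_accuracy,
    observed_scan = report$scan_accuracy,
    null_volume = null_vol, null_scan = null_scan,
    p_volume = pv$p, p_volume_label = pv$label,
    p_scan = ps$p, p_scan_label = ps$label,
    n_perm = n_perm
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations\n", x$n_perm))
  cat(sprintf("  volume level: observed %.3f, p %s\n",
              x$observed_volume, x$p_volume_label))
  cat(sprintf("  scan level:   observed %.3f, p %s\n",
              x$observed_scan, x$p_scan_label))
  invisible(x)
}

#' Task identification within or between subjects
#'
#' Predicts the task label of each target scan from a database of scans
#' from other sessions. In `"within"` mode the database holds only the
#' target subject's other sessions (all tasks); in `"between"` mode the
#' target subject is excluded entirely and the database holds other
#' subjects' other sessions. Resting-state series should be truncated to
#' the task-scan length beforehand (see [cohort_eigen_series()]'s
#' `equalize_volumes`).
#'
#' @param series List of trimmed `eigen_series` covering at least 2 tasks.
#' @param mode `"within"` or `"between"`.
#' @return An `identification_report` with `label_kind = "task"` and a
#'   `task_accuracy` element (per-task volume-level accuracy).
#' @export
task_identification <- function(series, mode = c("within", "between")) {
  mode <- match.arg(mode)
  stopifnot(all(vapply(series, inherits, logical(1), "eigen_series")))
  subj <- vapply(series, `[[`, character(1), "subject_id")
  sess <- vapply(series, `[[`, character(1), "session_id")
  task <- vapply(series, `[[`, character(1), "task")
  if (length(unique(task)) < 2L) stop("task identification needs at least 2 tasks")
  nv <- vapply(series, function(es) ncol(es$v1), integer(1))
  if (length(unique(nv)) > 1L) {
    stop("all scans must have equal volume counts; truncate rest scans first")
  }
  ord <- order(subj, sess, task)
  series <- series[ord]; subj <- subj[ord]; sess <- sess[ord]; task <- task[ord]
  z <- lapply(series, std_v1)

  records <- list()
  for (i in seq_along(series)) {
    db_idx <- if (mode == "within") {
      which(subj == subj[i] & sess != sess[i])
    } else {
      which(subj != subj[i] & sess != sess[i])
    }
    if (length(db_idx) == 0L) stop("empty database pool for scan ", i)
    simmat <- vapply(db_idx, function(j) pair_best(z[[i]], z[[j]])$sim,
                     numeric(ncol(z[[i]])))
    if (!is.matrix(simmat)) simmat <- matrix(simmat, nrow = ncol(z[[i]]))
    wcol <- max.col(simmat, ties.method = "first")
    winner_scan <- db_idx[wcol]
    win_sim <- simmat[cbind(seq_along(wcol), wcol)]
    pred <- task[winner_scan]
    correct <- pred == task[i]
    predicted <- vote_label(pred, win_sim)
    records[[length(records) + 1L]] <- list(
      target = i, subject = subj[i], session = sess[i], task_label = task[i],
      db_sessions = unique(sess[db_idx]),
      winner_scan = winner_scan, winner_similarity = win_sim,
      n_volumes = length(wcol), n_correct = sum(correct),
      volume_accuracy = mean(correct),
      predicted_label = predicted, correct = predicted == task[i])
  }
  rep <- new_identification_report(records, subj, sess, task,
                                   label_kind = "task",
                                   config = list(mode = mode,
                                                 n_nodes = nrow(series[[1]]$v1)))
  acc <- vapply(records, `[[`, numeric(1), "volume_accuracy")
  tlab <- vapply(records, `[[`, character(1), "task_label")
  rep$task_accuracy <- tapply(acc, tlab, mean)
  rep
}

#' Subnetwork-stratified node down-sampling
#'
#' Samples nodes from a fine parcellation so that each subnetwork
#' contributes exactly the node count it has in a reference coarse
#' parcellation. Used to separate the effect of node count from node size.
#'
#' @param map A [make_subnetwork_map()] over the fine parcellation.
#' @param reference_counts Integer vector of per-subnetwork node counts to
#'   match (length = number of subnetworks).
#' @param seed Integer seed.
#' @return Sorted integer vector of selected node indices.
#' @export
downsample_nodes <- function(map, reference_counts, seed = 1L) {
  n_sub <- attr(map, "n_subnetworks") %||% max(map)
  stopifnot(length(reference_counts) == n_sub,
            all(reference_counts >= 0))
  sizes <- tabulate(map, nbins = n_sub)
  if (any(reference_counts > sizes)) {
    stop("a subnetwork has fewer nodes than its reference count")
  }
  set.seed(as.integer(seed))
  sel <- unlist(lapply(seq_len(n_sub), function(k) {
    pool <- which(map == k)
    if (reference_counts[k] == 0L) return(integer(0))
    if (reference_counts[k] == length(pool)) return(pool)
    sample(pool, reference_counts[k])
  }))
  sort(sel)
}

#' Split volume-level accuracy by motion flag
#'
#' Recomputes per-volume correctness from the report's winner bookkeeping
#' and aggregates separately over high-motion (flagged) and retained
#' volumes. Flags must be trimmed to the same volume indexing as the
#' eigenvector series (apply [trim_edge_artifact()] to the flags).
#'
#' @param report An `identification_report`.
#' @param flags_per_scan List of logical flag vectors, indexed like the
#'   rows of `report$scans`, each of length equal to that scan's trimmed
#'   volume count.
#' @return List with `accuracy_flagged` (NA if no volume was flagged),
#'   `accuracy_unflagged`, `n_flagged`, `n_unflagged`.
#' @export
split_by_motion <- function(report, flags_per_scan) {
  stopifnot(inherits(report, "identification_report"),
            length(flags_per_scan) == nrow(report$scans))
  labels <- if (report$label_kind == "identity") report$scans$subject else report$scans$task
  corr_f <- 0; n_f <- 0; corr_u <- 0; n_u <- 0
  for (rec in report$records) {
    f <- as.logical(flags_per_scan[[rec$target]])
    if (length(f) != rec$n_volumes) {
      stop("flag vector length does not match trimmed volume count")
    }
    truth <- record_truth(report, rec)
    correct <- labels[rec$winner_scan] == truth
    corr_f <- corr_f + sum(correct[f]);  n_f <- n_f + sum(f)
    corr_u <- corr_u + sum(correct[!f]); n_u <- n_u + sum(!f)
  }
  list(accuracy_flagged = if (n_f > 0) corr_f / n_f else NA_real_,
       accuracy_unflagged = if (n_u > 0) corr_u / n_u else NA_real_,
       n_flagged = n_f, n_unflagged = n_u)
}

#' Static-network fingerprinting baseline
#'
#' Classical whole-scan fingerprinting: each target scan's static network
#' (vectorized upper triangle) is correlated with every database scan's
#' network, and the owner of the most correlated database network is
#' predicted. Only scan-level accuracy is defined.
#'
#' @param networks List of N x N static networks (see [static_network()]).
#' @param subjects,sessions Character vectors labeling each network.
#' @param database_size Database sessions per target.
#' @return List with `scan_accuracy`, `n_targets`, and per-target records.
#' @export
static_fingerprint <- function(networks, subjects, sessions, database_size) {
  stopifnot(length(networks) == length(subjects),
            length(networks) == length(sessions))
  dims <- vapply(networks, nrow, integer(1))
  if (length(unique(dims)) != 1L) stop("all networks must have the same node count")
  ord <- order(subjects, sessions)
  networks <- networks[ord]; subjects <- subjects[ord]; sessions <- sessions[ord]
  vecs <- vapply(networks, upper_tri_values, numeric(choose(dims[1L], 2)))
  vz <- standardize_columns(vecs, "static network vectors")
  sess_u <- sort(unique(sessions))
  if (database_size > length(sess_u) - 1L) stop("database_size too large")
  records <- list()
  for (target_ses in sess_u) {
    candidates <- setdiff(sess_u, target_ses)
    subsets <- enumerate_database_subsets(length(candidates), database_size)
    for (ss in subsets) {
      db_idx <- which(sessions %in% candidates[ss])
      for (i in which(sessions == target_ses)) {
        r <- crossprod(vz[, i, drop = FALSE], vz[, db_idx, drop = FALSE])[1L, ]
        best <- which.max(r)
        records[[length(records) + 1L]] <- list(
          subject = subjects[i], session = sessions[i],
          predicted_label = subjects[db_idx[best]],
          best_r = r[best],
          correct = subjects[db_idx[best]] == subjects[i])
      }
    }
  }
  list(scan_accuracy = mean(vapply(records, `[[`, logical(1), "correct")),
       n_targets = length(records), records = records)
}

#' Percentile bootstrap CI for volume-level accuracy
#'
#' Resamples target-scan records with replacement and recomputes the pooled
#' volume-level accuracy.
#'
#' @param report An `identification_report`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return Named numeric vector `c(lower, estimate, upper)`.
#' @export
bootstrap_accuracy_ci <- function(report, n_boot = 2000, level = 0.95,
                                  seed = 1L) {
  stopifnot(inherits(report, "identification_report"))
  nc <- vapply(report$records, `[[`, numeric(1), "n_correct")
  nv <- vapply(report$records, `[[`, numeric(1), "n_volumes")
  set.seed(as.integer(seed))
  stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(nc), replace = TRUE)
    stat[b] <- sum(nc[idx]) / sum(nv[idx])
  }
  qs <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  c(lower = qs[1L], estimate = sum(nc) / sum(nv), upper = qs[2L])
}
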