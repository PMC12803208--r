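# Orchestration of the experiment matrix: cohort -> preprocessing ->
# eigenvector series -> identification, over node-count and database-size
# grids, with permutation nulls, tSNR summaries and motion splits.

#' Cohort to trimmed eigenvector series
#'
#' Runs every scan of a cohort through preprocessing ([process_scan()]) and
#' the phase pipeline ([eigen_series_from_scan()]). With
#' `equalize_volumes = TRUE`, resting-state scans are first truncated to
#' the shortest task-scan length so every label has equally many volumes
#' (required for task identification). Motion flags are trimmed to match
#' the series indexing and returned alongside.
#'
#' @param cohort List of [scan_record()]s.
#' @param config A [preproc_config()].
#' @param trim Edge-artifact trim length (volumes per end).
#' @param equalize_volumes Truncate all scans to the cohort's shortest scan
#'   length before processing.
#' @return List with `series` (trimmed `eigen_series` per scan) and
#'   `flags` (trimmed logical vectors per scan).
#' @export
cohort_eigen_series <- function(cohort, config = preproc_config(), trim = 5L,
                                equalize_volumes = FALSE) {
  stopifnot(all(vapply(cohort, inherits, logical(1), "scan_record")))
  if (equalize_volumes) {
    min_t <- min(vapply(cohort, n_volumes, integer(1)))
    cohort <- lapply(cohort, truncate_scan, n = min_t)
  }
  series <- vector("list", length(cohort))
  flags <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    proc <- process_scan(cohort[[i]], config)
    series[[i]] <- eigen_series_from_scan(proc, trim = trim)
    flags[[i]] <- trim_edge_artifact(as.logical(proc$motion_flags), k = trim)
  }
  list(series = series, flags = flags)
}

#' Experiment configuration
#'
#' @param cohort A [cohort_config()] (or [cohort_preset()]) defining the
#'   simulated study; its `n_nodes` is overridden per grid cell.
#' @param node_counts Integer vector of parcellation sizes to sweep.
#' @param database_sizes Integer vector of database-session counts.
#' @param n_perm Permutations per cell (0 disables the null).
#' @param trim Edge-artifact trim length.
#' @param prep A [preproc_config()]; its drop defaults to the cohort's.
#' @param seed Master seed for per-cell derived seeds.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(cohort, node_counts = cohort$n_nodes,
                              database_sizes = cohort$n_sessions - 1L,
                              n_perm = 0L, trim = 5L, prep = NULL,
                              seed = cohort$seed) {
  stopifnot(inherits(cohort, "cohort_config"),
            all(node_counts >= 2), all(database_sizes >= 1),
            all(database_sizes <= cohort$n_sessions - 1L), n_perm >= 0)
  if (is.null(prep)) {
    prep <- preproc_config(steady_state_drop = cohort$steady_state_drop,
                           band_low_hz = cohort$band_low_hz,
                           band_high_hz = cohort$band_high_hz)
  }
  structure(list(cohort = cohort, node_counts = as.integer(node_counts),
                 database_sizes = as.integer(database_sizes),
                 n_perm = as.integer(n_perm), trim = as.integer(trim),
                 prep = prep, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the experiment grid
#'
#' For each (node count, database size) cell: simulate the cohort at that
#' parcellation size, preprocess, compute eigenvector series, run the
#' identification protocol, and (optionally) the permutation null. Chance
#' expectations, the tSNR summary, and - when motion spikes are enabled -
#' the motion-split accuracies are attached per cell. A failing cell is
#' recorded with its error message and the run continues.
#'
#' @param config An [experiment_config()].
#' @param out Optional directory; if given, the report is written as JSON.
#' @return Object of class `experiment_report`: list of cells, each with
#'   its identification report and summaries.
#' @export
run_experiment <- function(config, out = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- expand.grid(n_nodes = config$node_counts,
                      database_size = config$database_sizes)
  cells <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    nn <- grid$n_nodes[g]
    k <- grid$database_size[g]
    cells[[g]] <- tryCatch({
      ccfg <- config$cohort
      ccfg$n_nodes <- as.integer(nn)
      # same latent seed across node counts: every grid cell observes the
      # same underlying cohort at a different parcellation granularity
      ccfg$seed <- mix_seed(config$seed, "cohort")
      cohort <- generate_cohort(ccfg)
      pipe <- cohort_eigen_series(cohort, config$prep, trim = config$trim)
      report <- run_identification(pipe$series, database_size = k)
      n_vol <- report$records[[1L]]$n_volumes
      perm <- if (config$n_perm > 0L) {
        permutation_null(report, n_perm = config$n_perm,
                         seed = mix_seed(config$seed, "perm", nn, k))
      }
      rest_idx <- which(vapply(cohort, `[[`, character(1), "task") == "rest")
      tsnr <- vapply(cohort[rest_idx],
                     function(s) mean(compute_tsnr(s), na.rm = TRUE),
                     numeric(1))
      motion <- if (ccfg$motion_spike_rate > 0) {
        lab_pipe <- vapply(pipe$series, function(es) {
          paste(es$subject_id, es$session_id, es$task, sep = "|")
        }, character(1))
        lab_rep <- paste(report$scans$subject, report$scans$session,
                         report$scans$task, sep = "|")
        split_by_motion(report, pipe$flags[match(lab_rep, lab_pipe)])
      }
      list(n_nodes = nn, database_size = k, status = "ok",
           volume_accuracy = report$volume_accuracy,
           scan_accuracy = report$scan_accuracy,
           chance_volume_accuracy = 1 / ccfg$n_subjects,
           chance_expected_volumes = chance_expectation(n_vol, ccfg$n_subjects),
           n_volumes_per_scan = n_vol,
           permutation = if (!is.null(perm)) {
             list(p_volume = perm$p_volume, p_volume_label = perm$p_volume_label,
                  p_scan = perm$p_scan, p_scan_label = perm$p_scan_label)
           },
           tsnr_mean = mean(tsnr), tsnr_sd = stats::sd(tsnr),
           motion_split = motion,
           report = report)
    }, error = function(e) {
      list(n_nodes = nn, database_size = k, status = "failed",
           error = conditionMessage(e))
    })
  }
  rep <- structure(list(cells = cells, config = list(
    node_counts = config$node_counts, database_sizes = config$database_sizes,
    n_perm = config$n_perm, trim = config$trim, seed = config$seed,
    n_subjects = config$cohort$n_subjects,
    n_sessions = config$cohort$n_sessions
  )), class = "experiment_report")
  if (!is.null(out)) write_experiment_report(rep, out)
  rep
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  %-8s %-8s %-8s %-10s %-10s\n",
              "nodes", "dbsize", "status", "vol.acc", "scan.acc"))
  for (cell in x$cells) {
    if (cell$status == "ok") {
      cat(sprintf("  %-8d %-8d %-8s %-10.3f %-10.3f\n", cell$n_nodes,
                  cell$database_size, cell$status,
                  cell$volume_accuracy, cell$scan_accuracy))
    } else {
      cat(sprintf("  %-8d %-8d %-8s %s\n", cell$n_nodes,
                  cell$database_size, cell$status, cell$error))
    }
  }
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' Per-cell summaries (accuracies, chance lines, permutation p-values, tSNR
#' and motion splits) are serialized; the full per-record bookkeeping is
#' omitted from the JSON payload.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slim <- unclass(report)
  slim$cells <- lapply(report$cells, function(cell) {
    cell$report <- NULL
    cell
  })
  path <- file.path(dir, "experiment_report.json")
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Down-sampled-parcellation experiment
#'
#' Generates a cohort at a fine parcellation (`n_nodes_large`), and for
#' each iteration samples `sum(reference counts)` nodes stratified by
#' subnetwork so the per-subnetwork counts match a coarse parcellation of
#' `n_nodes_small` nodes, then reruns the full identification on the node
#' subset. Anchors the result with the full coarse- and fine-parcellation
#' accuracies from cohorts at those sizes.
#'
#' @param cohort A [cohort_config()] (its `n_nodes` is overridden).
#' @param n_nodes_small,n_nodes_large Coarse and fine parcellation sizes.
#' @param n_subnetworks Number of subnetworks (default 17).
#' @param iterations Number of random down-samplings (study protocol: 100;
#'   smaller values for quick runs).
#' @param database_size Database sessions per target.
#' @param trim,prep As in [experiment_config()].
#' @param seed Master seed.
#' @return List with per-iteration accuracies, their mean and sd, and the
#'   small/large anchor accuracies.
#' @export
run_downsample_experiment <- function(cohort, n_nodes_small = 100,
                                      n_nodes_large = 1000,
                                      n_subnetworks = 17, iterations = 100,
                                      database_size = cohort$n_sessions - 1L,
                                      trim = 5L, prep = NULL,
                                      seed = cohort$seed) {
  stopifnot(inherits(cohort, "cohort_config"),
            n_nodes_small < n_nodes_large, iterations >= 1)
  if (is.null(prep)) {
    prep <- preproc_config(steady_state_drop = cohort$steady_state_drop,
                           band_low_hz = cohort$band_low_hz,
                           band_high_hz = cohort$band_high_hz)
  }
  run_at <- function(nn) {
    ccfg <- cohort
    ccfg$n_nodes <- as.integer(nn)
    ccfg$seed <- mix_seed(seed, "cohort")  # same latent cohort at both sizes
    generate_cohort(ccfg)
  }
  acc_of <- function(scans) {
    pipe <- cohort_eigen_series(scans, prep, trim = trim)
    run_identification(pipe$series, database_size = database_size)$volume_accuracy
  }
  small_acc <- acc_of(run_at(n_nodes_small))
  large_cohort <- run_at(n_nodes_large)
  large_acc <- acc_of(large_cohort)
  map_large <- make_subnetwork_map(n_nodes_large, n_subnetworks,
                                   seed = mix_seed(seed, "map", n_nodes_large))
  map_small <- make_subnetwork_map(n_nodes_small, n_subnetworks,
                                   seed = mix_seed(seed, "map", n_nodes_small))
  ref_counts <- tabulate(map_small, nbins = n_subnetworks)
  iter_acc <- numeric(iterations)
  for (it in seq_len(iterations)) {
    nodes <- downsample_nodes(map_large, ref_counts,
                              seed = mix_seed(seed, "ds", it))
    iter_acc[it] <- acc_of(lapply(large_cohort, subset_nodes, nodes = nodes))
  }
  list(iteration_accuracy = iter_acc,
       mean_accuracy = mean(iter_acc),
       sd_accuracy = stats::sd(iter_acc),
       small_accuracy = small_acc,
       large_accuracy = large_acc,
       n_nodes_small = n_nodes_small, n_nodes_large = n_nodes_large,
       iterations = iterations)
}

#' Compare temporal SNR between two parcellation granularities
#'
#' Computes each scan's mean nodal tSNR in both cohorts (paired by subject,
#' session and task) and summarizes the per-condition means and the paired
#' difference, with a paired t-test.
#'
#' @param cohort_a,cohort_b Lists of [scan_record()]s covering the same
#'   (subject, session, task) combinations at different node counts.
#' @return List with per-condition mean/sd, mean paired difference, and the
#'   paired t-test p-value.
#' @export
report_tsnr_comparison <- function(cohort_a, cohort_b) {
  key <- function(s) paste(s$subject_id, s$session_id, s$task, sep = "|")
  ka <- vapply(cohort_a, key, character(1))
  kb <- vapply(cohort_b, key, character(1))
  if (!setequal(ka, kb)) stop("cohorts do not cover the same scans")
  cohort_b <- cohort_b[match(ka, kb)]
  ma <- vapply(cohort_a, function(s) mean(compute_tsnr(s), na.rm = TRUE), numeric(1))
  mb <- vapply(cohort_b, function(s) mean(compute_tsnr(s), na.rm = TRUE), numeric(1))
  diff <- ma - mb
  pt <- if (stats::sd(diff) > 0) stats::t.test(ma, mb, paired = TRUE)$p.value else NA_real_
  list(mean_a = mean(ma), sd_a = stats::sd(ma),
       mean_b = mean(mb), sd_b = stats::sd(mb),
       mean_paired_difference = mean(diff),
       p_paired = pt, n_scans = length(ma))
}
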