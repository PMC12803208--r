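test_that("eigenvector similarity is absolute correlation with its symmetries", {
  set.seed(61)
  a <- rnorm(20)
  expect_equal(similarity(a, a), 1)
  expect_equal(similarity(a, -a), 1)
  b <- rnorm(20)
  expect_equal(similarity(a, b), similarity(b, a))
  expect_equal(similarity(-a, b), similarity(a, b))

  # 4-entry toy against the direct formula
  u <- c(1, 2, 4, 3); v <- c(2, 1, 5, 2)
  uc <- u - mean(u); vc <- v - mean(v)
  expect_equal(similarity(u, v),
               abs(sum(uc * vc) / sqrt(sum(uc^2) * sum(vc^2))),
               tolerance = 1e-12)
  expect_error(similarity(a, rep(1, 20)), "constant")
})

test_that("volume matching picks the most correlated database volume", {
  set.seed(62)
  target <- rnorm(30)
  strong <- vector_with_correlation(target, 0.9, seed = 1)
  weak <- vector_with_correlation(target, 0.3, seed = 2)
  pool <- database_pool(list(
    manual_eigen_series(matrix(strong, ncol = 1), subject = "sub-01"),
    manual_eigen_series(matrix(weak, ncol = 1), subject = "sub-02")
  ))
  m <- match_volume(target, pool)
  expect_equal(m$predicted_label, "sub-01")
  expect_equal(m$similarity, 0.9, tolerance = 1e-8)

  # exact copy wins with similarity 1
  pool2 <- database_pool(list(
    manual_eigen_series(matrix(weak, ncol = 1), subject = "sub-01"),
    manual_eigen_series(matrix(target, ncol = 1), subject = "sub-02")
  ))
  m2 <- match_volume(target, pool2)
  expect_equal(m2$predicted_label, "sub-02")
  expect_equal(m2$similarity, 1, tolerance = 1e-12)

  # exact tie: deterministic lexicographic winner, with a warning
  pool3 <- database_pool(list(
    manual_eigen_series(matrix(target, ncol = 1), subject = "sub-02"),
    manual_eigen_series(matrix(target, ncol = 1), subject = "sub-01")
  ))
  expect_warning(m3 <- match_volume(target, pool3), "tie")
  expect_equal(m3$predicted_label, "sub-01")
})

test_that("scan identification aggregates volume votes with majority rule", {
  set.seed(63)
  t1 <- rnorm(30); t2 <- rnorm(30); t3 <- rnorm(30)
  target <- manual_eigen_series(cbind(t1, t2, t3), subject = "sub-09",
                                session = "ses-09")
  pool <- database_pool(list(
    manual_eigen_series(cbind(t1, t2), subject = "sub-01", session = "ses-01"),
    manual_eigen_series(matrix(t3, ncol = 1), subject = "sub-02", session = "ses-01")
  ))
  pred <- identify_scan(target, pool, true_label = "sub-01")
  expect_equal(unname(pred$per_volume_label), c("sub-01", "sub-01", "sub-02"))
  expect_equal(pred$predicted_label, "sub-01")
  expect_true(pred$correct)
  expect_equal(pred$n_correct_volumes, 2L)
  expect_equal(pred$volume_accuracy, 2 / 3)

  # self-consistency: target present in its own database -> all volumes match
  pool_self <- database_pool(list(target,
    manual_eigen_series(matrix(rnorm(30), ncol = 1), subject = "sub-02")))
  self <- identify_scan(target, pool_self)
  expect_equal(self$volume_accuracy, 1)
  expect_true(all(self$winner_similarity > 1 - 1e-10))
})

test_that("database subset enumeration is exhaustive and ordered", {
  expect_length(enumerate_database_subsets(9, 5), 126)
  expect_length(enumerate_database_subsets(5, 3), 10)
  expect_length(enumerate_database_subsets(4, 4), 1)
  expect_identical(enumerate_database_subsets(3, 2),
                   list(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_error(enumerate_database_subsets(3, 4))
  expect_error(enumerate_database_subsets(3, 0))
})

test_that("the identification protocol enumerates targets and databases correctly", {
  cfg <- small_identity_config(seed = 64, n_subjects = 3, n_sessions = 3,
                               n_nodes = 30, n_volumes = 80)
  pipe <- quiet_pipeline(generate_cohort(cfg))
  full <- quiet_identify(pipe$series, database_size = 2)
  expect_equal(full$n_targets, 3L * 3L)  # sessions x subjects, one subset
  single <- quiet_identify(pipe$series, database_size = 1)
  expect_equal(single$n_targets, 3L * 2L * 3L)  # sessions x subsets x subjects
  expect_true(all(vapply(full$records, function(r) r$n_volumes, numeric(1)) ==
                    80 - 5 - 10))
  expect_error(quiet_identify(pipe$series, database_size = 3), "exceeds")
})

test_that("duplicated subjects make identification exactly exchangeable", {
  # subject B's scans are exact copies of subject A's: every match is a tie
  # resolved lexicographically, so volume accuracy is exactly chance (1/2)
  cfg <- small_identity_config(seed = 65, n_subjects = 1, n_sessions = 2,
                               n_nodes = 30, n_volumes = 80)
  pipe <- quiet_pipeline(generate_cohort(cfg))
  copy <- lapply(pipe$series, function(es) { es$subject_id <- "sub-99"; es })
  rep2 <- quiet_identify(c(pipe$series, copy), database_size = 1)
  expect_equal(rep2$volume_accuracy, 0.5, tolerance = 1e-12)
})

test_that("consistent relabeling of subjects leaves accuracies unchanged", {
  cfg <- small_identity_config(seed = 66, n_subjects = 3, n_sessions = 3,
                               n_nodes = 30, n_volumes = 80)
  pipe <- quiet_pipeline(generate_cohort(cfg))
  base <- quiet_identify(pipe$series, database_size = 2)
  relabel <- c("sub-01" = "zeta", "sub-02" = "alpha", "sub-03" = "mid")
  renamed <- lapply(pipe$series, function(es) {
    es$subject_id <- unname(relabel[es$subject_id]); es
  })
  swapped <- quiet_identify(renamed, database_size = 2)
  expect_equal(swapped$volume_accuracy, base$volume_accuracy)
  expect_equal(swapped$scan_accuracy, base$scan_accuracy)
})

test_that("permutation null is degenerate when all labels agree", {
  cfg <- small_identity_config(seed = 67, n_subjects = 1, n_sessions = 3,
                               n_nodes = 30, n_volumes = 80)
  pipe <- quiet_pipeline(generate_cohort(cfg))
  rep1 <- quiet_identify(pipe$series, database_size = 2)
  pn <- permutation_null(rep1, n_perm = 10, seed = 5)
  expect_true(all(pn$null_volume == rep1$volume_accuracy))
  expect_equal(pn$p_volume, 1)
})

test_that("permutation p-values are not inflated under the null", {
  ps <- vapply(1:6, function(i) {
    cfg <- small_identity_config(seed = 400 + i, n_subjects = 3,
                                 n_sessions = 2, n_nodes = 30,
                                 n_volumes = 60, subject_weight = 0,
                                 session_noise_weight = 1)
    pipe <- quiet_pipeline(generate_cohort(cfg))
    r0 <- quiet_identify(pipe$series, database_size = 1)
    suppressWarnings(permutation_null(r0, n_perm = 40, seed = 500 + i)$p_volume)
  }, numeric(1))
  expect_lte(sum(ps <= 0.05), 2L)
  expect_gt(mean(ps), 0.15)
})

test_that("stratified node down-sampling matches reference counts exactly", {
  map <- make_subnetwork_map(1000, 17, seed = 71)
  ref <- tabulate(make_subnetwork_map(100, 17, seed = 72), 17)
  sel <- downsample_nodes(map, ref, seed = 73)
  expect_length(sel, 100L)
  expect_equal(tabulate(map[sel], 17), ref)
  expect_identical(sel, downsample_nodes(map, ref, seed = 73))

  # counts all zero except one subnetwork taken whole
  ref2 <- integer(17); ref2[4] <- sum(map == 4)
  expect_identical(downsample_nodes(map, ref2, seed = 74), which(map == 4))
  ref3 <- integer(17); ref3[1] <- sum(map == 1) + 1L
  expect_error(downsample_nodes(map, ref3), "fewer")
})

test_that("motion splits partition volume-level accuracy", {
  cfg <- small_identity_config(seed = 75, n_subjects = 3, n_sessions = 2,
                               n_nodes = 30, n_volumes = 80)
  pipe <- quiet_pipeline(generate_cohort(cfg))
  rep1 <- quiet_identify(pipe$series, database_size = 1)
  t_len <- rep1$records[[1]]$n_volumes

  none <- lapply(seq_len(nrow(rep1$scans)), function(i) rep(FALSE, t_len))
  s0 <- split_by_motion(rep1, none)
  expect_true(is.na(s0$accuracy_flagged))
  expect_equal(s0$accuracy_unflagged, rep1$volume_accuracy)

  all_f <- lapply(seq_len(nrow(rep1$scans)), function(i) rep(TRUE, t_len))
  s1 <- split_by_motion(rep1, all_f)
  expect_equal(s1$accuracy_flagged, rep1$volume_accuracy)
  expect_true(is.na(s1$accuracy_unflagged))

  short <- lapply(seq_len(nrow(rep1$scans)), function(i) rep(FALSE, t_len - 1))
  expect_error(split_by_motion(rep1, short), "length")
})

test_that("static fingerprinting identifies block-distinct subjects", {
  blockify <- function(hot) {
    m <- diag(10)
    m[1:5, 1:5] <- 0.2; m[6:10, 6:10] <- 0.2
    if (hot == 1) m[1:5, 1:5] <- 0.9 else m[6:10, 6:10] <- 0.9
    diag(m) <- 1
    m + matrix(rnorm(100, sd = 0.01), 10)
  }
  set.seed(76)
  nets <- list(blockify(1), blockify(1), blockify(2), blockify(2))
  subs <- c("a", "a", "b", "b")
  sess <- c("s1", "s2", "s1", "s2")
  res <- static_fingerprint(nets, subs, sess, database_size = 1)
  expect_equal(res$scan_accuracy, 1)
  expect_equal(res$n_targets, 4L)

  # duplicate network in the database is matched with r = 1
  nets2 <- nets; nets2[[2]] <- nets[[1]]
  res2 <- static_fingerprint(nets2, subs, sess, database_size = 1)
  rec <- res2$records[[which(vapply(res2$records, function(r)
    r$session == "s1" && r$subject == "a", logical(1)))[1]]]
  expect_equal(rec$best_r, 1, tolerance = 1e-12)
})

test_that("bootstrap confidence intervals bracket the point estimate", {
  cfg <- small_identity_config(seed = 77, n_subjects = 3, n_sessions = 2,
                               n_nodes = 30, n_volumes = 80)
  pipe <- quiet_pipeline(generate_cohort(cfg))
  rep1 <- quiet_identify(pipe$series, database_size = 1)
  ci <- bootstrap_accuracy_ci(rep1, n_boot = 200, seed = 3)
  expect_lte(ci["lower"], ci["estimate"])
  expect_gte(ci["upper"], ci["estimate"])
  expect_equal(unname(ci["estimate"]), rep1$volume_accuracy)
})
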