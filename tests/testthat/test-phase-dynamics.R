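wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi

test_that("Hilbert phases of sampled sinusoids match the closed form", {
  f <- 0.05; tr <- 2.2; t_len <- 400
  sc <- sinusoid_scan(f, tr = tr, n_volumes = t_len)
  th <- hilbert_phase(sc)$theta[1, ]
  d <- wrap_pi(diff(th))
  core <- 20:(t_len - 20)
  expect_lt(max(abs(d[core] - 2 * pi * f * tr)), 1e-3)

  # identical nodes have identical phases
  two <- scan_record("s", "e", "rest", rbind(sc$data[1, ], sc$data[1, ]), tr)
  th2 <- hilbert_phase(two)$theta
  expect_equal(th2[1, ], th2[2, ])

  # quadrature pair: constant pi/2 offset mid-series
  tt <- (seq_len(t_len) - 1) * tr
  q <- scan_record("s", "e", "rest",
                   rbind(cos(2 * pi * f * tt), sin(2 * pi * f * tt)), tr)
  thq <- hilbert_phase(q)$theta
  off <- wrap_pi(thq[1, ] - thq[2, ])
  expect_lt(max(abs(off[150:250] - pi / 2)), 1e-2)

  const <- scan_record("s", "e", "rest", rbind(sc$data[1, ], rep(3, t_len)), tr)
  expect_error(hilbert_phase(const), "node 2")
})

test_that("edge trimming removes k volumes at each end", {
  mk_phase <- function(t_len) {
    structure(list(theta = matrix(runif(4 * t_len, -pi, pi), 4),
                   tr_seconds = 2.2, subject_id = "s", session_id = "e",
                   task = "rest"), class = "phase_series")
  }
  expect_equal(ncol(trim_edge_artifact(mk_phase(813))$theta), 803L)
  expect_equal(ncol(trim_edge_artifact(mk_phase(116))$theta), 106L)
  expect_equal(ncol(trim_edge_artifact(mk_phase(269))$theta), 259L)
  expect_error(trim_edge_artifact(mk_phase(10)), "too short")
  # flags trim consistently with series
  expect_length(trim_edge_artifact(rep(TRUE, 813)), 803L)
})

test_that("phase-coherence volumes satisfy the rank-2 trigonometric identity", {
  expect_equal(phase_coherence_volume(c(1.2, 1.2))[1, 2], 1)
  expect_equal(phase_coherence_volume(c(0, pi / 2))[1, 2], 0)

  set.seed(51)
  for (rep in 1:20) {
    th <- runif(30, -pi, pi)
    v <- phase_coherence_volume(th)
    oracle <- tcrossprod(cos(th)) + tcrossprod(sin(th))
    expect_lt(max(abs(v - oracle)), 1e-12)
    expect_equal(v, t(v))
    expect_equal(diag(v), rep(1, 30))
    ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * 30)          # PSD
    expect_lt(ev[3], 1e-8 * 30)              # rank <= 2
    expect_equal(sum(ev), 30, tolerance = 1e-8 * 30)  # trace identity
  }
})

test_that("leading eigenpairs match closed-form and dense solves", {
  # fully synchronized phases: rank-1, uniform eigenvector
  v <- phase_coherence_volume(rep(0.7, 10))
  lp <- leading_eigenvector(v)
  expect_equal(lp$lambda1, 10, tolerance = 1e-10)
  expect_equal(lp$variance_fraction, 1, tolerance = 1e-10)
  expect_equal(lp$v1, rep(1 / sqrt(10), 10), tolerance = 1e-10)

  # N=3 instance against the closed-form 2x2 reduction
  th <- c(0, pi / 2, pi)
  a <- sum(cos(th)^2); b <- sum(cos(th) * sin(th)); d <- sum(sin(th)^2)
  lam_closed <- (a + d + sqrt((a - d)^2 + 4 * b^2)) / 2
  expect_equal(leading_eigenvector(phase_coherence_volume(th))$lambda1,
               lam_closed, tolerance = 1e-10)

  # fast rank-2 series path vs dense eigendecomposition, N <= 10
  set.seed(52)
  th_mat <- matrix(runif(8 * 25, -pi, pi), 8)
  ps <- structure(list(theta = th_mat, tr_seconds = 2.2, subject_id = "s",
                       session_id = "e", task = "rest"),
                  class = "phase_series")
  es <- leading_eigen_series(ps)
  for (t in seq_len(25)) {
    dense <- leading_eigenvector(phase_coherence_volume(th_mat[, t]))
    expect_equal(es$lambda1[t], dense$lambda1, tolerance = 1e-10)
    expect_equal(es$v1[, t], dense$v1, tolerance = 1e-8)
    expect_equal(sum(es$v1[, t]^2), 1, tolerance = 1e-12)
  }
  expect_true(all(es$variance_fraction >= 0.5))
})

test_that("rank-1 reconstruction obeys the low-rank approximation bound", {
  # exact for synchronized phases
  vol <- phase_coherence_volume(rep(0.3, 6))
  lp <- leading_eigenvector(vol)
  expect_equal(reconstruct_outer(lp$v1, lp$lambda1), vol, tolerance = 1e-10)

  # generic volume: Frobenius error equals the second eigenvalue
  set.seed(53)
  th <- runif(12, -pi, pi)
  vol <- phase_coherence_volume(th)
  ev <- eigen(vol, symmetric = TRUE)
  approx <- reconstruct_outer(ev$vectors[, 1], ev$values[1])
  err <- sqrt(sum((vol - approx)^2))
  expect_lte(err, ev$values[2] + 1e-8)

  # sign flip leaves the outer product unchanged
  expect_equal(reconstruct_outer(-ev$vectors[, 1]),
               reconstruct_outer(ev$vectors[, 1]))
})

test_that("time collapse sums outer products", {
  set.seed(54)
  th <- matrix(runif(6 * 4, -pi, pi), 6)
  ps <- structure(list(theta = th, tr_seconds = 2.2, subject_id = "s",
                       session_id = "e", task = "rest"),
                  class = "phase_series")
  es <- leading_eigen_series(ps)

  one <- es; one$v1 <- es$v1[, 1, drop = FALSE]
  one$lambda1 <- es$lambda1[1]; one$variance_fraction <- es$variance_fraction[1]
  expect_equal(collapse_time(one),
               reconstruct_outer(es$v1[, 1], es$lambda1[1]), tolerance = 1e-12)

  mats <- lapply(1:4, function(t) reconstruct_outer(es$v1[, t], es$lambda1[t]))
  expect_equal(collapse_time(es), Reduce(`+`, mats), tolerance = 1e-10)
  expect_equal(collapse_time(list(mats[[1]], mats[[1]])), 2 * mats[[1]])
  expect_error(collapse_time(list()), "empty")

  raw <- lapply(1:4, function(t) reconstruct_outer(es$v1[, t]))
  expect_equal(collapse_time(es, weighted = FALSE), Reduce(`+`, raw),
               tolerance = 1e-10)
})

test_that("static networks are Pearson correlation matrices", {
  set.seed(55)
  base <- rnorm(6)
  x <- rbind(base, base, -base, rnorm(6))
  sc <- scan_record("s", "e", "rest", x, 2.2)
  sn <- static_network(sc)
  expect_equal(unname(sn[1, 2]), 1)
  expect_equal(unname(sn[1, 3]), -1)
  expect_equal(unname(diag(sn)), rep(1, 4))

  # 4-node 6-volume toy against the direct formula
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    xi <- x[i, ] - mean(x[i, ]); xj <- x[j, ] - mean(x[j, ])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(unname(sn), oracle, tolerance = 1e-12)

  bad <- scan_record("s", "e", "rest", rbind(rnorm(6), rep(1, 6)), 2.2)
  expect_error(static_network(bad), "node 2")
})
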