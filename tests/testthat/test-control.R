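test_that("state vectors are signed row sums", {
  W <- matrix(0.5, 3, 3); diag(W) <- 0
  expect_equal(state_vector(W), rep(1, 3))
  expect_equal(state_vector(matrix(0, 4, 4)), rep(0, 4))
  set.seed(1)
  R <- random_signed_fc(6)
  expect_equal(state_vector(R), rowSums(R))
})

test_that("stabilization shifts the spectrum below zero exactly", {
  set.seed(2)
  A0 <- matrix(runif(100), 10, 10); A0 <- (A0 + t(A0)) / 2; diag(A0) <- 0
  lmax <- max(eigen(A0, symmetric = TRUE, only.values = TRUE)$values)
  As <- stabilize(A0)
  ev <- eigen(As, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(max(ev), -1 / (1 + lmax), tolerance = 1e-10)
  expect_lt(max(ev), 0)
  # eigenvalues are the affine map of the originals
  ev0 <- eigen(A0, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), sort(ev0 / (1 + lmax) - 1), tolerance = 1e-10)
  expect_equal(stabilize(matrix(0, 3, 3)), -diag(3))
  expect_error(stabilize(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(stabilize(-diag(0.5, 3) + 0.5 - diag(0.5, 3)), "nonnegative")
})

test_that("zero endpoints cost zero energy and the trajectory stays at rest", {
  set.seed(3)
  pr <- random_control_problem(4)
  p0 <- control_problem(pr$A, rep(0, 4), rep(0, 4), n_steps = 101)
  r <- minimum_control_energy(p0)
  expect_equal(r$total_energy, 0, tolerance = 1e-20)
  expect_equal(max(abs(r$x_traj)), 0, tolerance = 1e-12)
  expect_equal(max(abs(r$u_traj)), 0, tolerance = 1e-12)
})

test_that("persistence energy obeys the hold-at-target feasibility bound", {
  set.seed(4)
  for (i in 1:10) {
    pr <- random_control_problem(5)
    rho <- sample(c(0.5, 1, 2), 1)
    p <- control_problem(pr$A, pr$xT, pr$xT, rho = rho, n_steps = 201)
    r <- minimum_control_energy(p)
    bound <- 1 * sum((pr$A %*% pr$xT)^2)      # T * ||A xT||^2
    expect_lte(r$total_energy, bound * (1 + 1e-9))
    expect_lte(r$terminal_residual, 1e-6)
  }
})

test_that("energy is quadratically homogeneous in the endpoint scale", {
  set.seed(5)
  pr <- random_control_problem(5)
  r1 <- minimum_control_energy(control_problem(pr$A, pr$x0, pr$xT, n_steps = 201))
  s <- 3.7
  r2 <- minimum_control_energy(control_problem(pr$A, s * pr$x0, s * pr$xT,
                                               n_steps = 201))
  expect_equal(r2$total_energy, s^2 * r1$total_energy,
               tolerance = 1e-9)
  expect_equal(r2$nodal_energy, s^2 * r1$nodal_energy, tolerance = 1e-8)
})

test_that("optimal energy matches the discretized QP oracle on random systems", {
  set.seed(6)
  for (i in 1:10) {
    pr <- random_control_problem(5)
    r <- minimum_control_energy(control_problem(pr$A, pr$x0, pr$xT,
                                                n_steps = 1001))
    o <- oracle_energy_qp(pr$A, pr$x0, pr$xT, m = 400)
    expect_lt(abs(r$total_energy - o$total_energy) / o$total_energy, 0.005)
    expect_lte(r$terminal_residual, 1e-6)
    expect_equal(sum(r$nodal_energy), r$total_energy,
                 tolerance = 1e-9 * r$total_energy)
    expect_true(all(r$nodal_energy >= 0))
  }
})

test_that("solution is insensitive to grid refinement", {
  set.seed(7)
  pr <- random_control_problem(6)
  e1 <- minimum_control_energy(control_problem(pr$A, pr$x0, pr$xT,
                                               n_steps = 501))$total_energy
  e2 <- minimum_control_energy(control_problem(pr$A, pr$x0, pr$xT,
                                               n_steps = 1001))$total_energy
  expect_lt(abs(e1 - e2) / e2, 0.001)
})

test_that("transition suite solves the four problems with shared dynamics", {
  set.seed(8)
  atl <- make_atlas(16, 4, 2, seed = 1)
  sc <- make_structural_connectome(atl, seed = 2)
  xi <- rnorm(20, 1); xs <- rnorm(20, 0.3)
  ts_ <- transition_suite(sc, xi, xs, n_steps = 201)
  expect_named(ts_$log_energy, c("IS", "SI", "II", "SS"))
  # persistence problems use equal endpoints
  expect_equal(ts_$results$II$x_traj[1, ], xi, tolerance = 1e-12)
  expect_equal(ts_$results$II$x_traj[201, ], xi, tolerance = 1e-6)
  expect_equal(ts_$results$SS$x_traj[1, ], xs, tolerance = 1e-12)
  # scaling both endpoints scales every energy by s^2
  s <- 2
  ts2 <- transition_suite(sc, s * xi, s * xs, n_steps = 201)
  expect_equal(ts2$total_energy, s^2 * ts_$total_energy, tolerance = 1e-8)
})

test_that("top contributors use ceiling arithmetic and mean log ranking", {
  E <- rbind(c(5, 1, 3, 2, 4, 6, 7, 0.5, 0.2, 8),
             c(4, 2, 3, 1, 5, 7, 6, 0.4, 0.3, 9))
  colnames(E) <- paste0("P", 1:10)
  nc <- nodal_contributions(E, fraction = 0.2)
  expect_length(nc$top, 2)
  mle <- colMeans(log(E))
  expect_equal(nc$ranking, order(mle, decreasing = TRUE))
  # single subject: ranking equals that subject's energies sorted
  nc1 <- nodal_contributions(E[1, ], fraction = 0.3)
  expect_equal(nc1$ranking, order(E[1, ], decreasing = TRUE))
  expect_length(nc1$top, 3)
})

test_that("hierarchy correlation behaves on monotone, reversed and independent maps", {
  atl <- make_atlas(40, 8, 4, seed = 1)
  vals <- as.numeric(atl$network_rank)
  vals[is.na(vals)] <- 0
  expect_equal(hierarchy_correlation(vals, atl), 1)
  expect_equal(hierarchy_correlation(-vals, atl), -1)
  set.seed(9)
  rhos <- vapply(1:200, function(i) hierarchy_correlation(rnorm(48), atl),
                 numeric(1))
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(200))
})
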