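two_cliques <- function(m) {
  n <- 2 * m
  W <- matrix(0, n, n)
  W[1:m, 1:m] <- 1
  W[(m + 1):n, (m + 1):n] <- 1
  diag(W) <- 0
  W
}

test_that("signed modularity matches trivial identities", {
  W <- matrix(0.4, 5, 5); diag(W) <- 0
  expect_equal(signed_modularity(W, rep(1, 5)), 0, tolerance = 1e-14)
  expect_equal(signed_modularity(matrix(0, 4, 4), c(1, 1, 2, 2)), 0)
})

test_that("Q, participation and within-module z equal exhaustive oracles on random signed graphs", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(3:6, 1)
    W <- random_signed_fc(n)
    m <- sample(1:3, n, replace = TRUE)
    m <- as.integer(factor(m))                # contiguous module ids
    gamma <- sample(c(0.8, 1, 1.3), 1)
    expect_equal(signed_modularity(W, m, gamma), oracle_signed_q(W, m, gamma),
                 tolerance = 1e-12)
    expect_equal(participation_coefficient(W, m), oracle_pc(W, m),
                 tolerance = 1e-12)
    expect_equal(within_module_z(W, m), oracle_wz(W, m), tolerance = 1e-12)
    # centering identity: z sums to ~0 within each module
    z <- within_module_z(W, m)
    for (s in unique(m)) expect_lt(abs(mean(z[m == s])), 1e-12)
  }
})

test_that("two positive cliques: correct partition is the exhaustive optimum and a negative bridge raises Q", {
  W <- two_cliques(3)
  part <- c(1, 1, 1, 2, 2, 2)
  q_direct <- oracle_signed_q(W, part)
  expect_equal(signed_modularity(W, part), q_direct, tolerance = 1e-12)
  best <- oracle_best_partition(W)
  expect_equal(q_direct, best$q, tolerance = 1e-12)
  # joining the cliques with one negative edge increases Q of the split
  Wneg <- W; Wneg[1, 4] <- Wneg[4, 1] <- -0.5
  Wpos <- W; Wpos[1, 4] <- Wpos[4, 1] <- 0.5
  expect_gt(signed_modularity(Wneg, part), signed_modularity(Wpos, part))
  expect_equal(signed_modularity(Wneg, part), oracle_signed_q(Wneg, part),
               tolerance = 1e-12)
})

test_that("louvain recovers planted cliques, respects the uniform-graph bound, and is seed-deterministic", {
  W <- two_cliques(4)
  truth <- rep(1:2, each = 4)
  best <- oracle_best_partition(W)
  for (it in 1:20) {
    p <- louvain_best(W, n_iter = 5, seed = it)
    expect_equal(p$n_modules, 2)
    expect_true(all(table(p$module_of, truth) %in% c(0, 4)))
    expect_equal(p$q_value, best$q, tolerance = 1e-12)
  }
  # complete uniform positive graph: no split beats one module
  Wu <- matrix(1, 6, 6); diag(Wu) <- 0
  p <- louvain_best(Wu, n_iter = 20, seed = 3)
  expect_lte(p$q_value, signed_modularity(Wu, rep(1, 6)) + 1e-12)
  # determinism
  p1 <- louvain_best(two_cliques(5), n_iter = 10, seed = 9)
  p2 <- louvain_best(two_cliques(5), n_iter = 10, seed = 9)
  expect_identical(p1, p2)
})

test_that("louvain Q is optimal on random planted block models verified exhaustively", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 8
    truth <- rep(1:2, each = 4)
    W <- matrix(runif(n * n, -0.2, 0.1), n, n)
    same <- outer(truth, truth, "==")
    W[same] <- runif(sum(same), 0.5, 1)
    W <- (W + t(W)) / 2; diag(W) <- 0
    best <- oracle_best_partition(W)
    p <- louvain_best(W, n_iter = 30, seed = rep)
    expect_gte(p$q_value, best$q - 1e-12)
  }
})

test_that("participation coefficient hand examples", {
  # node with all positive strength in its own module -> 0
  W <- two_cliques(3)
  expect_equal(participation_coefficient(W, rep(1:2, each = 3)), rep(0, 6))
  # node with equal strength to each of 2 modules -> 0.5
  W2 <- matrix(0, 3, 3)
  W2[1, 2] <- W2[2, 1] <- 0.7
  W2[1, 3] <- W2[3, 1] <- 0.7
  pc <- participation_coefficient(W2, c(1, 1, 2))
  expect_equal(pc[1], 0.5)
  # zero-strength node -> 0
  W3 <- matrix(0, 3, 3)
  expect_equal(participation_coefficient(W3, c(1, 2, 2)), rep(0, 3))
})

test_that("within-module z hand example uses population SD and sigma=0 rule", {
  # 3-node module with within-strengths {2, 2, 5}
  W <- matrix(0, 4, 4)
  W[1, 3] <- W[3, 1] <- 2
  W[2, 3] <- W[3, 2] <- 2
  W[1, 2] <- W[2, 1] <- 0
  W[3, 3] <- 0
  # strengths within module {1,2,3}: node1 = 2, node2 = 2, node3 = 4... build exact case instead
  W <- matrix(0, 3, 3)
  W[1, 3] <- W[3, 1] <- 2
  W[2, 3] <- W[3, 2] <- 3
  # kappa: node1=2, node2=3, node3=5 -> not the target; assert via oracle instead
  m <- c(1, 1, 1)
  expect_equal(within_module_z(W, m), oracle_wz(W, m), tolerance = 1e-12)
  # designed {2,2,5}: star with unequal spokes
  W <- matrix(0, 3, 3)
  W[1, 3] <- W[3, 1] <- 2
  W[2, 3] <- W[3, 2] <- 2
  W[1, 2] <- W[2, 1] <- 0
  kap <- rowSums(pmax(W, 0))                 # 2, 2, 4
  W[1, 2] <- W[2, 1] <- 0
  W[3, 1] <- W[1, 3] <- 2
  W[3, 2] <- W[2, 3] <- 3                    # kappa = 2, 3, 5
  z <- within_module_z(W, c(1, 1, 1))
  mu <- mean(c(2, 3, 5)); sig <- sqrt(mean((c(2, 3, 5) - mu)^2))
  expect_equal(z, (c(2, 3, 5) - mu) / sig, tolerance = 1e-12)
  # sigma = 0 -> z = 0 for all
  expect_equal(within_module_z(two_cliques(3), rep(1:2, each = 3)), rep(0, 6))
})

test_that("cartographic histogram normalises, clamps and matches binomial expectation", {
  h <- cartographic_histogram(rep(0, 7), rep(0, 7))
  expect_equal(sum(h), 1)
  expect_equal(h[1, 5], 1)                   # pc=0 -> bin 1; z=0 -> boundary bin 5
  set.seed(5)
  pc <- runif(10000); z <- rnorm(10000)
  h2 <- cartographic_histogram(pc, z, 10, 10)
  expect_equal(sum(h2), 1, tolerance = 1e-12)
  margins <- rowSums(h2)
  expect_true(all(abs(margins - 0.1) < 3 * sqrt(0.1 * 0.9 / 10000)))
  # out-of-range z lands in edge bins
  h3 <- cartographic_histogram(c(0.5, 0.5), c(-99, 99))
  expect_equal(h3[5, 1] + h3[5, 10], 1)
  expect_error(cartographic_histogram(0.1, 0, pc_bins = 0), "pc_bins")
})

test_that("state clustering recovers duplicate templates exactly and naming is pc-driven", {
  set.seed(8)
  mk_prof <- function(pc_level) {
    pc <- rep(pc_level, 20) + runif(20, 0, 0.01)
    z <- rnorm(20)
    list(pc = pc, z = z, hist = cartographic_histogram(pc, z))
  }
  pA <- mk_prof(0.8); pB <- mk_prof(0.2)
  profiles <- list(pA, pB, pA, pA, pB)[c(1, 2, 3, 4, 5)]
  asg <- cluster_states(profiles, seed = 1)
  expect_equal(asg$labels, c("Integrated", "Segregated", "Integrated",
                             "Integrated", "Segregated"))
  expect_gt(asg$mean_pc["Integrated"], asg$mean_pc["Segregated"])
  # invariance to window order permutation (same windows, shuffled)
  ord <- c(5, 3, 1, 2, 4)
  asg2 <- cluster_states(profiles[ord], seed = 1)
  expect_equal(asg2$labels, asg$labels[ord])
  # identical windows -> degenerate error
  expect_error(cluster_states(list(pA, pA, pA), seed = 1), "degenerate")
})

test_that("silhouette evaluation finds the planted number of regimes", {
  set.seed(9)
  mk <- function(pc_level) {
    pc <- pmin(pmax(rnorm(30, pc_level, 0.02), 0), 1)
    z <- rnorm(30)
    list(pc = pc, z = z, hist = cartographic_histogram(pc, z))
  }
  two <- c(lapply(1:8, function(i) mk(0.2)), lapply(1:8, function(i) mk(0.8)))
  q2 <- evaluate_k(two, k_range = 2:4, seed = 2)
  expect_equal(names(which.max(q2)), "k2")
  three <- c(lapply(1:6, function(i) mk(0.1)), lapply(1:6, function(i) mk(0.5)),
             lapply(1:6, function(i) mk(0.9)))
  q3 <- evaluate_k(three, k_range = 2:5, seed = 3)
  expect_equal(names(which.max(q3)), "k3")
  # degenerate k on duplicate templates is skipped with a warning
  pA <- mk(0.3); pB <- mk(0.7)
  expect_warning(qd <- evaluate_k(list(pA, pB, pA, pB), k_range = 2:3, seed = 4),
                 "distinct")
  expect_true(is.na(qd["k3"]))
})
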