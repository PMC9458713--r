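test_that("regime correlation matrices are valid correlation matrices", {
  atl <- make_atlas(24, 8, 4, seed = 1)
  for (b in c(0.3, 0, -0.15)) {
    sp <- regime_spec(as.integer(cut(1:32, 4)), 0.6, b)
    R <- regime_correlation(sp)
    expect_equal(R, t(R))
    expect_equal(diag(R), rep(1, 32))
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9)
  }
  expect_error(regime_spec(1:4, 1.2, 0.1), "within_corr")
  expect_error(regime_spec(1:4, 0.5, 1.0), "between_corr")
})

test_that("absorbing chains and identical regimes behave as the model dictates", {
  atl <- make_atlas(16, 0, 2, seed = 1)
  b <- simulate_bold(atl, p_stay = c(Integrated = 0.5, Segregated = 1),
                     n_timepoints = 50, seed = 2, init_state = "Segregated")
  expect_true(all(b$labels == "Segregated"))
  # identical regimes -> downstream recovery at chance: label sequence still hidden
  same <- regime_spec(atl$network, 0.5, 0.2, noise_sd = 0)
  b2 <- simulate_bold(atl, same, same, n_timepoints = 60, seed = 3)
  expect_equal(dim(b2$values), c(60, 16))
})

test_that("empirical correlations of regime samples converge to the attenuated regime matrix", {
  atl <- make_atlas(12, 0, 3, seed = 1)
  mod <- as.integer(cut(1:12, 3))
  ns <- 0.2
  sp <- regime_spec(mod, 0.6, 0.15, noise_sd = ns)
  # large-sample Monte-Carlo draw vs the specified regime matrix
  b <- simulate_bold(atl, sp, sp, p_stay = c(Integrated = 1, Segregated = 0),
                     n_timepoints = 10000, seed = 4, init_state = "Integrated")
  emp <- cor(b$values)
  same <- outer(mod, mod, "==") & upper.tri(emp)
  diffm <- outer(mod, mod, "!=") & upper.tri(emp)
  atten <- 1 / (1 + ns^2)
  se <- 1 / sqrt(10000)
  expect_lt(abs(mean(emp[same]) - 0.6 * atten), 3 * se)
  expect_lt(abs(mean(emp[diffm]) - 0.15 * atten), 3 * se)
})

test_that("markov stay probabilities converge to p_stay", {
  atl <- make_atlas(8, 0, 2, seed = 1)
  ps <- c(Integrated = 0.93, Segregated = 0.97)
  b <- simulate_bold(atl[, ], integrated = regime_spec(rep(1:2, 4), 0.5, 0, 0),
                     segregated = regime_spec(rep(1:2, 4), 0.5, 0, 0),
                     p_stay = ps, n_timepoints = 10000, seed = 5)
  a <- b$labels[-10000]; nxt <- b$labels[-1]
  for (s in names(ps)) {
    n_s <- sum(a == s)
    stay <- sum(a == s & nxt == s) / n_s
    ci <- 3 * sqrt(ps[[s]] * (1 - ps[[s]]) / n_s)
    expect_lt(abs(stay - ps[[s]]), ci)
  }
})

test_that("structural connectome invariants: symmetry, hub scaling, module contrast", {
  atl <- make_atlas(16, 4, 2, seed = 1)
  W1 <- make_structural_connectome(atl, hub_scale = 1, seed = 9)
  expect_equal(max(abs(W1 - t(W1))), 0)
  expect_equal(diag(W1), setNames(rep(0, 20), atl$parcel_id))
  expect_true(all(W1 >= 0))
  hubs <- atl$parcel_id[c(2, 7)]
  W2 <- make_structural_connectome(atl, hub_nodes = hubs, hub_scale = 0.6, seed = 9)
  hub <- atl$parcel_id %in% hubs
  inc <- outer(hub, hub, "|")
  expect_equal(W2[inc], W1[inc] * 0.6, tolerance = 1e-12)
  expect_equal(W2[!inc], W1[!inc])
  # monotone hub weakening: smaller hub_scale strictly weakens hub rows
  W3 <- make_structural_connectome(atl, hub_nodes = hubs, hub_scale = 0.3, seed = 9)
  expect_true(all(rowSums(W3)[hub] < rowSums(W2)[hub]))
  expect_error(make_structural_connectome(atl, density = 0), "degenerate")
  expect_error(make_structural_connectome(atl, hub_nodes = "nope"), "subset")
})

test_that("within-module structural weights dominate between-module weights", {
  atl <- make_atlas(20, 0, 2, seed = 1)
  mod <- as.integer(factor(atl$network))
  same <- outer(mod, mod, "==") & upper.tri(diag(20))
  diffm <- outer(mod, mod, "!=") & upper.tri(diag(20))
  ok <- vapply(1:100, function(s) {
    W <- make_structural_connectome(atl, density = 1, seed = s)
    mean(W[same]) > mean(W[diffm])
  }, logical(1))
  expect_true(all(ok))
})

test_that("receptor maps: anchoring, rank preservation and smoothness-zero independence", {
  atl <- make_atlas(60, 8, 4, seed = 1)
  anchor <- rnorm(68)
  m1 <- make_receptor_map(atl, anchor_map = anchor, anchor_rho = 1, seed = 2)
  expect_equal(cor(m1, anchor, method = "spearman"), 1)
  mneg <- make_receptor_map(atl, anchor_map = anchor, anchor_rho = -1, seed = 2)
  expect_equal(cor(mneg, anchor, method = "spearman"), -1)
  expect_error(make_receptor_map(atl, anchor_rho = 1.5), "anchor_rho")
  expect_error(make_receptor_map(atl, anchor_map = 1:3), "per atlas parcel")
  # smoothness 0: neighbouring parcels uncorrelated on average
  lags <- vapply(1:200, function(s) {
    m <- make_receptor_map(atl, smoothness_length = 0, seed = s)
    cor(m[-1], m[-length(m)])
  }, numeric(1))
  expect_lt(abs(mean(lags)), 3 * sd(lags) / sqrt(200))
})

test_that("anchored maps land near the target Spearman correlation", {
  atl <- make_atlas(200, 32, 7, seed = 1)
  anchor <- make_receptor_map(atl, seed = 999)
  rhos <- vapply(1:100, function(s)
    cor(make_receptor_map(atl, anchor_map = anchor, anchor_rho = -0.35,
                          seed = s),
        anchor, method = "spearman"), numeric(1))
  expect_lt(abs(mean(rhos) - (-0.35)), 0.1)
  expect_lt(sd(rhos), 0.2)
})

test_that("cohorts regenerate bit-identically and carry valid window truth", {
  atl <- make_atlas(24, 8, 4, seed = 1)
  c1 <- make_cohort(atlas = atl, n_per_group = c(VH = 2, nonVH = 2, control = 1),
                    n_timepoints = 40, window_len = 20, seed = 5)
  c2 <- make_cohort(atlas = atl, n_per_group = c(VH = 2, nonVH = 2, control = 1),
                    n_timepoints = 40, window_len = 20, seed = 5)
  expect_identical(c1, c2)
  for (s in c1$subjects) {
    expect_length(s$true_window_labels, nrow(sliding_windows(40, 20, 1)))
    expect_true(all(s$true_window_labels %in% c("Integrated", "Segregated")))
    expect_equal(dim(s$bold$values), c(40, 32))
  }
  expect_setequal(vapply(c1$subjects, `[[`, "", "group"),
                  c("VH", "nonVH", "control"))
})
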