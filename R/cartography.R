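#' Signed asymmetric modularity
#'
#' Modularity of a partition of a signed weighted network, with the
#' asymmetric weighting of positive and negative contributions: the positive
#' term is scaled by 1/v+ and the negative term by 1/(v+ + v-), where v+ and
#' v- are the total positive and negative weight. The chance expectation for
#' each sign is the configuration null e_ij = gamma * s_i s_j / v computed
#' from that sign's strengths, summed over all same-module pairs (self-pairs
#' included, with zero self-weight).
#'
#' @param W symmetric zero-diagonal signed matrix (an FC matrix).
#' @param module_of integer module index per node (1..M).
#' @param gamma resolution parameter.
#' @return realized modularity Q (0 for an all-zero matrix).
#' @export
signed_modularity <- function(W, module_of, gamma = 1) {
  assert_symmetric(W)
  n <- nrow(W)
  if (length(module_of) != n) stop_invalid("partition must cover all nodes")
  same <- outer(module_of, module_of, "==")
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  if (vp == 0 && vn == 0) return(0)
  q <- 0
  if (vp > 0)
    q <- q + sum((Wp - gamma * tcrossprod(sp) / vp)[same]) / vp
  if (vn > 0)
    q <- q - sum((Wn - gamma * tcrossprod(sn) / vn)[same]) / (vp + vn)
  q
}

# Modularity matrix B with Q(partition) = sum_{same module} B_ij,
# symmetric; this is what the Louvain heuristic optimises.
modularity_matrix <- function(W, gamma = 1) {
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  B <- matrix(0, nrow(W), ncol(W))
  if (vp > 0) B <- B + (Wp - gamma * tcrossprod(sp) / vp) / vp
  if (vn > 0) B <- B - (Wn - gamma * tcrossprod(sn) / vn) / (vp + vn)
  (B + t(B)) / 2
}

#' Best-of-n Louvain community detection under signed modularity
#'
#' Runs the greedy Louvain heuristic (node moving + aggregation) `n_iter`
#' times on the signed asymmetric modularity matrix, each run with its own
#' RNG sub-stream, and returns the partition with the highest Q (ties keep
#' the earliest run). Q is re-evaluated through [signed_modularity()] so the
#' stored value is exactly the quantity the partition score claims.
#'
#' @param W symmetric signed matrix.
#' @param gamma resolution parameter.
#' @param n_iter number of independent restarts.
#' @param seed integer seed governing all restarts.
#' @return a `partition` list: `module_of`, `n_modules`, `gamma`, `q_value`.
#' @export
louvain_best <- function(W, gamma = 1, n_iter = 100L, seed = 1L) {
  assert_symmetric(W)
  n_iter <- assert_count(n_iter, "n_iter")
  B <- modularity_matrix(W, gamma)
  best <- NULL
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      res <- louvain_modmat(B, 1e-10)
      if (is.null(best) || res$q > best$q + 1e-12) best <- res
    }
  })
  q <- signed_modularity(W, best$membership, gamma)
  structure(list(module_of = best$membership, n_modules = best$n_modules,
                 gamma = gamma, q_value = q),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d modules, Q = %.4f (gamma = %g)\n",
              x$n_modules, x$q_value, x$gamma))
  invisible(x)
}

#' Participation coefficient
#'
#' P_i = 1 - sum_s (kappa_is / k_i)^2 over modules s, where kappa_is is node
#' i's positive strength into module s and k_i its total positive strength.
#' Nodes with no positive strength get P_i = 0.
#'
#' @param W symmetric signed matrix (positive part used).
#' @param module_of module index per node, or a `partition`.
#' @return numeric vector in \[0, 1\].
#' @export
participation_coefficient <- function(W, module_of) {
  if (inherits(module_of, "partition")) module_of <- module_of$module_of
  assert_symmetric(W)
  Wp <- pmax(W, 0)
  M <- max(module_of)
  ind <- outer(module_of, seq_len(M), "==") * 1     # N x M membership
  kappa <- Wp %*% ind                               # strength into each module
  k <- rowSums(Wp)
  pc <- 1 - rowSums((kappa / ifelse(k > 0, k, 1))^2)
  pc[k == 0] <- 0
  pmin(pmax(pc, 0), 1)
}

#' Within-module degree z-score
#'
#' z_i = (kappa_is - mean kappa_.s) / sd kappa_.s, where kappa_is is node i's
#' positive strength to other nodes of its own module s and the moments are
#' taken over all nodes of s (population SD, matching the Brain Connectivity
#' Toolbox convention). Modules with zero dispersion give z = 0.
#'
#' @inheritParams participation_coefficient
#' @return numeric vector, mean 0 within every module.
#' @export
within_module_z <- function(W, module_of) {
  if (inherits(module_of, "partition")) module_of <- module_of$module_of
  assert_symmetric(W)
  Wp <- pmax(W, 0)
  n <- nrow(W)
  z <- numeric(n)
  for (s in unique(module_of)) {
    idx <- which(module_of == s)
    kap <- rowSums(Wp[idx, idx, drop = FALSE])
    mu <- mean(kap)
    sig <- sqrt(mean((kap - mu)^2))                 # population SD
    z[idx] <- if (sig > 0) (kap - mu) / sig else 0
  }
  z
}

#' Joint (participation coefficient, within-module z) histogram
#'
#' The cartographic profile of one window: a 2-D histogram of nodes over
#' pc in \[0, 1\] and z in `z_range` (out-of-range z clamped to the edge
#' bins), normalised to total mass 1.
#'
#' @param pc,z per-node values of equal length.
#' @param pc_bins,z_bins bin counts.
#' @param z_range z axis limits.
#' @return pc_bins x z_bins matrix summing to 1.
#' @export
cartographic_histogram <- function(pc, z, pc_bins = 10L, z_bins = 10L,
                                   z_range = c(-5, 5)) {
  pc_bins <- assert_count(pc_bins, "pc_bins")
  z_bins <- assert_count(z_bins, "z_bins")
  if (length(pc) != length(z)) stop_invalid("pc and z must have equal length")
  zc <- pmin(pmax(z, z_range[1]), z_range[2])
  ip <- pmin(pmax(ceiling(pc * pc_bins), 1L), pc_bins)
  iz <- pmin(pmax(ceiling((zc - z_range[1]) / diff(z_range) * z_bins), 1L), z_bins)
  H <- matrix(0, pc_bins, z_bins)
  for (k in seq_along(ip)) H[ip[k], iz[k]] <- H[ip[k], iz[k]] + 1
  H / length(pc)
}

#' Cartographic profile of one FC window
#'
#' Convenience composition: signed Louvain partition, participation
#' coefficient, within-module z and their joint histogram.
#'
#' @param W FC matrix of one window.
#' @param gamma,n_iter,seed passed to [louvain_best()].
#' @param pc_bins,z_bins,z_range passed to [cartographic_histogram()].
#' @return list with `partition`, `pc`, `z`, `hist`.
#' @export
cartographic_profile <- function(W, gamma = 1, n_iter = 100L, seed = 1L,
                                 pc_bins = 10L, z_bins = 10L, z_range = c(-5, 5)) {
  part <- louvain_best(W, gamma = gamma, n_iter = n_iter, seed = seed)
  pc <- participation_coefficient(W, part)
  z <- within_module_z(W, part)
  list(partition = part, pc = pc, z = z,
       hist = cartographic_histogram(pc, z, pc_bins, z_bins, z_range))
}

#' Cluster windows into Integrated and Segregated states
#'
#' k = 2 k-means (Euclidean, multiple restarts) on the flattened cartographic
#' histograms of one participant's windows. The cluster with the strictly
#' higher mean per-window participation coefficient is named `Integrated`;
#' a tie raises an error rather than guessing.
#'
#' @param profiles list of per-window profiles (each with `$hist` and `$pc`),
#'   as produced by [cartographic_profile()].
#' @param seed integer seed.
#' @param n_restarts k-means restarts.
#' @return a `state_assignment` list: `labels` (per window), `centroids`,
#'   `mean_pc` (per cluster), `inertia`, `window_mean_pc`.
#' @export
cluster_states <- function(profiles, seed = 1L, n_restarts = 50L) {
  if (length(profiles) < 2L) stop_invalid("need at least 2 windows to cluster")
  X <- t(vapply(profiles, function(p) as.numeric(p$hist),
                numeric(length(profiles[[1]]$hist))))
  wpc <- vapply(profiles, function(p) mean(p$pc), numeric(1))
  if (nrow(unique(X)) < 2L)
    stop_invalid("degenerate clustering: all windows have identical profiles; ",
                 "two states cannot be distinguished")
  km <- with_seed(seed, kmeans(X, centers = 2L, nstart = n_restarts, iter.max = 100L))
  mean_pc <- tapply(wpc, km$cluster, mean)
  if (abs(diff(range(mean_pc))) < 1e-15)
    stop_invalid("degenerate clustering: clusters have identical mean ",
                 "participation coefficient; Integrated state undefined")
  integrated_cluster <- as.integer(names(which.max(mean_pc)))
  labels <- ifelse(km$cluster == integrated_cluster, "Integrated", "Segregated")
  ord <- if (integrated_cluster == 1L) 1:2 else 2:1
  structure(list(labels = labels,
                 centroids = km$centers[ord, , drop = FALSE],
                 mean_pc = c(Integrated = unname(mean_pc[as.character(integrated_cluster)]),
                             Segregated = unname(mean_pc[as.character(3L - integrated_cluster)])),
                 inertia = km$tot.withinss,
                 window_mean_pc = wpc),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat(sprintf("state_assignment: %d windows (%d Integrated, %d Segregated); mean pc I=%.3f S=%.3f\n",
              length(x$labels), sum(x$labels == "Integrated"),
              sum(x$labels == "Segregated"), x$mean_pc["Integrated"],
              x$mean_pc["Segregated"]))
  invisible(x)
}

#' Silhouette-based evaluation of the number of clusters
#'
#' Mean silhouette width of k-means solutions over a range of k, on the
#' flattened histograms. Degenerate k (more centers than distinct windows)
#' are skipped with a warning and reported as NA.
#'
#' @param profiles as in [cluster_states()].
#' @param k_range candidate cluster counts.
#' @param seed integer seed.
#' @return named numeric vector of mean silhouette widths.
#' @export
evaluate_k <- function(profiles, k_range = 2:6, seed = 1L) {
  X <- t(vapply(profiles, function(p) as.numeric(p$hist),
                numeric(length(profiles[[1]]$hist))))
  d <- stats::dist(X)
  n_distinct <- nrow(unique(X))
  out <- setNames(rep(NA_real_, length(k_range)), paste0("k", k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k >= nrow(X) || k > n_distinct) {
      warning(sprintf("k = %d skipped: only %d distinct windows", k, n_distinct),
              call. = FALSE)
      next
    }
    km <- with_seed(derive_seed(seed, k),
                    kmeans(X, centers = k, nstart = 20L, iter.max = 100L))
    sil <- cluster::silhouette(km$cluster, d)
    out[i] <- mean(sil[, "sil_width"])
  }
  out
}
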