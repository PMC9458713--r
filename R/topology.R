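#' Mean functional connectome per state
#'
#' Elementwise mean of the windows assigned to each state. A state with no
#' windows is returned as `NULL` and flagged in `absent`.
#'
#' @param dfc a `dynamic_fc` (or plain list of FC matrices).
#' @param labels per-window state labels (or a `state_assignment`).
#' @return list with `Integrated`, `Segregated` (matrix or `NULL`),
#'   `n_windows` (named counts) and `absent` (named logical).
#' @export
state_mean_fc <- function(dfc, labels) {
  windows <- if (inherits(dfc, "dynamic_fc")) dfc$windows else dfc
  labels <- check_labels(labels)
  if (length(windows) != length(labels))
    stop_invalid("one label per window required")
  out <- list()
  counts <- c(Integrated = 0L, Segregated = 0L)
  for (s in c("Integrated", "Segregated")) {
    idx <- which(labels == s)
    counts[s] <- length(idx)
    out[[s]] <- if (length(idx)) Reduce(`+`, windows[idx]) / length(idx) else NULL
  }
  out$n_windows <- counts
  out$absent <- counts == 0L
  out
}

#' Mean signed connectivity density
#'
#' Mean of the off-diagonal upper-triangle weights. For a full signed
#' correlation matrix the usual binary density is ill-defined, so the mean
#' signed weight is reported; `positive_fraction = TRUE` instead gives the
#' fraction of positive edges.
#'
#' @param W FC matrix.
#' @param positive_fraction report fraction of positive edges instead.
#' @return scalar.
#' @export
fc_density <- function(W, positive_fraction = FALSE) {
  assert_square(W)
  v <- upper_tri_values(W)
  if (positive_fraction) mean(v > 0) else mean(v)
}

#' Shannon entropy of connectivity values
#'
#' Entropy (nats) of the histogram of upper-triangle weights over `n_bins`
#' fixed bins spanning \[-1, 1\].
#'
#' @param W FC matrix.
#' @param n_bins number of bins.
#' @return entropy in nats, in \[0, log(n_bins)\].
#' @export
weight_entropy <- function(W, n_bins = 64L) {
  assert_square(W)
  n_bins <- assert_count(n_bins, "n_bins")
  v <- upper_tri_values(W)
  idx <- pmin(pmax(ceiling((v + 1) / 2 * n_bins), 1L), n_bins)
  p <- tabulate(idx, n_bins) / length(v)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Structure-function coupling
#'
#' Spearman correlation between structural and functional edge weights over
#' the upper-triangle edges with nonzero structural weight.
#'
#' @param SC structural connectome (symmetric nonnegative).
#' @param FC functional connectome, same parcel order.
#' @return Spearman rho.
#' @export
structure_function_coupling <- function(SC, FC) {
  assert_square(SC, "SC"); assert_square(FC, "FC")
  if (!all(dim(SC) == dim(FC)))
    stop_invalid("SC and FC must have matching dimensions")
  ut <- upper.tri(SC)
  keep <- ut & SC > 0
  if (sum(keep) < 3) stop_invalid("fewer than 3 structural edges; coupling undefined")
  cor(SC[keep], FC[keep], method = "spearman")
}

#' Network-based statistic (NBS) group comparison
#'
#' Edgewise GLM contrast between two groups (optionally with covariates),
#' thresholded at |t| >= `t_threshold`; connected components of the
#' suprathreshold edges are scored by extent (edge count) and family-wise
#' error corrected against the max-component-size permutation null.
#' Covariates are handled by Freedman-Lane residual permutation: the reduced
#' (covariate-only) model's residuals are permuted and added back to its
#' fitted values before the full-model t-statistics are recomputed.
#'
#' @param matrices list of symmetric N x N subject matrices (same order as
#'   `group`).
#' @param group two-level factor (or coercible).
#' @param covariates optional numeric matrix (subjects x covariates).
#' @param t_threshold primary |t| threshold (> 0).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return an `nbs_result`: `components` (list of edge data frames with
#'   columns `i`, `j`, `t`), `component_sizes`, `p_fwe`, `null_max_size`,
#'   `t_threshold`, `n_perm`, `seed`, `t_stats` (edge vector), `edge_index`.
#' @export
nbs <- function(matrices, group, covariates = NULL, t_threshold = 2.7,
                n_perm = 5000L, seed = 1L) {
  if (!is.numeric(t_threshold) || length(t_threshold) != 1L || t_threshold <= 0)
    stop_invalid("`t_threshold` must be a positive scalar")
  n_perm <- assert_count(n_perm, "n_perm")
  group <- factor(group)
  if (nlevels(group) != 2L) stop_invalid("`group` must have exactly 2 levels")
  if (any(table(group) < 2L)) stop_invalid("need >= 2 subjects per group")
  ns <- length(matrices)
  if (ns != length(group)) stop_invalid("one matrix per subject required")

  N <- nrow(matrices[[1]])
  ut <- which(upper.tri(matrices[[1]]))
  Y <- t(vapply(matrices, function(m) m[ut], numeric(length(ut))))  # subj x edges

  g <- as.numeric(group == levels(group)[2])
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates)
  }
  p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  K <- XtXinv %*% t(X)
  cvec <- c(0, 1, rep(0, p - 2))
  cKc <- drop(t(cvec) %*% XtXinv %*% cvec)

  edge_t <- function(Ymat) {
    B <- K %*% Ymat
    res <- Ymat - X %*% B
    s2 <- colSums(res^2) / (ns - p)
    drop(cvec %*% B) / sqrt(pmax(s2 * cKc, .Machine$double.xmin))
  }

  comp_of_edges <- function(sup) {               # sup: indices into ut
    if (!length(sup)) return(list(sizes = integer(0), membership = integer(0)))
    ij <- arrayInd(ut[sup], c(N, N))
    gr <- igraph::graph_from_edgelist(ij, directed = FALSE)
    cm <- igraph::components(gr)
    em <- cm$membership[ij[, 1]]                 # component of each edge
    list(sizes = as.integer(table(em)), membership = as.integer(em))
  }

  tobs <- edge_t(Y)
  sup_obs <- which(abs(tobs) >= t_threshold)
  obs <- comp_of_edges(sup_obs)

  # Freedman-Lane: reduced model excludes the group column
  Z <- X[, -2, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Yfit <- Hz %*% Y
  Yres <- Y - Yfit

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(ns)
      tp <- edge_t(Yfit + Yres[perm, , drop = FALSE])
      sp <- which(abs(tp) >= t_threshold)
      cs <- comp_of_edges(sp)$sizes
      if (length(cs)) max(cs) else 0L
    }, integer(1))
  })

  sizes <- obs$sizes
  p_fwe <- vapply(sizes, function(sz)
    (1 + sum(null_max >= sz)) / (1 + n_perm), numeric(1))

  comps <- lapply(seq_along(sizes), function(ci) {
    e <- sup_obs[obs$membership == ci]
    ij <- arrayInd(ut[e], c(N, N))
    data.frame(i = ij[, 1], j = ij[, 2], t = tobs[e])
  })
  ord <- order(sizes, decreasing = TRUE)
  structure(list(components = comps[ord], component_sizes = sizes[ord],
                 p_fwe = p_fwe[ord], null_max_size = null_max,
                 t_threshold = t_threshold, n_perm = n_perm,
                 seed = as.integer(seed), t_stats = tobs, edge_index = ut),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("nbs_result: %d suprathreshold component(s) at |t| >= %.2f, %d permutations\n",
              length(x$components), x$t_threshold, x$n_perm))
  if (length(x$component_sizes))
    cat(sprintf("  sizes: %s; FWE p: %s\n",
                paste(x$component_sizes, collapse = ", "),
                paste(signif(x$p_fwe, 3), collapse = ", ")))
  invisible(x)
}
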