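#' State vector of a state-mean functional connectome
#'
#' The sum connectivity profile: per node, the sum of its signed edge
#' weights to all other nodes (self-edges are zero by construction).
#'
#' @param W state-mean FC matrix.
#' @return numeric vector of length N.
#' @export
state_vector <- function(W) {
  assert_square(W)
  rowSums(W) - diag(W)
}

#' Stabilize a structural connectome into a drift matrix
#'
#' A_stab = A / (1 + lambda_max(A)) - I, where lambda_max is the largest
#' eigenvalue of the (symmetric, nonnegative) connectome. Every eigenvalue
#' of the result is negative (the largest is -1/(1 + lambda_max)), so the
#' unforced linear system x' = A_stab x is strictly stable; the map is also
#' invariant to a global rescaling of A.
#'
#' @param A symmetric nonnegative zero-diagonal matrix.
#' @return stabilized drift matrix.
#' @export
stabilize <- function(A) {
  assert_symmetric(A, "A", tol = 1e-9)
  if (any(A < 0)) stop_invalid("structural connectome must be nonnegative")
  if (all(A == 0)) return(-diag(nrow(A)))
  lmax <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  A / (1 + lmax) - diag(nrow(A))
}

#' Define a fixed-endpoint linear-quadratic control problem
#'
#' Continuous-time dynamics x' = A x + B u with B = I (every node
#' controllable) and cost
#' integral_0^T (xT - x)' S (xT - x) + rho u'u dt, S = I, steering the
#' system from x(0) = x0 to x(T) = xT exactly.
#'
#' @param A_stab stabilized drift matrix (all eigenvalues negative; see
#'   [stabilize()]).
#' @param x0,xT initial and target state vectors.
#' @param rho input-penalty weight (> 0).
#' @param T_horizon control horizon (> 0).
#' @param n_steps trajectory grid points (>= 2).
#' @return a `control_problem` list.
#' @export
control_problem <- function(A_stab, x0, xT, rho = 1, T_horizon = 1,
                            n_steps = 1001L) {
  assert_square(A_stab, "A_stab")
  rho <- assert_scalar(rho, "rho", 1e-12)
  T_horizon <- assert_scalar(T_horizon, "T_horizon", 1e-12)
  n_steps <- assert_count(n_steps, "n_steps", min = 2L)
  n <- nrow(A_stab)
  if (length(x0) != n || length(xT) != n)
    stop_invalid("x0 and xT must have length nrow(A_stab)")
  ev <- eigen(A_stab, only.values = TRUE)$values
  if (max(Re(ev)) >= 0)
    stop_invalid("A_stab must have all eigenvalues with negative real part; ",
                 "apply stabilize() first")
  structure(list(A = A_stab, x0 = as.numeric(x0), xT = as.numeric(xT),
                 rho = rho, T_horizon = T_horizon, n_steps = n_steps),
            class = "control_problem")
}

# Hamiltonian-system quantities shared by all transitions with the same
# drift matrix: M is the 2N x 2N state/costate block matrix, E its horizon
# propagator, G = integral_0^T expm(M s) ds, and (Es, Gs) the per-grid-step
# versions.
control_cache <- function(A, rho, T_horizon, n_steps) {
  n <- nrow(A)
  M <- rbind(cbind(A, -diag(n) / (2 * rho)),
             cbind(-2 * diag(n), -t(A)))
  E <- as.matrix(Matrix::expm(M * T_horizon))
  G <- expm_integral(M, E, T_horizon)
  dt <- T_horizon / (n_steps - 1)
  Es <- as.matrix(Matrix::expm(M * dt))
  Gs <- expm_integral(M, Es, dt)
  list(M = M, E = E, G = G, Es = Es, Gs = Gs, dt = dt, n = n)
}

# integral_0^t expm(M s) ds; M is generically invertible here, with an
# augmented-exponential fallback for the singular case.
expm_integral <- function(M, Emat, t) {
  n2 <- nrow(M)
  G <- tryCatch(solve(M, Emat - diag(n2)), error = function(e) NULL)
  if (is.null(G)) {
    aug <- rbind(cbind(M, diag(n2)), matrix(0, n2, 2 * n2))
    G <- as.matrix(Matrix::expm(aug * t))[seq_len(n2), n2 + seq_len(n2)]
  }
  G
}

#' Solve the minimum control energy problem
#'
#' Solves the continuous-time fixed-endpoint linear-quadratic problem via
#' the Hamiltonian two-point boundary system: state and costate propagate
#' jointly under a 2N x 2N block matrix with constant forcing from the
#' target-tracking penalty; the matrix exponential over the horizon yields a
#' linear system for the initial costate that enforces x(T) = xT; the
#' optimal input is u(t) = -B'p(t) / (2 rho), evaluated on the
#' discretization grid, and per-node energies are trapezoid-rule integrals
#' of u_i(t)^2. The reported energy is this input cost alone; the full
#' objective (tracking + rho-weighted input) is also stored.
#'
#' @param problem a [control_problem()].
#' @param cache internal precomputation (used by [transition_suite()]).
#' @param residual_tol terminal residual above which the result is flagged.
#' @param rcond_threshold reciprocal-condition floor for the terminal system.
#' @return a `control_result`: `u_traj`, `x_traj` (n_steps x N),
#'   `nodal_energy`, `total_energy`, `log_energy`, `objective_value`,
#'   `terminal_residual`, `flagged`, `times`.
#' @export
minimum_control_energy <- function(problem, cache = NULL,
                                   residual_tol = 1e-6,
                                   rcond_threshold = 1e-12) {
  stopifnot(inherits(problem, "control_problem"))
  n <- length(problem$x0)
  if (is.null(cache))
    cache <- control_cache(problem$A, problem$rho, problem$T_horizon,
                           problem$n_steps)
  cvec <- c(rep(0, n), 2 * problem$xT)
  d <- drop(cache$G %*% cvec)
  E11 <- cache$E[seq_len(n), seq_len(n)]
  E12 <- cache$E[seq_len(n), n + seq_len(n)]
  rc <- rcond(E12)
  if (!is.finite(rc) || rc < rcond_threshold)
    stop_invalid(sprintf(
      "terminal boundary system ill-conditioned (rcond = %.3g < %.3g); ",
      rc, rcond_threshold),
      "consider a shorter horizon or larger rho")
  p0 <- solve(E12, problem$xT - drop(E11 %*% problem$x0) - d[seq_len(n)])

  ns <- problem$n_steps
  Z <- matrix(0, ns, 2 * n)
  Z[1, ] <- c(problem$x0, p0)
  ds <- drop(cache$Gs %*% cvec)
  for (k in seq_len(ns - 1L))
    Z[k + 1L, ] <- drop(cache$Es %*% Z[k, ]) + ds
  X <- Z[, seq_len(n), drop = FALSE]
  U <- -Z[, n + seq_len(n), drop = FALSE] / (2 * problem$rho)

  w <- c(0.5, rep(1, ns - 2L), 0.5) * cache$dt
  nodal <- colSums(U^2 * w)
  total <- sum(nodal)
  track <- sum(rowSums(sweep(X, 2, problem$xT)^2) * w)
  resid <- sqrt(sum((X[ns, ] - problem$xT)^2))
  flagged <- resid > residual_tol
  if (flagged)
    warning(sprintf("terminal residual %.3g exceeds tolerance %.3g", resid,
                    residual_tol), call. = FALSE)
  structure(list(u_traj = U, x_traj = X, nodal_energy = nodal,
                 total_energy = total, log_energy = log(total),
                 objective_value = track + problem$rho * total,
                 terminal_residual = resid, flagged = flagged,
                 times = seq(0, problem$T_horizon, length.out = ns)),
            class = "control_result")
}

#' @export
print.control_result <- function(x, ...) {
  cat(sprintf("control_result: total energy %.6g (log %.4f), terminal residual %.2g%s\n",
              x$total_energy, x$log_energy, x$terminal_residual,
              if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' Transition and persistence energies for one subject
#'
#' Solves the four problems sharing one stabilized drift matrix:
#' Integrated-to-Segregated (IS), Segregated-to-Integrated (SI), and the two
#' persistence problems II and SS where initial and target state coincide.
#'
#' @param sc structural connectome (raw; stabilized internally) or an
#'   already-stabilized drift matrix with `stabilized = TRUE`.
#' @param x_integrated,x_segregated state vectors (see [state_vector()]).
#' @param rho,T_horizon,n_steps control parameters.
#' @param stabilized set `TRUE` if `sc` is already a drift matrix.
#' @param normalize unit-normalize both state vectors before solving.
#'   Raw sum-connectivity vectors scale with how many (and how pure) windows
#'   entered each state mean, so cross-subject energy comparisons on raw
#'   vectors confound state geometry with estimation magnitude; the unit
#'   sphere removes that scale. Default `FALSE` (raw, as defined).
#' @return a `transition_suite` list: `results` (named list of
#'   `control_result`), `log_energy` (named vector IS/SI/II/SS),
#'   `nodal_energy` (4 x N matrix).
#' @export
transition_suite <- function(sc, x_integrated, x_segregated, rho = 1,
                             T_horizon = 1, n_steps = 1001L,
                             stabilized = FALSE, normalize = FALSE) {
  A <- if (stabilized) sc else stabilize(sc)
  if (normalize) {
    x_integrated <- x_integrated / sqrt(sum(x_integrated^2))
    x_segregated <- x_segregated / sqrt(sum(x_segregated^2))
  }
  cache <- control_cache(A, rho, T_horizon, n_steps)
  ends <- list(IS = list(x_integrated, x_segregated),
               SI = list(x_segregated, x_integrated),
               II = list(x_integrated, x_integrated),
               SS = list(x_segregated, x_segregated))
  results <- lapply(ends, function(e) {
    pr <- control_problem(A, e[[1]], e[[2]], rho = rho,
                          T_horizon = T_horizon, n_steps = n_steps)
    minimum_control_energy(pr, cache = cache)
  })
  structure(list(
    results = results,
    log_energy = vapply(results, `[[`, numeric(1), "log_energy"),
    total_energy = vapply(results, `[[`, numeric(1), "total_energy"),
    nodal_energy = t(vapply(results, `[[`, numeric(nrow(A)), "nodal_energy"))),
    class = "transition_suite")
}

#' Top contributors to a transition
#'
#' Ranks nodes by their mean log nodal energy across subjects and returns
#' the top `ceiling(fraction * N)` set (default top 20%).
#'
#' @param nodal_energy subjects x N matrix of nodal energies (or a vector
#'   for a single subject). Columns may be named by parcel.
#' @param fraction top fraction to extract.
#' @return list: `mean_log_energy` (per node), `ranking` (node indices,
#'   descending), `top` (indices), `top_names` (if named).
#' @export
nodal_contributions <- function(nodal_energy, fraction = 0.2) {
  if (is.vector(nodal_energy)) nodal_energy <- matrix(nodal_energy, 1,
                                                      dimnames = list(NULL, names(nodal_energy)))
  fraction <- assert_scalar(fraction, "fraction", 1e-12, 1)
  mle <- colMeans(log(pmax(nodal_energy, .Machine$double.xmin)))
  ranking <- order(mle, decreasing = TRUE)
  k <- ceiling(fraction * ncol(nodal_energy))
  top <- ranking[seq_len(k)]
  list(mean_log_energy = mle, ranking = ranking, top = top,
       top_names = colnames(nodal_energy)[top])
}

#' Correlation of a nodal map with the cortical hierarchy
#'
#' Spearman correlation between per-node values and the ordinal network
#' hierarchy rank (1 = unimodal ... transmodal), over cortical parcels only
#' (the subcortex carries no hierarchy position).
#'
#' @param values nodal vector of length N (atlas order).
#' @param atlas a `parcel_atlas` with `network_rank`.
#' @return Spearman rho.
#' @export
hierarchy_correlation <- function(values, atlas) {
  assert_atlas(atlas)
  if (length(values) != nrow(atlas))
    stop_invalid("`values` must have one entry per atlas parcel")
  keep <- atlas$is_cortical & !is.na(atlas$network_rank)
  if (sum(keep) < 3) stop_invalid("fewer than 3 cortical parcels")
  cor(values[keep], atlas$network_rank[keep], method = "spearman")
}
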