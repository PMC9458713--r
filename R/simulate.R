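#' Specify a connectivity regime
#'
#' A regime is a block-structured correlation model over parcels: every pair
#' of parcels in the same module correlates at `within_corr`, every pair in
#' different modules at `between_corr`, with unit variances. An Integrated
#' regime has `between_corr` close to `within_corr` (strong between-module
#' coupling); a Segregated regime has `between_corr` near zero. `noise_sd`
#' is the standard deviation of white measurement noise added on top of the
#' latent regime signal, so the observed off-diagonal correlations are the
#' regime values attenuated by 1/(1 + noise_sd^2).
#'
#' @param module_assignment integer/character vector mapping each parcel to a
#'   module.
#' @param within_corr within-module correlation, in (0, 1).
#' @param between_corr between-module correlation, in (-1, 1); negative
#'   values model anticorrelated systems (the implied matrix is repaired to
#'   PSD if the requested anticorrelation exceeds what the block geometry
#'   admits).
#' @param noise_sd standard deviation of additive white noise (>= 0).
#' @return a `regime_spec` list.
#' @export
regime_spec <- function(module_assignment, within_corr, between_corr, noise_sd = 0.3) {
  within_corr <- assert_scalar(within_corr, "within_corr", 1e-12, 1 - 1e-12)
  between_corr <- assert_scalar(between_corr, "between_corr", -1 + 1e-12, 1 - 1e-12)
  noise_sd <- assert_scalar(noise_sd, "noise_sd", 0)
  structure(list(module_assignment = module_assignment,
                 within_corr = within_corr,
                 between_corr = between_corr,
                 noise_sd = noise_sd),
            class = "regime_spec")
}

#' Correlation matrix implied by a regime, repaired to be positive
#' semi-definite
#'
#' Eigenvalues below 1e-10 are clipped and the diagonal renormalised to 1 so
#' the result is always a valid correlation matrix.
#'
#' @param spec a [regime_spec()].
#' @return symmetric unit-diagonal PSD matrix.
#' @export
regime_correlation <- function(spec) {
  stopifnot(inherits(spec, "regime_spec"))
  mod <- as.integer(factor(spec$module_assignment))
  n <- length(mod)
  same <- outer(mod, mod, "==")
  R <- ifelse(same, spec$within_corr, spec$between_corr)
  diag(R) <- 1
  repair_correlation(R)
}

repair_correlation <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 1e-10) {
    v <- pmax(e$values, 1e-10)
    R <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(R))
    if (any(d <= 0))
      stop_invalid("regime matrix could not be repaired to a correlation matrix ",
                   sprintf("(min eigenvalue %.3g, min diagonal %.3g)",
                           min(e$values), min(diag(R))))
    R <- R / tcrossprod(d)
    R <- (R + t(R)) / 2
    diag(R) <- 1
  }
  R
}

#' Simulate regime-switching BOLD timeseries
#'
#' A hidden two-state Markov chain (Integrated/Segregated) selects, at each
#' timepoint, which regime correlation matrix generates that timepoint's
#' signal; samples are i.i.d. zero-mean multivariate normal given the active
#' regime (no hemodynamic convolution), with optional additive white noise.
#' The hidden label sequence is returned as ground truth for downstream
#' state-recovery checks.
#'
#' @param atlas a `parcel_atlas`; its networks are the default modules.
#' @param integrated,segregated [regime_spec()] objects (defaults built from
#'   the atlas networks if `NULL`).
#' @param p_stay named vector of stay probabilities
#'   `c(Integrated=, Segregated=)`.
#' @param n_timepoints number of retained timepoints (>= 2).
#' @param tr_seconds repetition time in seconds.
#' @param seed integer seed.
#' @param init_state starting state, `"Integrated"`, `"Segregated"`, or
#'   `NULL` to draw from the chain's stationary distribution.
#' @return a `bold_ts` list: `values` (T x N matrix), `tr_seconds`,
#'   `parcel_id`, `labels` (hidden state per timepoint).
#' @export
simulate_bold <- function(atlas, integrated = NULL, segregated = NULL,
                          p_stay = c(Integrated = 0.98, Segregated = 0.98),
                          n_timepoints = 101L, tr_seconds = 0.7,
                          seed = 1L, init_state = NULL) {
  assert_atlas(atlas)
  n_timepoints <- assert_count(n_timepoints, "n_timepoints", min = 2L)
  tr_seconds <- assert_scalar(tr_seconds, "tr_seconds", 1e-9)
  if (is.null(integrated) || is.null(segregated)) {
    dflt <- default_regimes(atlas)
    if (is.null(integrated)) integrated <- dflt$integrated
    if (is.null(segregated)) segregated <- dflt$segregated
  }
  for (s in c("Integrated", "Segregated"))
    assert_scalar(p_stay[[s]], paste0("p_stay[", s, "]"), 0, 1)

  n <- nrow(atlas)
  Li <- attr(integrated, "chol_cache") %||%
    chol(regime_correlation(integrated) + diag(1e-12, n))
  Ls <- attr(segregated, "chol_cache") %||%
    chol(regime_correlation(segregated) + diag(1e-12, n))

  with_seed(seed, {
    labels <- markov_labels(p_stay, n_timepoints, init_state)
    Z <- matrix(rnorm(n_timepoints * n), n_timepoints, n)
    X <- matrix(0, n_timepoints, n)
    ii <- labels == "Integrated"
    if (any(ii)) X[ii, ] <- Z[ii, , drop = FALSE] %*% Li
    if (any(!ii)) X[!ii, ] <- Z[!ii, , drop = FALSE] %*% Ls
    ns <- ifelse(ii, integrated$noise_sd, segregated$noise_sd)
    if (any(ns > 0)) X <- X + ns * matrix(rnorm(n_timepoints * n), n_timepoints, n)
    colnames(X) <- atlas$parcel_id
    structure(list(values = X, tr_seconds = tr_seconds,
                   parcel_id = atlas$parcel_id, labels = labels),
              class = "bold_ts")
  })
}

#' Default integrated/segregated regime pair for an atlas
#'
#' Four contiguous macro-modules (coarse functional systems) share
#' within-module correlation 0.6; the integrated regime couples them at
#' +0.15, the segregated regime anticorrelates them at -0.15 (the
#' mirror-image design puts the participation-coefficient floor crossing at
#' the 50% regime-mixture point, and the negative between-module edges keep
#' Louvain's detected granularity stable under windowed sampling noise).
#'
#' @param atlas a `parcel_atlas`.
#' @param n_macro number of macro-modules.
#' @param within_corr,coupling,noise_sd regime parameters; the integrated
#'   regime uses `+coupling` between macro-modules and the segregated
#'   regime `-coupling`.
#' @return list with elements `integrated` and `segregated` ([regime_spec()]
#'   objects, with cached Cholesky factors for fast repeated simulation).
#' @export
default_regimes <- function(atlas, n_macro = 4L, within_corr = 0.6,
                            coupling = 0.15, noise_sd = 0.2) {
  assert_atlas(atlas)
  n <- nrow(atlas)
  macro <- as.integer(cut(seq_len(n), n_macro))
  integ <- regime_spec(macro, within_corr, coupling, noise_sd = noise_sd)
  seg <- regime_spec(macro, within_corr, -coupling, noise_sd = noise_sd)
  attr(integ, "chol_cache") <- chol(regime_correlation(integ) + diag(1e-12, n))
  attr(seg, "chol_cache") <- chol(regime_correlation(seg) + diag(1e-12, n))
  list(integrated = integ, segregated = seg)
}

# Hidden-chain draw from the CURRENT RNG state; simulate_bold draws this
# first under its seed, so conditioning code can prescan label sequences
# cheaply and then regenerate the identical full run from the same seed.
markov_labels <- function(p_stay, n_timepoints, init_state = NULL) {
  labels <- character(n_timepoints)
  pi_stat <- stationary_two_state(p_stay[["Integrated"]], p_stay[["Segregated"]])
  labels[1] <- if (is.null(init_state)) {
    if (runif(1) < pi_stat) "Integrated" else "Segregated"
  } else match.arg(init_state, c("Integrated", "Segregated"))
  for (t in seq_len(n_timepoints - 1L)) {
    stay <- p_stay[[labels[t]]]
    labels[t + 1L] <- if (runif(1) < stay) labels[t] else
      setdiff(c("Integrated", "Segregated"), labels[t])
  }
  labels
}

stationary_two_state <- function(p_ii, p_ss) {
  a <- 1 - p_ii; b <- 1 - p_ss
  if (a + b == 0) return(0.5)
  b / (a + b)
}

#' Generate a modular weighted structural connectome
#'
#' Edge weights are lognormal, heavier within modules than between; a random
#' symmetric mask retains a `density` fraction of edges. All edges incident
#' to `hub_nodes` are multiplied once by `hub_scale`; `hub_scale < 1` plants
#' the structural weakening of designated control-hub regions that
#' characterises the hallucinator-like group.
#'
#' @param atlas a `parcel_atlas`.
#' @param module_assignment per-parcel module labels (default: atlas
#'   networks).
#' @param hub_nodes character vector of parcel ids (subset of the atlas).
#' @param hub_scale multiplicative factor in (0, 1] applied to hub-incident
#'   edges.
#' @param density fraction of possible edges retained, in (0, 1].
#' @param seed integer seed.
#' @return symmetric nonnegative zero-diagonal matrix with parcel dimnames.
#' @export
make_structural_connectome <- function(atlas, module_assignment = NULL,
                                       hub_nodes = character(0),
                                       hub_scale = 1, density = 0.6,
                                       seed = 1L) {
  assert_atlas(atlas)
  if (is.null(module_assignment)) module_assignment <- atlas$network
  hub_scale <- assert_scalar(hub_scale, "hub_scale", 1e-12, 1)
  if (!is.numeric(density) || length(density) != 1L || density <= 0 || density > 1)
    stop_invalid("`density` must be in (0, 1]; density = 0 is degenerate")
  if (!all(hub_nodes %in% atlas$parcel_id))
    stop_invalid("`hub_nodes` must be a subset of atlas parcel ids")

  n <- nrow(atlas)
  mod <- as.integer(factor(module_assignment))
  with_seed(seed, {
    same <- outer(mod, mod, "==")
    meanlog <- ifelse(same, log(1.0), log(0.3))
    W <- matrix(rlnorm(n * n, meanlog = meanlog, sdlog = 0.5), n, n)
    keep <- matrix(runif(n * n) < density, n, n)
    W <- W * keep
    W[lower.tri(W)] <- t(W)[lower.tri(W)]           # symmetrise from upper
    diag(W) <- 0
    hub <- atlas$parcel_id %in% hub_nodes
    if (any(hub) && hub_scale < 1) {
      inc <- outer(hub, hub, "|")                   # incident once per edge
      W[inc] <- W[inc] * hub_scale
    }
    dimnames(W) <- list(atlas$parcel_id, atlas$parcel_id)
    W
  })
}

#' Generate a spatially autocorrelated nodal map
#'
#' Draws from a Gaussian process over parcel centroids with an exponential
#' kernel on great-circle distance (correlation length `smoothness_length`
#' in radians; 0 gives spatially independent values). When `anchor_map` is
#' given, the draw is mixed with the gaussianized ranks of the anchor so the
#' realized Spearman correlation targets `anchor_rho` (the mixing weight
#' uses the bivariate-normal identity rho_pearson = 2 sin(pi rho_s / 6)).
#'
#' @param atlas a `parcel_atlas`.
#' @param smoothness_length correlation length (radians of arc), >= 0;
#'   the default 0.3 rad keeps maps smooth while leaving enough effective
#'   degrees of freedom that moderate map correlations remain detectable
#'   under the spin null.
#' @param anchor_map optional nodal vector of length N.
#' @param anchor_rho target Spearman correlation with `anchor_map`,
#'   in \[-1, 1\].
#' @param seed integer seed.
#' @return named numeric vector of length N.
#' @export
make_receptor_map <- function(atlas, smoothness_length = 0.3,
                              anchor_map = NULL, anchor_rho = 0, seed = 1L) {
  assert_atlas(atlas)
  smoothness_length <- assert_scalar(smoothness_length, "smoothness_length", 0)
  if (abs(anchor_rho) > 1) stop_invalid("`anchor_rho` must be in [-1, 1]")
  n <- nrow(atlas)
  if (!is.null(anchor_map) && length(anchor_map) != n)
    stop_invalid("`anchor_map` must have one value per atlas parcel")

  g <- with_seed(seed, {
    if (smoothness_length == 0) {
      rnorm(n)
    } else {
      xyz <- atlas_centroids(atlas)
      u <- xyz / sqrt(rowSums(xyz^2))
      ang <- acos(pmin(1, pmax(-1, tcrossprod(u))))
      K <- exp(-ang / smoothness_length) + diag(1e-8, n)
      drop(crossprod(chol(K), rnorm(n)))
    }
  })
  if (!is.null(anchor_map)) {
    a <- qnorm((rank(anchor_map, ties.method = "average") - 0.5) / n)
    a <- a / sd(a)
    g <- (g - mean(g)) / sd(g)
    rho_p <- 2 * sin(pi * anchor_rho / 6)
    g <- rho_p * a + sqrt(1 - rho_p^2) * g
  }
  names(g) <- atlas$parcel_id
  g
}

#' Generate a complete synthetic cohort with planted group effects
#'
#' Builds an atlas (unless supplied), then per subject a regime-switching
#' BOLD run and a structural connectome. The VH-like (hallucinator) group
#' carries two planted effects: a stickier Segregated state
#' (`p_stay_segregated_vh`) and structural weakening of hub-incident edges
#' (`hub_scale_vh` < 1). Ground-truth per-window labels (majority of the
#' hidden timepoint labels in each window) are stored alongside each subject.
#'
#' @param atlas optional `parcel_atlas`; default `make_atlas(200, 32, 7)`.
#' @param n_per_group named counts for groups `VH`, `nonVH`, `control`.
#' @param n_timepoints,tr_seconds BOLD geometry.
#' @param window_len,step window geometry used for the stored true window
#'   labels.
#' @param p_stay baseline stay probabilities (both states, non-VH groups).
#' @param p_stay_segregated_vh Segregated stay probability in the VH group.
#' @param hub_fraction fraction of parcels designated structural hubs.
#' @param hub_scale_vh hub edge scaling in the VH group (1 = no weakening).
#' @param noise_sd observation noise SD passed to both regimes.
#' @param conditioning how each subject's hidden chain is conditioned (runs
#'   are redrawn up to `max_attempts` times; the conditional Markov law).
#'   `"switch"` (default) accepts runs where some window is at least
#'   `purity`-pure in each regime; at the default geometry this selects
#'   runs with a single regime switch near mid-run, the only realizations
#'   whose window-majority ground truth is unambiguous, and is the
#'   condition under which state recovery is assessed. `"both_states"`
#'   accepts any run where at least `min_windows_each` windows have each
#'   majority label; it leaves the stay-probability contrasts between
#'   groups intact and is the condition used for planted group-effect
#'   experiments. `"none"` disables conditioning.
#' @param purity window purity for `"switch"` (capped at the geometric
#'   feasibility limit (T-1)/2W).
#' @param min_windows_each window count for `"both_states"`.
#' @param max_attempts bound on redraws per subject.
#' @param seed integer master seed; per-subject seeds are derived from it and
#'   recorded, so regeneration is bit-identical.
#' @return a `synthetic_cohort` list: `atlas`, `subjects` (each with
#'   `subject_id`, `group`, `bold`, `sc`, `true_window_labels`), `planted`.
#' @export
make_cohort <- function(atlas = NULL,
                        n_per_group = c(VH = 12, nonVH = 12, control = 0),
                        n_timepoints = 101L, tr_seconds = 0.7,
                        window_len = 63L, step = 1L,
                        p_stay = c(Integrated = 0.98, Segregated = 0.98),
                        p_stay_segregated_vh = 0.995,
                        hub_fraction = 0.15, hub_scale_vh = 0.6,
                        noise_sd = 0.2,
                        conditioning = c("switch", "both_states", "none"),
                        purity = 0.78, min_windows_each = 6L,
                        max_attempts = 2000L, seed = 1L) {
  conditioning <- match.arg(conditioning)
  if (is.null(atlas)) atlas <- make_atlas(200, 32, 7, seed = seed)
  assert_atlas(atlas)
  window_len <- assert_count(window_len, "window_len")
  n_timepoints <- assert_count(n_timepoints, "n_timepoints", min = window_len)

  regimes <- default_regimes(atlas, noise_sd = noise_sd)
  integ <- regimes$integrated
  seg <- regimes$segregated

  # hubs: highest-rank parcels spread over networks, deterministic given seed
  n_hubs <- max(1L, round(hub_fraction * nrow(atlas)))
  hub_nodes <- with_seed(derive_seed(seed, 0L),
                         sample(atlas$parcel_id, n_hubs))

  groups <- rep(names(n_per_group), times = n_per_group)
  subjects <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    grp <- groups[k]
    sseed <- derive_seed(seed, k)
    ps <- p_stay
    if (grp == "VH") ps[["Segregated"]] <- p_stay_segregated_vh
    ranges <- sliding_windows(n_timepoints, window_len, step)
    # a single switch can reach window purity at most (T-1)/(2W); cap the
    # requested purity at the feasible level for this geometry
    purity_eff <- min(purity, (n_timepoints - 1) / (2 * window_len) - 0.005)
    if (purity_eff <= 0.5) purity_eff <- 0
    accept <- switch(conditioning,
      none = function(f) TRUE,
      switch = function(f) purity_eff == 0 ||
        (max(f) >= purity_eff && min(f) <= 1 - purity_eff),
      both_states = function(f) sum(f > 0.5) >= min_windows_each &&
        sum(f < 0.5) >= min_windows_each)
    # prescan the cheap hidden-chain draw; only the accepted seed gets the
    # full multivariate simulation
    frac_i <- NULL
    for (attempt in 0:max(0L, max_attempts - 1L)) {
      lab <- with_seed(sseed + 10000L * attempt,
                       markov_labels(ps, n_timepoints))
      frac_i <- vapply(seq_len(nrow(ranges)), function(w)
        mean(lab[ranges[w, 1]:ranges[w, 2]] == "Integrated"), numeric(1))
      if (accept(frac_i)) break
      if (attempt == max_attempts - 1L)
        warning(sprintf(
          "subject %d: both regimes not clearly expressed after %d draws",
          k, max_attempts), call. = FALSE)
    }
    bold <- simulate_bold(atlas, integ, seg, p_stay = ps,
                          n_timepoints = n_timepoints,
                          tr_seconds = tr_seconds,
                          seed = sseed + 10000L * attempt)
    sc <- make_structural_connectome(
      atlas, hub_nodes = hub_nodes,
      hub_scale = if (grp == "VH") hub_scale_vh else 1,
      seed = sseed + 1L)
    twl <- ifelse(frac_i > 0.5, "Integrated", "Segregated")
    subjects[[k]] <- list(subject_id = sprintf("sub-%03d", k), group = grp,
                          bold = bold, sc = sc, true_window_labels = twl)
  }
  structure(list(
    atlas = atlas, subjects = subjects,
    planted = list(hub_nodes = hub_nodes, hub_scale_vh = hub_scale_vh,
                   p_stay = p_stay, p_stay_segregated_vh = p_stay_segregated_vh,
                   window_len = window_len, step = step, seed = as.integer(seed))),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects (%s), %d parcels, %d timepoints\n",
              length(x$subjects),
              paste(names(table(vapply(x$subjects, `[[`, "", "group"))),
                    table(vapply(x$subjects, `[[`, "", "group")),
                    sep = "=", collapse = ", "),
              nrow(x$atlas), nrow(x$subjects[[1]]$bold$values)))
  invisible(x)
}
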