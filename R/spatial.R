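#' Spin permutations of a parcel atlas
#'
#' For each permutation a uniform random 3-D rotation is drawn; it is
#' applied to the left-hemisphere cortical centroids and its x-mirrored
#' counterpart to the right hemisphere, and each cortical parcel is
#' reassigned to the nearest rotated parcel of the same hemisphere
#' (duplicates permitted, the canonical formulation). Subcortical parcels
#' cannot be rotated on the cortical sphere and are uniformly permuted among
#' themselves.
#'
#' @param atlas a `parcel_atlas` with cortical centroids on the unit sphere.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return n_perm x N integer matrix; row k reassigns parcel `i` the value
#'   of parcel `perm[k, i]`.
#' @export
spin_permutation <- function(atlas, n_perm, seed = 1L) {
  assert_atlas(atlas)
  n_perm <- assert_count(n_perm, "n_perm")
  cort <- which(atlas$is_cortical)
  if (!length(cort)) stop_invalid("atlas has no cortical parcels to spin")
  sub <- which(!atlas$is_cortical)
  xyz <- atlas_centroids(atlas)
  left <- which(atlas$is_cortical & atlas$hemisphere == "L")
  right <- which(atlas$is_cortical & atlas$hemisphere == "R")
  mirror <- diag(c(-1, 1, 1))

  P <- matrix(seq_len(nrow(atlas)), n_perm, nrow(atlas), byrow = TRUE)
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      R <- random_rotation()
      for (h in list(list(idx = left, rot = R),
                     list(idx = right, rot = mirror %*% R %*% mirror))) {
        if (!length(h$idx)) next
        rot_xyz <- xyz[h$idx, , drop = FALSE] %*% t(h$rot)
        # cosine similarity: nearest rotated parcel to each original centroid
        sim <- xyz[h$idx, , drop = FALSE] %*% t(rot_xyz)
        P[k, h$idx] <- h$idx[max.col(sim, ties.method = "first")]
      }
      if (length(sub) > 1L) P[k, sub] <- sub[sample.int(length(sub))]
    }
  })
  P
}

# Haar-uniform rotation from the QR decomposition of a Gaussian matrix,
# sign-corrected and constrained to det +1.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Spin permutation test for the correlation of two nodal maps
#'
#' Empirical Spearman correlation between `map_x` and `map_y`, against the
#' null distribution obtained by recomputing the correlation with `map_y`
#' spatially reassigned by each spin permutation. The default p-value is
#' two-sided on the magnitude, p = (1 + #\{|null| >= |rho|\}) / (1 + n_perm).
#'
#' @param map_x,map_y nodal vectors of length N (atlas order).
#' @param atlas a `parcel_atlas`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"` (one-sided on
#'   null >= empirical).
#' @param perms optional precomputed [spin_permutation()] matrix.
#' @return a `spin_test_result`: `rho`, `null_rhos`, `p_spin`, `n_perm`,
#'   `seed`.
#' @export
spin_test <- function(map_x, map_y, atlas, n_perm = 1000L, seed = 1L,
                      alternative = c("two.sided", "greater"), perms = NULL) {
  assert_atlas(atlas)
  alternative <- match.arg(alternative)
  n <- nrow(atlas)
  if (length(map_x) != n || length(map_y) != n)
    stop_invalid("maps must have one value per atlas parcel")
  if (sd(map_x) == 0 || sd(map_y) == 0)
    stop_invalid("constant map: correlation undefined")
  if (is.null(perms)) perms <- spin_permutation(atlas, n_perm, seed)
  n_perm <- nrow(perms)

  rx <- rank(map_x); ry <- rank(map_y)
  rho <- cor(rx, ry)
  null_rhos <- vapply(seq_len(n_perm), function(k)
    cor(rx, rank(map_y[perms[k, ]])), numeric(1))
  p_spin <- if (alternative == "two.sided")
    (1 + sum(abs(null_rhos) >= abs(rho))) / (1 + n_perm)
  else
    (1 + sum(null_rhos >= rho)) / (1 + n_perm)
  structure(list(rho = rho, null_rhos = null_rhos, p_spin = p_spin,
                 n_perm = n_perm, seed = as.integer(seed),
                 alternative = alternative),
            class = "spin_test_result")
}

#' @export
print.spin_test_result <- function(x, ...) {
  cat(sprintf("spin_test_result: rho = %.3f, p_spin = %.4g (%d permutations)\n",
              x$rho, x$p_spin, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values (delegates to `stats::p.adjust`).
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @return q-values, same length, capped at 1.
#' @export
fdr_bh <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_invalid("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Screen a family of nodal maps against an energy map
#'
#' Spin test of each map in the family against the energy map (all tests
#' share one permutation set for the atlas, so results are deterministic in
#' the seed and invariant to family order), with BH-FDR across the family.
#' Distinct families (e.g. PET receptor densities vs gene expression) should
#' be screened in separate calls so each is corrected on its own.
#'
#' @param energy_map nodal vector (e.g. nodal transition energy).
#' @param maps named list of nodal vectors, or an N x M matrix with column
#'   names.
#' @param atlas a `parcel_atlas`.
#' @param n_perm,seed permutation parameters.
#' @return data frame (map, rho, p_spin, q_spin) sorted by q then p.
#' @export
map_family_screen <- function(energy_map, maps, atlas, n_perm = 1000L,
                              seed = 1L) {
  if (is.matrix(maps)) maps <- as.list(as.data.frame(maps))
  if (!length(maps)) stop_invalid("empty map family")
  if (is.null(names(maps)) || any(names(maps) == ""))
    names(maps) <- paste0("map", seq_along(maps))
  perms <- spin_permutation(atlas, n_perm, seed)
  tests <- lapply(maps, function(m)
    spin_test(energy_map, m, atlas, seed = seed, perms = perms))
  out <- data.frame(map = names(maps),
                    rho = vapply(tests, `[[`, numeric(1), "rho"),
                    p_spin = vapply(tests, `[[`, numeric(1), "p_spin"),
                    row.names = NULL)
  out$q_spin <- fdr_bh(out$p_spin)
  out[order(out$q_spin, out$p_spin), , drop = FALSE]
}
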