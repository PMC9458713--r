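#' Build a synthetic parcel atlas on the unit sphere
#'
#' Constructs a parcellation with `n_cortical` cortical parcels split evenly
#' into a left and a mirrored right hemisphere, plus `n_subcortical`
#' subcortical parcels. Cortical centroids are laid out by a deterministic
#' Fibonacci-spiral construction on the left half of the unit sphere
#' (`x < 0`), and the right hemisphere is the exact mirror image with `x`
#' negated, which is what the mirrored spin rotation downstream relies on.
#' Cortical networks are assigned as contiguous blocks along the spiral
#' within each hemisphere, so networks are spatially coherent; each network
#' carries an ordinal hierarchy rank (1 = most unimodal, `n_networks` = most
#' transmodal). Subcortical parcels sit on an interior shell (radius 0.3) and
#' are labelled `"Subcortical"` with no hierarchy rank.
#'
#' @param n_cortical number of cortical parcels (split across hemispheres).
#' @param n_subcortical number of subcortical parcels.
#' @param n_networks number of cortical networks; must not exceed the number
#'   of cortical parcels per hemisphere.
#' @param seed integer seed, recorded for provenance (the construction itself
#'   is deterministic).
#' @return A `parcel_atlas` data frame with columns `parcel_id`, `name`,
#'   `hemisphere` (`"L"`, `"R"` or `NA`), `network`, `network_rank`,
#'   `is_cortical`, `x`, `y`, `z`.
#' @examples
#' atl <- make_atlas(200, 32, 7, seed = 1)
#' nrow(atl)                     # 232
#' table(atl$network)
#' @export
make_atlas <- function(n_cortical, n_subcortical = 0L, n_networks = 7L, seed = 1L) {
  n_cortical <- assert_count(n_cortical, "n_cortical", min = 1L)
  n_subcortical <- assert_count(n_subcortical, "n_subcortical", min = 0L)
  n_networks <- assert_count(n_networks, "n_networks", min = 1L)
  if (n_cortical < n_networks)
    stop_invalid("`n_cortical` must be >= `n_networks`")

  n_left <- ceiling(n_cortical / 2)
  n_right <- n_cortical - n_left
  left <- fibonacci_hemisphere(n_left)
  right <- left[seq_len(n_right), , drop = FALSE]
  right[, 1] <- -right[, 1]                      # mirror x
  xyz <- rbind(left, right)
  hemi <- c(rep("L", n_left), rep("R", n_right))

  net_names <- cortical_network_names(n_networks)
  nets_left <- net_names[block_assign(n_left, n_networks)]
  nets_right <- net_names[block_assign(n_right, n_networks)]
  network <- c(nets_left, nets_right)
  rank <- match(network, net_names)

  if (n_subcortical > 0) {
    sub_xyz <- 0.3 * fibonacci_sphere(n_subcortical)
    xyz <- rbind(xyz, sub_xyz)
    hemi <- c(hemi, rep(NA_character_, n_subcortical))
    network <- c(network, rep("Subcortical", n_subcortical))
    rank <- c(rank, rep(NA_integer_, n_subcortical))
  }

  n <- n_cortical + n_subcortical
  if (n < 8) stop_invalid("atlas must have at least 8 parcels")
  id <- sprintf("P%03d", seq_len(n))
  atlas <- data.frame(
    parcel_id = id,
    name = paste0(ifelse(is.na(hemi), "SUB", hemi), "_", network, "_", id),
    hemisphere = hemi,
    network = network,
    network_rank = rank,
    is_cortical = c(rep(TRUE, n_cortical), rep(FALSE, n_subcortical)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  attr(atlas, "seed") <- as.integer(seed)
  class(atlas) <- c("parcel_atlas", "data.frame")
  atlas
}

# Quasi-uniform points on the left half (x < 0) of the unit sphere:
# polar angle from an equal-area stratification, azimuth from the golden-angle
# spiral folded into (pi/2, 3*pi/2).
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- (1 + sqrt(5)) / 2
  phi <- pi / 2 + pi * ((i * golden) %% 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- (1 + sqrt(5)) / 2
  phi <- 2 * pi * ((i * golden) %% 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

block_assign <- function(n, k) {
  sizes <- diff(round(seq(0, n, length.out = k + 1)))
  rep(seq_len(k), times = sizes)
}

# Canonical resting-state network names ordered unimodal -> transmodal.
cortical_network_names <- function(k) {
  yeo <- c("Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
           "Limbic", "Frontoparietal", "DefaultMode")
  if (k <= length(yeo)) yeo[seq_len(k)] else c(yeo, paste0("Net", seq_len(k - length(yeo)) + 7L))
}

assert_atlas <- function(atlas) {
  need <- c("parcel_id", "hemisphere", "network", "network_rank",
            "is_cortical", "x", "y", "z")
  if (!is.data.frame(atlas) || !all(need %in% names(atlas)))
    stop_invalid("`atlas` must be a parcel_atlas data frame (see make_atlas)")
  if (anyDuplicated(atlas$parcel_id))
    stop_invalid("atlas parcel_id values must be unique")
  invisible(atlas)
}

atlas_centroids <- function(atlas) {
  m <- as.matrix(atlas[, c("x", "y", "z")])
  rownames(m) <- atlas$parcel_id
  m
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat(sprintf("parcel_atlas: %d parcels (%d cortical, %d subcortical), %d cortical networks\n",
              nrow(x), sum(x$is_cortical), sum(!x$is_cortical),
              length(unique(x$network[x$is_cortical]))))
  invisible(x)
}

#' Read/write a parcel atlas as TSV
#'
#' @param atlas a `parcel_atlas`.
#' @param path file path.
#' @return `read_atlas` returns a `parcel_atlas`; `write_atlas` returns
#'   `path` invisibly.
#' @export
write_atlas <- function(atlas, path) {
  assert_atlas(atlas)
  write.table(as.data.frame(atlas), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  atlas <- read.delim(path, stringsAsFactors = FALSE)
  atlas$hemisphere <- as.character(atlas$hemisphere)
  assert_atlas(atlas)
  class(atlas) <- c("parcel_atlas", "data.frame")
  atlas
}
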