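# Internal argument checks shared across modules.

stop_invalid <- function(...) stop(..., call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != round(x) || x < min)
    stop_invalid(sprintf("`%s` must be a single integer >= %d (got %s)",
                         name, min, paste(format(x), collapse = ",")))
  as.integer(x)
}

assert_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < lo || x > hi)
    stop_invalid(sprintf("`%s` must be a single finite number in [%s, %s]",
                         name, format(lo), format(hi)))
  as.numeric(x)
}

assert_square <- function(W, name = "W") {
  if (!is.matrix(W) || nrow(W) != ncol(W) || !is.numeric(W))
    stop_invalid(sprintf("`%s` must be a square numeric matrix", name))
  if (any(!is.finite(W)))
    stop_invalid(sprintf("`%s` contains non-finite entries", name))
  invisible(W)
}

assert_symmetric <- function(W, name = "W", tol = 1e-9) {
  assert_square(W, name)
  d <- max(abs(W - t(W)))
  if (d > tol)
    stop_invalid(sprintf("`%s` is not symmetric (max |W - t(W)| = %.3g > %.3g)",
                         name, d, tol))
  invisible(W)
}

# Set seed locally without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Cheap deterministic sub-seed derivation (stays well below 2^31).
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7L + 13L
}

upper_tri_values <- function(W) W[upper.tri(W)]
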