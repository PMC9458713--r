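#' Sliding-window index ranges
#'
#' Enumerates the windows of `window_len` timepoints advancing by `step`
#' over a series of length `n_timepoints`. With step 1 this yields
#' `T - window_len + 1` windows.
#'
#' @param n_timepoints series length T.
#' @param window_len window length in TRs.
#' @param step window advance in TRs.
#' @return integer matrix with columns `start`, `end` (1-based, inclusive).
#' @examples
#' nrow(sliding_windows(101, 63))  # 39
#' @export
sliding_windows <- function(n_timepoints, window_len, step = 1L) {
  n_timepoints <- assert_count(n_timepoints, "n_timepoints")
  window_len <- assert_count(window_len, "window_len")
  step <- assert_count(step, "step")
  if (window_len > n_timepoints)
    stop_invalid(sprintf("window_len (%d) exceeds series length (%d)",
                         window_len, n_timepoints))
  starts <- seq.int(1L, n_timepoints - window_len + 1L, by = step)
  cbind(start = starts, end = starts + window_len - 1L)
}

#' Windowed functional connectivity matrix
#'
#' Pairwise Pearson correlation of the parcel timeseries restricted to one
#' window; the diagonal is zeroed so strength sums never include self-edges.
#' A parcel that is constant within the window has undefined correlations;
#' its edges are set to 0 and a warning is emitted.
#'
#' @param values T x N numeric matrix.
#' @param start,end window bounds (1-based, inclusive).
#' @return N x N symmetric zero-diagonal matrix, entries in \[-1, 1\].
#' @export
window_fc <- function(values, start, end) {
  if (start < 1 || end > nrow(values) || start > end)
    stop_invalid("window range outside the timeseries")
  X <- values[start:end, , drop = FALSE]
  sds <- apply(X, 2, sd)
  flat <- sds == 0 | !is.finite(sds)
  W <- suppressWarnings(cor(X))
  if (any(flat)) {
    warning(sprintf("%d parcel(s) constant within window [%d,%d]; edges set to 0",
                    sum(flat), start, end), call. = FALSE)
    W[flat, ] <- 0
    W[, flat] <- 0
  }
  W[!is.finite(W)] <- 0
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

#' Dynamic functional connectivity series
#'
#' Applies [window_fc()] to every sliding window of a BOLD run.
#'
#' @param bold a `bold_ts` (see [simulate_bold()]) or a plain T x N matrix.
#' @param window_len,step window geometry in TRs.
#' @param tr_seconds repetition time; taken from `bold` when available.
#' @return a `dynamic_fc` list: `windows` (list of FC matrices), `ranges`,
#'   `window_len`, `step`, `tr_seconds`, `window_seconds`.
#' @export
dynamic_fc <- function(bold, window_len, step = 1L, tr_seconds = NULL) {
  if (inherits(bold, "bold_ts")) {
    values <- bold$values
    if (is.null(tr_seconds)) tr_seconds <- bold$tr_seconds
  } else {
    values <- as.matrix(bold)
    if (is.null(tr_seconds)) tr_seconds <- NA_real_
  }
  if (any(!is.finite(values)))
    stop_invalid("BOLD values contain non-finite entries")
  ranges <- sliding_windows(nrow(values), window_len, step)
  windows <- lapply(seq_len(nrow(ranges)), function(k)
    window_fc(values, ranges[k, 1], ranges[k, 2]))
  structure(list(windows = windows, ranges = ranges,
                 window_len = as.integer(window_len), step = as.integer(step),
                 tr_seconds = tr_seconds,
                 window_seconds = window_len * tr_seconds),
            class = "dynamic_fc")
}

#' @export
print.dynamic_fc <- function(x, ...) {
  cat(sprintf("dynamic_fc: %d windows of %d TRs (step %d), %d parcels\n",
              length(x$windows), x$window_len, x$step, nrow(x$windows[[1]])))
  invisible(x)
}
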