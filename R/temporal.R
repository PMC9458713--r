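#' Fraction of time spent in each state
#'
#' Count of windows carrying each label divided by the number of windows.
#'
#' @param labels character vector of `"Integrated"`/`"Segregated"` labels.
#' @return named numeric vector `c(Integrated=, Segregated=)` summing to 1.
#' @export
fraction_time <- function(labels) {
  labels <- check_labels(labels)
  tab <- table(factor(labels, c("Integrated", "Segregated")))
  c(tab / length(labels))
}

#' Mean dwell time per state
#'
#' Mean length of the maximal runs of consecutive windows in each state, in
#' windows. A state that never occurs gets dwell 0 and is flagged in the
#' `absent` attribute (so group summaries never silently drop subjects).
#'
#' @inheritParams fraction_time
#' @return named numeric vector with attribute `absent` (named logical).
#' @export
dwell_times <- function(labels) {
  labels <- check_labels(labels)
  r <- rle(labels)
  out <- c(Integrated = 0, Segregated = 0)
  absent <- c(Integrated = TRUE, Segregated = TRUE)
  for (s in names(out)) {
    runs <- r$lengths[r$values == s]
    if (length(runs)) { out[s] <- mean(runs); absent[s] <- FALSE }
  }
  attr(out, "absent") <- absent
  out
}

#' Count state transitions
#'
#' Adjacent-pair label changes, split by direction.
#'
#' @inheritParams fraction_time
#' @return named integer vector `c(total=, is=, si=)` where `is` counts
#'   Integrated-to-Segregated switches and `si` the reverse.
#' @export
transitions <- function(labels) {
  labels <- check_labels(labels)
  if (length(labels) == 1L) return(c(total = 0L, is = 0L, si = 0L))
  a <- labels[-length(labels)]
  b <- labels[-1L]
  is_ <- sum(a == "Integrated" & b == "Segregated")
  si_ <- sum(a == "Segregated" & b == "Integrated")
  c(total = is_ + si_, is = is_, si = si_)
}

#' All temporal metrics for one label sequence
#'
#' @inheritParams fraction_time
#' @return one-row data frame: `fraction_integrated`, `dwell_integrated`,
#'   `dwell_segregated`, `n_transitions`, `n_is`, `n_si`, plus absent flags.
#' @export
temporal_metrics <- function(labels) {
  f <- fraction_time(labels)
  d <- dwell_times(labels)
  tr <- transitions(labels)
  data.frame(fraction_integrated = unname(f["Integrated"]),
             dwell_integrated = unname(d["Integrated"]),
             dwell_segregated = unname(d["Segregated"]),
             integrated_absent = unname(attr(d, "absent")["Integrated"]),
             segregated_absent = unname(attr(d, "absent")["Segregated"]),
             n_transitions = unname(tr["total"]),
             n_is = unname(tr["is"]),
             n_si = unname(tr["si"]))
}

check_labels <- function(labels) {
  if (inherits(labels, "state_assignment")) labels <- labels$labels
  labels <- as.character(labels)
  if (!length(labels)) stop_invalid("label sequence is empty")
  bad <- setdiff(unique(labels), c("Integrated", "Segregated"))
  if (length(bad))
    stop_invalid("unknown state labels: ", paste(bad, collapse = ", "))
  labels
}
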