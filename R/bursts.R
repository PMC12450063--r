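#' Detect bursts by an interspike-interval ceiling
#'
#' Partitions a spike train into bursts: a gap strictly greater than the
#' ceiling closes the current group (a gap exactly equal to the ceiling keeps
#' the group open). Groups of at least two spikes become bursts; singletons
#' are returned separately as tonic spikes. The intraburst firing rate is
#' (n_spikes - 1) / duration.
#'
#' @param train a [spike_train()] (or a numeric vector of sorted spike times).
#' @param isi_ceiling_s ISI ceiling in seconds; see [isi_ceiling()].
#' @return A list with `bursts`, a data frame with columns `neuron`, `onset`,
#'   `offset`, `n_spikes`, `duration`, `rate_hz`, and `tonic`, the numeric
#'   vector of spike times not assigned to any burst.
#' @export
#' @examples
#' tr <- spike_train("LG", c(0, 0.1, 0.2, 3.0, 3.1, 3.2), 0, 10)
#' detect_bursts(tr, 2.0)$bursts
detect_bursts <- function(train, isi_ceiling_s) {
  stopifnot(isi_ceiling_s > 0)
  if (is.numeric(train)) train <- spike_train("IC", train,
                                              min(c(train, 0)),
                                              max(c(train, 1)) + 1)
  ts <- train$times
  empty <- data.frame(neuron = character(), onset = numeric(),
                      offset = numeric(), n_spikes = integer(),
                      duration = numeric(), rate_hz = numeric())
  if (length(ts) == 0L) return(list(bursts = empty, tonic = numeric(0)))
  # group id increments after every gap exceeding the ceiling
  grp <- cumsum(c(1, diff(ts) > isi_ceiling_s))
  size <- tabulate(grp)
  keep <- size[grp] >= 2L
  tonic <- ts[!keep]
  if (!any(keep)) return(list(bursts = empty, tonic = tonic))
  gs <- split(ts[keep], grp[keep])
  onset <- vapply(gs, function(g) g[1L], numeric(1))
  offset <- vapply(gs, function(g) g[length(g)], numeric(1))
  n <- vapply(gs, length, integer(1))
  dur <- offset - onset
  if (any(dur <= 0)) stop("coincident spikes produce a zero-duration burst")
  bursts <- data.frame(neuron = train$neuron, onset = unname(onset),
                       offset = unname(offset), n_spikes = unname(n),
                       duration = unname(dur),
                       rate_hz = unname((n - 1) / dur))
  bursts <- bursts[order(bursts$onset), , drop = FALSE]
  rownames(bursts) <- NULL
  list(bursts = bursts, tonic = tonic)
}

#' Intraburst firing rate
#'
#' The number of action potentials in a burst minus one, divided by the burst
#' duration (onset of first to onset of last spike).
#'
#' @param n_spikes spike count, at least 2.
#' @param duration burst duration in seconds, positive.
#' @return Firing rate in Hz.
#' @export
burst_rate <- function(n_spikes, duration) {
  stopifnot(all(n_spikes >= 2), all(duration > 0))
  (n_spikes - 1) / duration
}

#' Assign bursts to a window by onset
#'
#' A burst belongs to the window containing its onset (onset-owns rule), so a
#' burst truncated by a segment boundary is counted in exactly one segment.
#'
#' @param bursts a burst data frame from [detect_bursts()].
#' @param window a list/one-row data frame with `start`, `stop`.
#' @return The subset of `bursts` whose onset lies in `[start, stop)`.
#' @export
bursts_in_window <- function(bursts, window) {
  keep <- bursts$onset >= window$start & bursts$onset < window$stop
  out <- bursts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
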