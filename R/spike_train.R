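#' Construct a spike train
#'
#' A spike train is one neuron's sorted spike times (seconds) over a recording
#' window. Times must be strictly increasing and lie inside
#' `[t_start, t_stop]`.
#'
#' @param neuron neuron label, one of the identified STG neurons.
#' @param times numeric vector of spike times, seconds.
#' @param t_start,t_stop recording window bounds, seconds.
#' @return An object of class `spike_train`.
#' @export
#' @examples
#' spike_train("PD", c(0.1, 0.2, 0.9), 0, 10)
spike_train <- function(neuron, times, t_start, t_stop) {
  neuron <- match.arg(neuron, STG_NEURONS)
  times <- as.numeric(times)
  stopifnot(is.numeric(t_start), is.numeric(t_stop))
  if (t_stop <= t_start) stop("t_stop must exceed t_start")
  if (length(times)) {
    if (any(diff(times) <= 0)) {
      bad <- which(diff(times) <= 0)[1L]
      stop(sprintf(
        "spike times for neuron %s not strictly increasing at t = %.6f",
        neuron, times[bad + 1L]))
    }
    if (times[1L] < t_start || times[length(times)] > t_stop)
      stop(sprintf("spike times for neuron %s fall outside [%g, %g]",
                   neuron, t_start, t_stop))
  }
  structure(list(neuron = neuron, times = times,
                 t_start = as.numeric(t_start), t_stop = as.numeric(t_stop)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes on [%g, %g] s\n",
              x$neuron, length(x$times), x$t_start, x$t_stop))
  invisible(x)
}

#' Construct a recording
#'
#' A recording bundles one experiment's spike trains with its manifest
#' metadata: subject, condition label, and the incubation window. The default
#' incubation duration is 900 s (a 15 min incubation).
#'
#' @param trains named list of [spike_train()] objects, one per neuron.
#' @param subject_id subject identifier.
#' @param condition condition label (free text, e.g. "1uM-UH").
#' @param incubation_start incubation onset, seconds.
#' @param incubation_duration incubation length, seconds (default 900).
#' @return An object of class `gm_recording`.
#' @export
gm_recording <- function(trains, subject_id = "subject",
                         condition = "unknown",
                         incubation_start = 0,
                         incubation_duration = 900) {
  stopifnot(is.list(trains))
  nms <- vapply(trains, function(tr) tr$neuron, character(1))
  if (anyDuplicated(nms)) stop("at most one train per neuron")
  names(trains) <- nms
  for (tr in trains) {
    if (!inherits(tr, "spike_train")) stop("trains must be spike_train objects")
    if (incubation_start < tr$t_start ||
        incubation_start + incubation_duration > tr$t_stop)
      stop(sprintf(
        "incubation window [%g, %g] not inside recording window of %s",
        incubation_start, incubation_start + incubation_duration, tr$neuron))
  }
  structure(list(subject_id = as.character(subject_id),
                 condition = as.character(condition),
                 incubation_start = as.numeric(incubation_start),
                 incubation_duration = as.numeric(incubation_duration),
                 trains = trains),
            class = "gm_recording")
}

#' @export
print.gm_recording <- function(x, ...) {
  cat(sprintf("<gm_recording> subject %s, condition %s\n",
              x$subject_id, x$condition))
  cat(sprintf("  incubation [%g, %g] s; %d train(s): %s\n",
              x$incubation_start,
              x$incubation_start + x$incubation_duration,
              length(x$trains), paste(names(x$trains), collapse = ", ")))
  invisible(x)
}

#' Read a recording from a spike CSV and a manifest
#'
#' The spike file has header `neuron,time_s`, one spike per row, times in
#' seconds. The manifest (YAML or JSON, chosen by extension) supplies
#' `subject_id`, `condition`, `incubation_start_s` and (optionally)
#' `incubation_duration_s`.
#'
#' @param spike_csv_path path to the spike CSV.
#' @param manifest_path path to the YAML/JSON manifest.
#' @return A [gm_recording()].
#' @export
read_recording <- function(spike_csv_path, manifest_path) {
  df <- utils::read.csv(spike_csv_path, stringsAsFactors = FALSE)
  if (!all(c("neuron", "time_s") %in% names(df)))
    stop("spike CSV must have columns neuron,time_s")
  man <- if (grepl("\\.ya?ml$", manifest_path, ignore.case = TRUE))
    yaml::read_yaml(manifest_path)
  else jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (k in c("subject_id", "condition", "incubation_start_s"))
    if (is.null(man[[k]])) stop(sprintf("manifest missing key '%s'", k))
  dur <- if (is.null(man$incubation_duration_s)) 900 else man$incubation_duration_s
  bad <- setdiff(unique(df$neuron), STG_NEURONS)
  if (length(bad))
    stop(sprintf("unknown neuron label(s): %s", paste(bad, collapse = ", ")))
  if (nrow(df) == 0L)
    message("spike CSV is empty; recording has zero trains")
  t0 <- man$incubation_start_s
  t_start <- min(c(df$time_s, t0))
  t_stop <- max(c(df$time_s, t0 + dur))
  trains <- lapply(split(df$time_s, df$neuron), function(ts) sort(ts))
  trains <- mapply(function(ts, nm) {
    if (anyDuplicated(ts)) {
      d <- ts[duplicated(ts)][1L]
      stop(sprintf("duplicate spike time for neuron %s at t = %.6f", nm, d))
    }
    spike_train(nm, ts, t_start, t_stop)
  }, trains, names(trains), SIMPLIFY = FALSE)
  gm_recording(trains, subject_id = man$subject_id, condition = man$condition,
               incubation_start = t0, incubation_duration = dur)
}

#' Write a recording to a spike CSV and a manifest
#'
#' Inverse of [read_recording()]; spike rows are ordered by neuron then time.
#'
#' @param rec a [gm_recording()].
#' @param spike_csv_path,manifest_path output paths (manifest written as JSON
#'   or YAML by extension).
#' @return Invisibly, the two paths.
#' @export
write_recording <- function(rec, spike_csv_path, manifest_path) {
  rows <- do.call(rbind, lapply(rec$trains, function(tr) {
    if (!length(tr$times)) return(NULL)
    data.frame(neuron = tr$neuron, time_s = tr$times)
  }))
  if (is.null(rows)) rows <- data.frame(neuron = character(), time_s = numeric())
  utils::write.csv(rows, spike_csv_path, row.names = FALSE, quote = FALSE)
  man <- list(subject_id = rec$subject_id, condition = rec$condition,
              incubation_start_s = rec$incubation_start,
              incubation_duration_s = rec$incubation_duration)
  if (grepl("\\.ya?ml$", manifest_path, ignore.case = TRUE))
    yaml::write_yaml(man, manifest_path)
  else jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(c(spike_csv_path, manifest_path))
}

#' Segment windows of an incubation
#'
#' Divides an incubation into nonoverlapping 200-s analysis windows, excluding
#' the first 60 s so the preparation reaches steady state. With the default
#' 900-s incubation this yields four segments spanning 800 of the remaining
#' 840 s (95%).
#'
#' @param rec a [gm_recording()], or a numeric incubation start (with
#'   `duration` supplied).
#' @param duration incubation duration, seconds; taken from `rec` when it is a
#'   recording.
#' @return A data frame with columns `index` (0-based), `start`, `stop`;
#'   windows are half-open `[start, stop)`.
#' @export
#' @examples
#' segment_windows(0, duration = 900)
segment_windows <- function(rec, duration = NULL) {
  if (inherits(rec, "gm_recording")) {
    start <- rec$incubation_start
    duration <- rec$incubation_duration
  } else {
    start <- as.numeric(rec)
    if (is.null(duration)) stop("duration required when rec is numeric")
  }
  seg_len <- 200
  lead_in <- 60
  n_full <- floor((duration - lead_in) / seg_len)
  if (n_full < 1)
    stop(sprintf("incubation of %g s too short for one %g-s segment", duration,
                 seg_len))
  if (n_full > 4L) n_full <- 4L
  if (n_full < 4L)
    warning(sprintf("incubation of %g s yields only %d segment(s)", duration,
                    n_full))
  idx <- seq_len(n_full) - 1L
  data.frame(index = idx,
             start = start + lead_in + seg_len * idx,
             stop = start + lead_in + seg_len * (idx + 1L))
}

#' Restrict a spike train to a window
#'
#' Keeps spikes with `start <= t < stop` (half-open, so a spike on a shared
#' boundary is counted in exactly one window).
#'
#' @param train a [spike_train()].
#' @param window a one-row data frame (or list) with `start` and `stop`.
#' @return A [spike_train()] over the window.
#' @export
slice_train <- function(train, window) {
  keep <- train$times >= window$start & train$times < window$stop
  spike_train(train$neuron, train$times[keep],
              t_start = window$start, t_stop = window$stop)
}

#' Write result tables
#'
#' Writes each data frame in `tables` as `<name>.csv` under `out_dir` with a
#' deterministic column order (as given), plus a `stats.json` summary when a
#' list element named `stats` is present (always written, possibly as an empty
#' mapping). Reals survive a round trip to 12 significant digits.
#'
#' @param tables named list; data frames become CSVs, the element `stats`
#'   (a list) becomes `stats.json`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the written paths.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  stats <- if (is.null(tables$stats)) structure(list(), names = character(0))
           else tables$stats
  for (nm in setdiff(names(tables), "stats")) {
    tab <- tables[[nm]]
    if (!is.data.frame(tab)) stop(sprintf("table '%s' is not a data frame", nm))
    p <- file.path(out_dir, paste0(nm, ".csv"))
    out <- tab
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 15)
    utils::write.csv(out, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats, p, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, p))
}
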