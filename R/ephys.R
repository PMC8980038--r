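#' Construct a spike train
#'
#' @param times spike times in seconds, strictly increasing, within
#'   `[0, duration]`.
#' @param duration epoch length in seconds (default 300).
#' @param id optional neuron identifier.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, duration = 300, id = NULL) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]")
  structure(list(times = times, duration = duration, id = id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train%s: %d spikes over %g s (%.2f Hz)\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "",
              length(x$times), x$duration, length(x$times) / x$duration))
  invisible(x)
}

#' Burst segmentation of a spike train (80/160 ms rule)
#'
#' Bursts of dopamine-neuron firing are discrete events: a burst opens when
#' two consecutive spikes fall within an inter-spike interval (ISI)
#' strictly shorter than `onset_isi` (80 ms), it extends while the next ISI
#' is at most `offset_isi` (160 ms), and it terminates at the first ISI
#' strictly longer than `offset_isi` (or at the end of the train). Scanning
#' is greedy left-to-right and resumes at the spike following the last
#' spike of a closed burst, so a burst's boundary spike cannot seed the
#' next burst. Spikes with ISIs in the 80-160 ms zone can extend an open
#' burst but never open one.
#'
#' @param train a [spike_train()] (or numeric vector of sorted times).
#' @param onset_isi burst-onset ISI threshold in seconds (default 0.080,
#'   exclusive).
#' @param offset_isi burst-termination ISI threshold in seconds (default
#'   0.160; ISIs <= this continue the burst, > this end it).
#' @return object of class `burst_segmentation`: data.frame with columns
#'   `first` and `last` (1-based spike indices, inclusive); every burst has
#'   at least 2 spikes.
#' @examples
#' seg <- detect_bursts(spike_train(c(0, 0.05, 0.10, 0.30, 1.00), 2))
#' seg$bursts          # one burst: spikes 1-3
#' @export
detect_bursts <- function(train, onset_isi = 0.080, offset_isi = 0.160) {
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (is.unsorted(t, strictly = TRUE)) stop("spike times must be sorted")
  n <- length(t)
  first <- integer(0); last <- integer(0)
  i <- 1L
  while (i < n) {
    if (t[i + 1L] - t[i] < onset_isi) {
      j <- i + 1L
      while (j < n && t[j + 1L] - t[j] <= offset_isi) j <- j + 1L
      first <- c(first, i); last <- c(last, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  structure(list(bursts = data.frame(first = first, last = last),
                 n_spikes = n,
                 onset_isi = onset_isi, offset_isi = offset_isi),
            class = "burst_segmentation")
}

#' @export
print.burst_segmentation <- function(x, ...) {
  cat(sprintf("burst_segmentation: %d burst(s) over %d spikes\n",
              nrow(x$bursts), x$n_spikes))
  invisible(x)
}

#' Logical burst membership per spike
#' @param seg a [detect_bursts()] segmentation.
#' @return logical vector, TRUE for spikes inside a burst.
#' @export
burst_membership <- function(seg) {
  stopifnot(inherits(seg, "burst_segmentation"))
  inb <- logical(seg$n_spikes)
  for (k in seq_len(nrow(seg$bursts)))
    inb[seg$bursts$first[k]:seg$bursts$last[k]] <- TRUE
  inb
}

#' Percentage of spikes within bursts (%SWB)
#'
#' Number of spikes inside bursts divided by the total number of spikes,
#' times 100. An empty train yields 0 (flagged with a message).
#'
#' @param train a [spike_train()] or numeric times.
#' @param seg segmentation from [detect_bursts()] on the same train;
#'   computed if missing.
#' @return percentage in [0, 100].
#' @export
percent_swb <- function(train, seg = NULL) {
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (length(t) == 0L) {
    message("empty spike train; %SWB set to 0")
    return(0)
  }
  if (is.null(seg)) seg <- detect_bursts(train)
  100 * sum(burst_membership(seg)) / length(t)
}

#' Firing rate and %SWB on overlapping windows
#'
#' Metrics are measured on successive windows of `window` seconds with
#' `overlap` seconds shared between consecutive windows (step =
#' `window - overlap`), over a total epoch of `epoch` seconds; defaults
#' (60 s windows, 45 s overlap, 300 s epoch) give 17 windows. Windows are
#' half-open `[start, start + window)`. The per-window %SWB uses the
#' global burst segmentation: a burst spanning a window edge contributes
#' only its in-window spikes. The summary across windows is the unweighted
#' mean.
#'
#' @param train a [spike_train()].
#' @param window window length in seconds (default 60).
#' @param overlap overlap between consecutive windows in seconds
#'   (default 45); must be < `window`.
#' @param epoch total analysed period in seconds (default 300).
#' @param onset_isi,offset_isi burst thresholds, passed to
#'   [detect_bursts()].
#' @return object of class `windowed_metrics`: list with `windows`
#'   (data.frame: `start`, `end`, `n_spikes`, `rate_hz`, `pct_swb`),
#'   `mean_rate_hz`, `mean_pct_swb`, `n_bursts`, `pct_swb_overall`.
#' @export
windowed_metrics <- function(train, window = 60, overlap = 45, epoch = 300,
                             onset_isi = 0.080, offset_isi = 0.160) {
  if (overlap >= window) stop("overlap must be smaller than window")
  if (window > epoch) stop("window must not exceed epoch")
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  seg <- detect_bursts(t, onset_isi, offset_isi)
  inb <- burst_membership(seg)
  if (length(t) == 0L) message("empty spike train; all windowed metrics 0")

  starts <- seq(0, epoch - window, by = window - overlap)
  rows <- lapply(starts, function(s) {
    inw <- t >= s & t < s + window
    nw <- sum(inw)
    data.frame(start = s, end = s + window, n_spikes = nw,
               rate_hz = nw / window,
               pct_swb = if (nw) 100 * sum(inb[inw]) / nw else 0)
  })
  win <- do.call(rbind, rows)
  structure(list(windows = win,
                 mean_rate_hz = mean(win$rate_hz),
                 mean_pct_swb = mean(win$pct_swb),
                 n_bursts = nrow(seg$bursts),
                 pct_swb_overall = if (length(t))
                   100 * sum(inb) / length(t) else 0),
            class = "windowed_metrics")
}

#' @export
print.windowed_metrics <- function(x, ...) {
  cat(sprintf("windowed_metrics: %d windows; mean rate %.2f Hz; mean %%SWB %.1f (overall %.1f); %d bursts\n",
              nrow(x$windows), x$mean_rate_hz, x$mean_pct_swb,
              x$pct_swb_overall, x$n_bursts))
  invisible(x)
}

#' Electrophysiological identification of dopamine neurons
#'
#' A recorded unit is classified as dopaminergic when all four criteria
#' hold: (i) a typical triphasic action potential with a marked negative
#' deflection; (ii) a long spike duration (> 2.0 ms); (iii) an action
#' potential width from start to negative trough > 1.1 ms; and (iv) a slow
#' firing rate (> 1 and < 10 Hz).
#'
#' @param triphasic_negative_deflection logical.
#' @param ap_duration_ms action potential duration (ms).
#' @param start_to_trough_ms width from start to negative trough (ms).
#' @param mean_rate_hz mean firing rate (Hz).
#' @return list with `is_dopamine` and a named logical `criteria` vector.
#' @examples
#' classify_dopamine(TRUE, 2.5, 1.3, 4)$is_dopamine   # TRUE
#' classify_dopamine(TRUE, 2.5, 1.3, 12)$is_dopamine  # FALSE (rate)
#' @export
classify_dopamine <- function(triphasic_negative_deflection, ap_duration_ms,
                              start_to_trough_ms, mean_rate_hz) {
  if (any(c(ap_duration_ms, start_to_trough_ms, mean_rate_hz) < 0))
    stop("waveform features and rate must be non-negative")
  criteria <- c(triphasic = isTRUE(triphasic_negative_deflection),
                duration = ap_duration_ms > 2.0,
                width = start_to_trough_ms > 1.1,
                rate = mean_rate_hz > 1 && mean_rate_hz < 10)
  list(is_dopamine = all(criteria), criteria = criteria)
}

#' Relative fluorescence change (dF/F)
#'
#' `(Ft - F0) / F0`, where `F0` and `Ft` are fluorescence intensities
#' before and after stimulation.
#'
#' @param F0 baseline fluorescence (> 0).
#' @param Ft post-stimulation fluorescence.
#' @return relative change (vectorised).
#' @examples
#' delta_f_over_f(100, 150)  # 0.5
#' @export
delta_f_over_f <- function(F0, Ft) {
  if (any(F0 <= 0)) stop("F0 must be positive")
  (Ft - F0) / F0
}

#' Read spike trains from a CSV of (neuron_id, time_s)
#'
#' @param path CSV with columns `neuron_id` and `time_s` (header required).
#' @param duration epoch length passed to [spike_train()].
#' @return named list of `spike_train` objects.
#' @export
read_spike_trains <- function(path, duration = 300) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("neuron_id", "time_s") %in% names(tab)))
    stop("CSV must have columns neuron_id, time_s")
  lapply(split(tab$time_s, tab$neuron_id), function(tt)
    spike_train(sort(tt), duration = duration))
}

#' Per-neuron burst metrics table
#'
#' @param trains list of [spike_train()] objects.
#' @param ... passed to [windowed_metrics()].
#' @return data.frame with one row per neuron: `neuron`, `n_spikes`,
#'   `rate_hz`, `n_bursts`, `pct_swb`, `mean_window_rate_hz`,
#'   `mean_window_pct_swb`.
#' @export
burst_metrics_table <- function(trains, ...) {
  rows <- lapply(seq_along(trains), function(i) {
    tr <- trains[[i]]
    wm <- windowed_metrics(tr, ...)
    data.frame(neuron = names(trains)[i] %||% as.character(i),
               n_spikes = length(tr$times),
               rate_hz = length(tr$times) / tr$duration,
               n_bursts = wm$n_bursts,
               pct_swb = wm$pct_swb_overall,
               mean_window_rate_hz = wm$mean_rate_hz,
               mean_window_pct_swb = wm$mean_pct_swb)
  })
  do.call(rbind, rows)
}
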