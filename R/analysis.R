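#' Instantaneous phase via the Hilbert transform
#'
#' Removes the mean, builds the analytic signal in the frequency domain
#' (zeroing negative frequencies) and returns its argument, the
#' instantaneous phase in `[-pi, pi)`.
#'
#' @param signal numeric time series of length >= 16.
#' @return numeric phase vector, same length, in `[-pi, pi)`.
#' @export
hilbert_phase <- function(signal) {
  n <- length(signal)
  if (n < 16L) stop("signal must have length >= 16")
  if (any(!is.finite(signal))) stop("signal must be finite")
  x <- signal - mean(signal)
  if (max(abs(x)) < 1e-12 * max(1, max(abs(signal))))
    stop("constant signal: phase undefined")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- fft(X * h, inverse = TRUE) / n
  p <- Arg(a)
  p[p >= pi] <- p[p >= pi] - 2 * pi
  p
}

#' Per-vertex phase series of a field recording
#'
#' Extracts the instantaneous phase of either the state signal `x2 - x1`
#' (the default source) or of the transmitted spike probability
#' (the rate-conversion output `lambda`) for each CA1 vertex.
#'
#' @param recording a `field_recording`.
#' @param vertices integer vertex ids (rows of the recording) to analyze.
#' @param source `"state"` (`x2 - x1`) or `"probability"` (transmitted
#'   `lambda` per Eqs. of the conversion layer).
#' @param conv a `conversion_params` (used for `source = "probability"`).
#' @return an object of class `phase_series`: list with `phase`
#'   (`n_samples` x `n_vertices`), `times`, `vertices`, `source`.
#' @export
phase_from_recording <- function(recording, vertices,
                                 source = c("state", "probability"),
                                 conv = conversion_params()) {
  source <- match.arg(source)
  stopifnot(inherits(recording, "field_recording"), length(vertices) >= 1)
  sig <- switch(source,
    state = recording$x2[vertices, , drop = FALSE] -
            recording$x1[vertices, , drop = FALSE],
    probability = {
      l1 <- rate_from_x1(recording$x1[vertices, , drop = FALSE], conv)
      l2 <- rate_from_x2(recording$x2[vertices, , drop = FALSE], conv)
      matrix(l1 + l2, nrow = length(vertices))
    })
  ph <- apply(sig, 1L, hilbert_phase)  # n_samples x n_vertices
  structure(list(phase = ph, times = recording$times,
                 vertices = as.integer(vertices), source = source),
            class = "phase_series")
}

#' Phase-locked spike histogram
#'
#' Bins every spike at the instantaneous phase of its vertex's signal at
#' the spike time (nearest recorded sample at or before the spike), builds
#' per-vertex histograms over `[-pi, pi)` (half-open, left-inclusive bins)
#' and averages them across vertices. Samples within the edge fraction at
#' either end of the recording are excluded from the statistics to avoid
#' Hilbert edge artifacts.
#'
#' @param phases a `phase_series` whose `vertices` cover the spike record's
#'   devices.
#' @param spikes a `spike_record` (its `counts` matrix is used: network
#'   spikes per step per device) or a plain counts matrix aligned to the
#'   phase series' vertices; the spike-record device order must equal
#'   `phases$vertices`.
#' @param n_bins number of phase bins (default 20).
#' @param edge_frac fraction of samples discarded at each end
#'   (default 0.05).
#' @param use `"counts"` (network spikes) or `"device_counts"` (bridge
#'   device spikes) when `spikes` is a `spike_record`.
#' @return an object of class `phase_lock_histogram`: list with `breaks`,
#'   `counts` (per-bin, summed over vertices), `per_vertex` (n_bins x
#'   n_vertices), `average` (mean across vertices of the per-vertex
#'   histograms), `vector_strength`, `n_spikes`, `spike_phases`.
#' @export
phase_locked_histogram <- function(phases, spikes, n_bins = 20L,
                                   edge_frac = 0.05,
                                   use = c("counts", "device_counts")) {
  use <- match.arg(use)
  stopifnot(inherits(phases, "phase_series"), n_bins >= 2)
  if (inherits(spikes, "spike_record")) {
    if (!identical(as.integer(spikes$device_order),
                   as.integer(phases$vertices)))
      stop("spike record device order does not match the phase series vertices")
    cnt <- spikes[[use]]
    spike_times <- seq_len(nrow(cnt)) * spikes$dt
  } else {
    cnt <- as.matrix(spikes)
    spike_times <- attr(spikes, "times")
    if (is.null(spike_times))
      stop("a plain counts matrix needs a 'times' attribute")
  }
  if (ncol(cnt) != length(phases$vertices))
    stop("vertex count mismatch between spikes and phases")
  t0 <- phases$times[1]
  tmax <- phases$times[length(phases$times)]
  tol <- if (length(phases$times) > 1)
    0.5 * (phases$times[2] - phases$times[1]) else 0
  if (any(cnt > 0 & (spike_times < t0 - tol | spike_times > tmax + tol)))
    stop("spike outside the time range of the phase signal")
  spike_times <- pmin(pmax(spike_times, t0), tmax)
  # nearest recorded sample at or before each spike step
  samp <- findInterval(spike_times, phases$times)
  ns <- length(phases$times)
  lo <- max(1L, ceiling(edge_frac * ns))
  hi <- min(ns, floor((1 - edge_frac) * ns))
  keep <- samp >= lo & samp <= hi

  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  per_vertex <- matrix(0, n_bins, ncol(cnt))
  all_phases <- vector("list", ncol(cnt))
  for (v in seq_len(ncol(cnt))) {
    k <- which(keep & cnt[, v] > 0)
    if (!length(k)) next
    ph <- rep(phases$phase[samp[k], v], times = cnt[k, v])
    all_phases[[v]] <- ph
    bin <- pmin(pmax(findInterval(ph, breaks, left.open = FALSE), 1L), n_bins)
    per_vertex[, v] <- tabulate(bin, nbins = n_bins)
  }
  sp <- unlist(all_phases, use.names = FALSE)
  vs <- if (length(sp)) vector_strength(sp) else NA_real_
  structure(list(
    breaks = breaks, counts = rowSums(per_vertex),
    per_vertex = per_vertex, average = rowMeans(per_vertex),
    vector_strength = vs, n_spikes = length(sp), spike_phases = sp
  ), class = "phase_lock_histogram")
}

#' @export
print.phase_lock_histogram <- function(x, ...) {
  cat("<phase_lock_histogram> ", x$n_spikes, " spikes, ",
      length(x$counts), " bins, vector strength ",
      signif(x$vector_strength, 4), "\n", sep = "")
  invisible(x)
}

#' Vector strength of a set of spike phases
#'
#' Magnitude of the mean unit phasor: 1 for perfect phase locking, about 0
#' for phases uniform on the circle.
#'
#' @param phases spike phases in radians (>= 1 value).
#' @return scalar in `[0, 1]`.
#' @export
vector_strength <- function(phases) {
  if (length(phases) == 0L) stop("vector strength of zero spikes is undefined")
  Mod(mean(exp(1i * phases)))
}

#' Seizure-onset latency map
#'
#' For each node, the time of the first detected upward crossing of
#' `threshold` by the seizure marker `x2 - x1` (see [detect_seizures()]
#' for the threshold and hysteresis conventions). Onset-zone nodes start
#' at the marker value 0, armed, and cross within the first spike-and-wave
#' complex, giving them minimal latency; nodes that never seize are `NA`.
#'
#' @param recording a `field_recording`.
#' @param threshold crossing level of `x2 - x1` (default 1).
#' @param hysteresis arming band (default 0.5).
#' @return named numeric vector of latencies (ms), `NA` where absent.
#' @export
onset_latency_map <- function(recording, threshold = 1, hysteresis = 0.5) {
  stopifnot(inherits(recording, "field_recording"))
  sig <- recording$x2 - recording$x1
  n <- nrow(sig)
  lat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    on <- detect_seizures(sig[i, ], recording$times, threshold, hysteresis)
    if (length(on)) lat[i] <- on[1]
  }
  names(lat) <- seq_len(n)
  lat
}

#' Detect recurrent seizure-like events in one signal
#'
#' Upward crossings of `threshold` by `x2 - x1` with hysteresis. The
#' interictal marker rests near +0.6 while ictal activity - autonomous
#' spike-and-wave cycles as well as recruitment ramps - exceeds 1.5, so
#' the default threshold of 1 separates the two without requiring any
#' preceding downswing. The detector is armed while the signal is at or
#' below `threshold`; it fires at the next sample above `threshold` and
#' re-arms only after the signal falls below `threshold - hysteresis`, so
#' a sustained suprathreshold excursion is counted once (one event per
#' spike-and-wave cycle; see [seizure_episodes()] for grouping cycles into
#' seizures).
#'
#' @param signal numeric `x2 - x1` series.
#' @param times sample times (ms).
#' @param threshold onset level (default 1).
#' @param hysteresis re-arming band (default 0.5).
#' @return numeric vector of onset times (ms); empty if no event.
#' @export
detect_seizures <- function(signal, times, threshold = 1, hysteresis = 0.5) {
  stopifnot(length(signal) == length(times), hysteresis >= 0)
  armed <- signal[1] <= threshold
  onsets <- numeric(0)
  for (k in seq_along(signal)) {
    if (armed && signal[k] > threshold) {
      onsets <- c(onsets, times[k])
      armed <- FALSE
    } else if (!armed && signal[k] < threshold - hysteresis) {
      armed <- TRUE
    }
  }
  onsets
}

#' Group event onsets into seizure episodes
#'
#' The hysteresis detector fires once per spike-and-wave cycle, so a single
#' ictal episode yields a train of closely spaced onsets. Onsets separated
#' by less than `gap` are merged into one episode (the slow permittivity
#' variable keeps inter-seizure silences far longer than the intra-seizure
#' cycle period, so any gap between those two scales works).
#'
#' @param onsets numeric onset times (ms) from [detect_seizures()].
#' @param gap minimum silence (ms) separating two episodes (default 2000).
#' @return numeric vector of episode start times (ms).
#' @export
seizure_episodes <- function(onsets, gap = 2000) {
  if (length(onsets) == 0L) return(numeric(0))
  onsets <- sort(onsets)
  starts <- onsets[c(TRUE, diff(onsets) > gap)]
  starts
}
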