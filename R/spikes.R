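# Stimulus generation, monitors that partition raw AER data by population,
# and rate/raster summaries.

#' Independent Poisson spike trains for a population
#'
#' Generates one homogeneous Poisson train per population unit and encodes
#' it physically: either on the units' soma (source) addresses, for use as
#' a replayed source stream, or on one of their synapse (destination)
#' addresses, for direct stimulation. Deterministic given the seed.
#'
#' @param pop a `population`.
#' @param rates_hz per-unit rate(s) in Hz (recycled to the population size).
#' @param duration_s train length in seconds.
#' @param seed RNG seed.
#' @param target `"soma"` or a synapse label of the population.
#' @return `event_stream` of board-level physical addresses.
#' @export
poisson_trains <- function(pop, rates_hz, duration_s, seed,
                           target = "soma") {
  rates_hz <- rep_len(as.numeric(rates_hz), length(pop))
  if (any(rates_hz < 0)) stop("rates must be >= 0")
  phys <- target_phys(pop, target)
  with_seed(seed, {
    times <- lapply(rates_hz, poisson_times, duration_s = duration_s)
    event_stream(rep(phys, lengths(times)), unlist(times))
  })
}

#' Regular (periodic) spike trains for a population
#'
#' Exact periodic spike times `phase + k / rate`, floor-quantised to
#' microseconds, for precisely timed stimulation.
#'
#' @param pop a `population`.
#' @param rate_hz spike rate (scalar, > 0).
#' @param duration_s train length in seconds.
#' @param phase_s per-unit phase offset(s) in seconds (recycled).
#' @param target `"soma"` or a synapse label.
#' @return `event_stream` of board-level physical addresses.
#' @export
regular_trains <- function(pop, rate_hz, duration_s, phase_s = 0,
                           target = "soma") {
  if (rate_hz <= 0) stop("rate must be > 0")
  phase_s <- rep_len(as.numeric(phase_s), length(pop))
  phys <- target_phys(pop, target)
  times <- lapply(phase_s, function(ph) {
    k <- seq(0, length.out = max(0, ceiling((duration_s - ph) * rate_hz)))
    t <- ph + k / rate_hz
    floor(t[t < duration_s & t >= 0] * 1e6)
  })
  event_stream(rep(phys, lengths(times)), unlist(times))
}

target_phys <- function(pop, target) {
  if (identical(target, "soma")) soma_phys(pop)
  else {
    g <- pop$synapses[[target]]
    if (is.null(g))
      stop(sprintf("population '%s' has no synapse label '%s'", pop$name,
                   target))
    # one synapse address per unit (the first, in enumeration order)
    phys <- synapse_phys(pop, target)
    phys[match(seq_len(length(pop)), attr(g, "unit"))]
  }
}

# ---- monitors --------------------------------------------------------------

#' Create a monitor for a population
#'
#' A monitor collects raw AER events belonging to its population's soma
#' addresses and keys them by unit (position in the population's ordered
#' soma group). Monitors are mutable collectors: [monitor_distribute()]
#' appends in place.
#'
#' @param pop a `population`.
#' @return an object of class `monitor`.
#' @export
monitor <- function(pop) {
  e <- new.env(parent = emptyenv())
  e$pop <- pop
  e$phys <- soma_phys(pop)
  e$spikes <- data.frame(unit = integer(0), timestamp_us = numeric(0))
  class(e) <- "monitor"
  e
}

#' @export
print.monitor <- function(x, ...) {
  cat(sprintf("<monitor of '%s'> %d collected spike(s) over %d unit(s)\n",
              x$pop$name, nrow(x$spikes), length(x$pop)))
  invisible(x)
}

#' Distribute raw AER data over population monitors
#'
#' Each event is assigned to every monitor whose population contains its
#' address (overlapping monitors double-count by design: a subpopulation
#' monitor is independent of its parent's). Events claimed by no monitor
#' are returned as the unclaimed stream, so for disjoint monitors
#' `claimed + unclaimed = total`.
#'
#' @param raw `event_stream` of board-level physical addresses.
#' @param monitors list of [monitor()] objects (updated in place).
#' @param ca the setup's [channel_addressing()] (reserved for future
#'   translated-form collection; matching is on physical addresses).
#' @return list with `unclaimed` (`event_stream`) and `n_claimed` (events
#'   claimed by at least one monitor).
#' @export
monitor_distribute <- function(raw, monitors, ca = NULL) {
  claimed <- rep(FALSE, nrow(raw))
  for (m in monitors) {
    i <- match(raw$address, m$phys)
    hit <- !is.na(i)
    if (any(hit)) {
      sp <- data.frame(unit = i[hit], timestamp_us = raw$timestamp_us[hit])
      sp <- sp[order(sp$timestamp_us, sp$unit), , drop = FALSE]
      rownames(sp) <- NULL
      m$spikes <- rbind(m$spikes, sp)
    }
    claimed <- claimed | hit
  }
  list(unclaimed = event_stream(raw$address[!claimed],
                                raw$timestamp_us[!claimed]),
       n_claimed = sum(claimed))
}

#' Population mean firing rate time series
#'
#' Bins a monitor's collected spikes and divides each bin's count by
#' (bin width x population size); the last, possibly partial, bin is
#' normalised by its actual width.
#'
#' @param mon a [monitor()].
#' @param bin_s bin width in seconds (> 0).
#' @param t_end_s end of the analysis window; defaults to the last spike.
#' @return data.frame with `time_s` (bin start) and `rate_hz`.
#' @export
firing_rate <- function(mon, bin_s, t_end_s = NULL) {
  if (bin_s <= 0) stop("bin width must be > 0")
  t <- mon$spikes$timestamp_us / 1e6
  if (is.null(t_end_s)) t_end_s <- if (length(t)) max(t) + 1e-6 else bin_s
  n_bins <- max(1L, ceiling(t_end_s / bin_s - 1e-9))
  starts <- (seq_len(n_bins) - 1L) * bin_s
  widths <- pmin(bin_s, t_end_s - starts)
  t <- t[t < t_end_s]
  counts <- if (length(t)) tabulate(floor(t / bin_s) + 1L,
                                    nbins = length(starts))
  else rep(0L, length(starts))
  data.frame(time_s = starts,
             rate_hz = counts / (widths * max(1L, length(mon$pop))))
}

# per-unit spike counts in fixed bins; used by experiment decoders
unit_bin_counts <- function(mon, bin_s, t_end_s) {
  n_bins <- ceiling(t_end_s / bin_s)
  m <- matrix(0L, nrow = length(mon$pop), ncol = n_bins)
  if (nrow(mon$spikes)) {
    b <- pmin(floor(mon$spikes$timestamp_us / 1e6 / bin_s) + 1L, n_bins)
    for (k in seq_along(b)) m[mon$spikes$unit[k], b[k]] <-
        m[mon$spikes$unit[k], b[k]] + 1L
  }
  m
}

#' Export / read a monitor raster as CSV
#'
#' Two-column CSV `unit,timestamp_us`; `unit` is the 1-based position in
#' the population's ordered soma group. Round trips are exact.
#'
#' @param mon a [monitor()].
#' @param file path.
#' @return [read_raster()] returns the raster data.frame.
#' @export
raster_export <- function(mon, file) {
  df <- data.frame(unit = mon$spikes$unit,
                   timestamp_us = format(mon$spikes$timestamp_us,
                                         scientific = FALSE, trim = TRUE))
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname raster_export
#' @export
read_raster <- function(file) {
  df <- read.csv(file, colClasses = c("integer", "numeric"))
  if (!identical(names(df), c("unit", "timestamp_us")))
    stop(sprintf("'%s': expected header 'unit,timestamp_us'", file))
  df
}
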