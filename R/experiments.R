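# End-to-end demo 1: selective amplification and tracking. The virtual
# retina watches two bars of different size sliding horizontally; each
# group of pixel columns projects onto one excitatory neuron of the sWTA
# chip, which selects and tracks the position of the larger (stronger)
# stimulus.

#' Two-bar sliding stimulus for the virtual retina
#'
#' Renders two bright vertical bars of different length translating
#' horizontally in opposite directions over a dark background, and returns
#' the ground-truth x-trajectory of the longer bar for scoring. The bars
#' bounce (default) or wrap at the frame edges. Fully deterministic.
#'
#' @param frame `(rows, cols)` of the frames (default 64 x 64).
#' @param lengths vertical extents of the two bars in pixels (must differ).
#' @param y_pos top rows of the two bars.
#' @param x0 starting columns.
#' @param velocity per-frame horizontal velocities (opposite signs).
#' @param fps frame rate (Hz).
#' @param duration_s stimulus length in seconds.
#' @param width bar width in pixels.
#' @param boundary `"bounce"` or `"wrap"`.
#' @return list with `frames` (array rows x cols x n), `times_us`,
#'   `truth` (data.frame `frame`, `time_us`, `x` of the longer bar's left
#'   column) and the echoed geometry.
#' @export
make_bars_stimulus <- function(frame = c(64, 64), lengths = c(20, 6),
                               y_pos = c(10, 40), x0 = c(5, 58),
                               velocity = c(1, -1), fps = 100,
                               duration_s = 3, width = 1,
                               boundary = c("bounce", "wrap")) {
  boundary <- match.arg(boundary)
  nr <- frame[1]; nc <- frame[2]
  if (length(lengths) != 2 || lengths[1] == lengths[2])
    stop("exactly two bars of different lengths are required")
  if (any(y_pos + lengths - 1 >= nr) || any(y_pos < 0))
    stop("bars must fit vertically inside the frame")
  if (any(x0 < 0) || any(x0 + width - 1 >= nc))
    stop("bar start columns must lie inside the frame")
  n_frames <- max(2L, round(duration_s * fps))
  times_us <- floor((seq_len(n_frames) - 1) / fps * 1e6)

  span <- nc - width
  bar_x <- function(x_start, v, f) {
    p <- x_start + v * (f - 1)
    if (boundary == "wrap") p %% (span + 1)
    else {                                   # triangle-wave reflection
      m <- p %% (2 * span)
      ifelse(m > span, 2 * span - m, m)
    }
  }
  frames <- array(0, dim = c(nr, nc, n_frames))
  xs <- matrix(0L, nrow = n_frames, ncol = 2)
  for (f in seq_len(n_frames)) {
    img <- matrix(0, nr, nc)
    for (b in 1:2) {
      x <- as.integer(round(bar_x(x0[b], velocity[b], f)))
      xs[f, b] <- x
      img[y_pos[b] + seq_len(lengths[b]), x + seq_len(width)] <- 1
    }
    frames[, , f] <- img
  }
  long <- which.max(lengths)
  list(frames = frames, times_us = times_us,
       truth = data.frame(frame = seq_len(n_frames), time_us = times_us,
                          x = xs[, long]),
       frame = frame, lengths = lengths, y_pos = y_pos, x0 = x0,
       velocity = velocity, fps = fps, width = width, boundary = boundary)
}

#' Retina-to-sWTA tracking experiment
#'
#' Full pipeline: the bar stimulus is encoded by the virtual retina into
#' address events; a column-projection LUT routes every pixel of a column
#' group to the excitatory synapse of one sWTA neuron; the chip is
#' simulated through the batch run orchestration; the winner trajectory is
#' the per-time-bin argmax of the excitatory neurons' firing, compared
#' against the known position of the longer bar.
#'
#' @param stimulus a [make_bars_stimulus()] result.
#' @param columns_per_neuron pixel columns pooled per sWTA neuron (the
#'   retina width must be divisible by it).
#' @param bin_s decoding bin width in seconds.
#' @param seed RNG seed.
#' @param swta a [build_swta_chip()] virtual chip (default configuration).
#' @param input_weight,ei_weight,noise_sd chip biases set through the
#'   configurator before the run: the retina-input synapse weight scaled
#'   for the dense DVS burst drive, the excitatory-to-inhibitory weight
#'   raised so the few retina-driven neurons recruit the global
#'   inhibition, and a small membrane current noise so trials differ
#'   across seeds.
#' @return list with `trajectory` (data.frame `time_s`, `winner`, `truth`,
#'   `error`; indices are 0-based neuron positions, `winner` NA in silent
#'   bins), `median_error` (median over scorable bins), `monitored` raw
#'   events and the `neuro_setup` used.
#' @export
run_tracking <- function(stimulus = make_bars_stimulus(),
                         columns_per_neuron = 2, bin_s = 0.1, seed = 1L,
                         swta = build_swta_chip(), input_weight = 0.0033,
                         ei_weight = 0.8, noise_sd = 5) {
  setup <- demo_setup()
  nc <- stimulus$frame[2]
  if (nc %% columns_per_neuron != 0)
    stop(sprintf("%d retina columns are not divisible by columns_per_neuron = %d",
                 nc, columns_per_neuron))
  n_used <- nc / columns_per_neuron
  ns <- load_plugins(setup, options = list(chip_models = list(ifslwta = swta)))
  ca <- ns$ca
  set_parameter(ns, "ifslwta", "w_exc", input_weight)
  set_parameter(ns, "ifslwta", "w_ei", ei_weight)
  set_parameter(ns, "ifslwta", "noise_sd", noise_sd)

  retina <- setup$chips$retina
  ret_events <- dvs_encode(stimulus$frames, stimulus$times_us, chip = retina)
  ret_chan <- setup$channels[["retina"]]
  board <- event_stream(ret_events$address + ret_chan * 2^ca$channel_offset,
                        ret_events$timestamp_us)

  # column-projection LUT: every pixel -> excitatory synapse of its neuron
  grid <- expand.grid(x = 0:(nc - 1), y = 0:(stimulus$frame[1] - 1),
                      KEEP.OUT.ATTRS = FALSE)
  lut <- connection_lut(
    encode_address(ca, ret_chan, grid, "source"),
    encode_address(ca, setup$channels[["ifslwta"]],
                   data.frame(neuron = grid$x %/% columns_per_neuron,
                              synapse = 0L), "destination"),
    multiplicity = TRUE)                     # column pixels share a synapse

  duration_s <- (max(stimulus$times_us) + 1) / 1e6
  monitored <- setup_run(ns, lut, board, duration_s, seed = seed)

  p_wta <- populate_linear(setup$chips$ifslwta, ca, n_used,
                           blocks = "excitatory", name = "p_wta")
  mon <- monitor(p_wta)
  monitor_distribute(monitored, list(mon))
  counts <- unit_bin_counts(mon, bin_s, duration_s)
  winner <- apply(counts, 2, function(col)
    if (sum(col) == 0) NA_integer_ else which.max(col) - 1L)

  bin_starts <- (seq_len(ncol(counts)) - 1) * bin_s
  truth_idx <- vapply(bin_starts, function(t0) {
    sel <- stimulus$truth$time_us >= t0 * 1e6 &
      stimulus$truth$time_us < (t0 + bin_s) * 1e6
    if (!any(sel)) return(NA_integer_)
    as.integer(round(mean(stimulus$truth$x[sel])) %/% columns_per_neuron)
  }, integer(1))
  err <- abs(winner - truth_idx)
  list(trajectory = data.frame(time_s = bin_starts, winner = winner,
                               truth = truth_idx, error = err),
       median_error = stats::median(err, na.rm = TRUE),
       monitored = monitored, ns = ns)
}
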