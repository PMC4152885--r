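# The virtual transceiver chip: an idealized leaky integrate-and-fire
# stand-in for the silicon neuron/synapse circuits, driven and read out
# purely through address events. Behavioural fidelity (winner-take-all
# selection, persistent activity) is the goal, not circuit-level fidelity.

# canonical dynamics parameter keys every LIF chip exposes
LIF_PARAM_KEYS <- c("tau_m", "r_in", "theta", "v_reset", "t_ref",
                    "tau_s_exc", "tau_s_inh", "w_exc", "w_inh",
                    "i_const", "noise_sd")

lif_parameter_specs <- function(values = list()) {
  defaults <- list(tau_m = 0.02, r_in = 1, theta = 1, v_reset = 0,
                   t_ref = 0.002, tau_s_exc = 0.005, tau_s_inh = 0.005,
                   w_exc = 0.5, w_inh = -0.5, i_const = 0, noise_sd = 0)
  units <- c(tau_m = "s", r_in = "ohm", theta = "V", v_reset = "V",
             t_ref = "s", tau_s_exc = "s", tau_s_inh = "s", w_exc = "A",
             w_inh = "A", i_const = "A", noise_sd = "A")
  names_long <- c(tau_m = "membrane time constant",
                  r_in = "input resistance", theta = "firing threshold",
                  v_reset = "reset potential", t_ref = "refractory period",
                  tau_s_exc = "excitatory synapse time constant",
                  tau_s_inh = "inhibitory synapse time constant",
                  w_exc = "excitatory synapse weight",
                  w_inh = "inhibitory synapse weight",
                  i_const = "constant bias current",
                  noise_sd = "current noise s.d.")
  defaults[names(values)] <- values
  lapply(names(defaults), function(k)
    parameter_spec(if (k %in% names(names_long)) names_long[[k]] else k,
                   if (k %in% names(units)) units[[k]] else "",
                   defaults[[k]], k))
}

#' Generic LIF transceiver chip description
#'
#' Builds a `chip_description` for a linear array of `n` neurons, each with
#' one excitatory and one inhibitory AER synapse, exposing the standard
#' dynamics parameters of the virtual backend.
#'
#' @param chip_id chip identifier.
#' @param n number of neurons.
#' @param soma_blocks optional data.frame `label`,`offset`,`extent`
#'   partitioning the array into soma blocks (default one block "neurons").
#' @param params named list overriding parameter typical values.
#' @param block_params optional per-block parameter overrides: a named
#'   list (block label -> named list of dynamics keys) stored as
#'   block-level parameters with access keys `"<label>.<key>"`; the
#'   virtual backend applies them to that block's neurons in place of the
#'   chip-level value.
#' @return a `chip_description`.
#' @export
make_lif_chip_description <- function(chip_id, n, soma_blocks = NULL,
                                      params = list(), block_params = list()) {
  nb <- max(1L, ceiling(log2(n)))
  src <- address_spec("source", list(field_spec("neuron", 0:(nb - 1), 2^nb - 1)))
  dst <- address_spec("destination",
                      list(field_spec("neuron", 0:(nb - 1), 2^nb - 1),
                           field_spec("synapse", nb, 1)))
  if (is.null(soma_blocks))
    soma_blocks <- data.frame(label = "neurons", offset = 0L, extent = n)
  soma <- lapply(seq_len(nrow(soma_blocks)), function(i) {
    lab <- soma_blocks$label[i]
    bp <- block_params[[lab]] %||% list()
    block_spec("soma", lab,
               data.frame(name = "neuron", offset = soma_blocks$offset[i],
                          extent = soma_blocks$extent[i]),
               parameters = lapply(names(bp), function(k)
                 parameter_spec(paste(lab, k), "", bp[[k]],
                                paste0(lab, ".", k))))
  })
  syn <- list(
    block_spec("synapse", "excitatory",
               data.frame(name = c("neuron", "synapse"), offset = c(0L, 0L),
                          extent = c(n, 1L))),
    block_spec("synapse", "inhibitory",
               data.frame(name = c("neuron", "synapse"), offset = c(0L, 1L),
                          extent = c(n, 1L))))
  chip_description(chip_id, soma, syn, src, dst, lif_parameter_specs(params))
}

#' Construct a virtual chip from a chip description
#'
#' The virtual chip realises the chip description's address space with LIF
#' dynamics: every soma address is a neuron, every synapse address an input
#' port on one of two current channels (excitatory / inhibitory, mapped by
#' synapse block label). Parameters are initialised from the description's
#' typical values and live in a mutable environment shared with the
#' configurator backend.
#'
#' @param chip a `chip_description` whose parameters include the standard
#'   LIF keys (see [make_lif_chip_description()]).
#' @param internal optional hard-wired (non-AER) connectivity: data.frame
#'   with columns `src`, `dst` (1-based neuron indices in source
#'   enumeration order), `chan` (1 excitatory, 2 inhibitory) and `wkey`
#'   (parameter key providing the weight, resolved at simulation time).
#' @return an object of class `virtual_chip`.
#' @export
virtual_chip <- function(chip, internal = NULL) {
  stopifnot(inherits(chip, "chip_description"))
  pspecs <- chip_parameters(chip)
  keys <- vapply(pspecs, `[[`, character(1), "access_key")
  missing <- setdiff(LIF_PARAM_KEYS, keys)
  if (length(missing))
    stop(sprintf("chip '%s' lacks dynamics parameter(s): %s", chip$chip_id,
                 paste(missing, collapse = ", ")))
  params <- new.env(parent = emptyenv())
  for (p in pspecs) assign(p$access_key, p$typical_value, envir = params)

  src <- enumerate_addresses(chip, "source")
  src_phys <- spec_encode(chip$source_spec, src)
  n <- nrow(src)

  # destination decode table: chip-local physical -> (unit, channel)
  dest_map <- NULL
  if (length(chip$synapse_blocks) > 0L) {
    dst <- enumerate_addresses(chip, "destination")
    blk <- attr(dst, "block")
    nf <- neuron_fields(chip)
    unit <- match(coord_key(dst, nf), coord_key(src, nf))
    chan <- ifelse(grepl("inh", blk), 2L, 1L)
    dest_map <- data.frame(phys = spec_encode(chip$dest_spec, dst),
                           unit = unit, chan = chan)
    dest_map <- dest_map[!is.na(dest_map$unit), , drop = FALSE]
  }
  if (!is.null(internal)) {
    stopifnot(all(c("src", "dst", "chan", "wkey") %in% names(internal)),
              all(internal$src >= 1 & internal$src <= n),
              all(internal$dst >= 1 & internal$dst <= n))
  }
  structure(list(chip = chip, n = n, src_coords = src, src_phys = src_phys,
                 dest_map = dest_map, internal = internal, params = params),
            class = "virtual_chip")
}

#' @export
print.virtual_chip <- function(x, ...) {
  cat(sprintf("<virtual_chip '%s'> %d neuron(s), %d hard-wired connection(s)\n",
              x$chip$chip_id, x$n,
              if (is.null(x$internal)) 0L else nrow(x$internal)))
  invisible(x)
}

# per-neuron resolution of a dynamics parameter: the chip-level value,
# overridden for the neurons of any soma block that declares a block-level
# parameter with access key "<block label>.<key>"
vc_param_vec <- function(vc, key) {
  v <- rep(vc_param(vc, key), vc$n)
  blk <- attr(vc$src_coords, "block")
  for (lab in unique(blk)) {
    bk <- paste0(lab, ".", key)
    if (exists(bk, envir = vc$params, inherits = FALSE))
      v[blk == lab] <- get(bk, envir = vc$params)
  }
  v
}

vc_param <- function(vc, key) {
  if (!exists(key, envir = vc$params, inherits = FALSE))
    stop(sprintf("chip '%s': unknown parameter key '%s' (has: %s)",
                 vc$chip$chip_id, key,
                 paste(sort(ls(vc$params)), collapse = ", ")))
  get(key, envir = vc$params)
}

# resolve chip-local destination addresses to (unit, chan, weight)
resolve_dest <- function(vc, phys) {
  if (is.null(vc$dest_map)) stop(sprintf("chip '%s' accepts no input events",
                                         vc$chip$chip_id))
  i <- match(phys, vc$dest_map$phys)
  if (anyNA(i))
    stop(sprintf("address %s is not a destination (synapse) address of chip '%s'",
                 format(phys[which(is.na(i))[1L]], scientific = FALSE),
                 vc$chip$chip_id))
  data.frame(unit = vc$dest_map$unit[i], chan = vc$dest_map$chan[i])
}

#' Simulate a virtual chip on an input event stream
#'
#' Fixed-step integration (default dt = 0.1 ms): each stimulus event adds
#' its synapse's weight to the target neuron's synaptic current, currents
#' decay exponentially, membranes integrate leakily, and threshold
#' crossings emit soma source events. Deterministic given the seed (the
#' seed only matters when current noise is enabled).
#'
#' @param vc a [virtual_chip()].
#' @param stimulus `event_stream` of chip-local destination (synapse)
#'   addresses; timestamps in microseconds.
#' @param duration_s simulated time in seconds.
#' @param seed RNG seed.
#' @param feedback_lut optional `connection_lut` of chip-local addresses
#'   (source soma -> destination synapse of this same chip) applied as
#'   one-step-delayed feedback, emulating a mapper loop.
#' @param dt integration step in seconds.
#' @param record record and return the membrane/current trace of
#'   `record_unit`.
#' @param record_unit 1-based neuron index for the trace.
#' @return list with `events` (`event_stream` of chip-local source
#'   addresses, sorted by time, ties by address), `spike_unit`,
#'   `spike_time_us`, and optional `v_trace`, `i_trace`.
#' @export
simulate_chip <- function(vc, stimulus = event_stream(), duration_s,
                          seed = 0L, feedback_lut = NULL, dt = 1e-4,
                          record = FALSE, record_unit = 1L) {
  stopifnot(inherits(vc, "virtual_chip"))
  n_steps <- as.integer(round(duration_s / dt))
  dt_us <- dt * 1e6

  p <- function(k) vc_param(vc, k)
  pv <- function(k) vc_param_vec(vc, k)
  # receiving-synapse weights, per neuron and channel
  w_mat <- rbind(pv("w_exc"), pv("w_inh"))
  tau_s <- c(p("tau_s_exc"), p("tau_s_inh"))

  if (nrow(stimulus) > 0L) {
    tgt <- resolve_dest(vc, stimulus$address)
    st_step <- as.integer(stimulus$timestamp_us %/% dt_us)
    keep <- st_step < n_steps
    st <- data.frame(step = st_step, neuron = tgt$unit - 1L,
                     chan = tgt$chan - 1L,
                     w = w_mat[cbind(tgt$chan, tgt$unit)])[keep, , drop = FALSE]
    st <- st[order(st$step), , drop = FALSE]
  } else {
    st <- data.frame(step = integer(0), neuron = integer(0),
                     chan = integer(0), w = numeric(0))
  }

  # routing table: hard-wired internal connections plus mapper feedback
  rt <- data.frame(src = integer(0), dst = integer(0), chan = integer(0),
                   w = numeric(0))
  if (!is.null(vc$internal) && nrow(vc$internal) > 0L) {
    w <- vapply(vc$internal$wkey, function(k) vc_param(vc, k), numeric(1))
    rt <- rbind(rt, data.frame(src = vc$internal$src, dst = vc$internal$dst,
                               chan = vc$internal$chan, w = unname(w)))
  }
  if (!is.null(feedback_lut) && nrow(feedback_lut) > 0L) {
    su <- match(feedback_lut$source, vc$src_phys)
    if (anyNA(su))
      stop("feedback LUT source is not a soma address of the chip")
    tg <- resolve_dest(vc, feedback_lut$destination)
    rt <- rbind(rt, data.frame(src = su, dst = tg$unit, chan = tg$chan,
                               w = w_mat[cbind(tg$chan, tg$unit)]))
  }
  rt <- rt[order(rt$src), , drop = FALSE]
  r_ptr <- c(0L, cumsum(tabulate(rt$src, nbins = vc$n)))

  res <- with_seed(seed, sim_lif_core(
    vc$n, dt, n_steps,
    pv("tau_m"), pv("r_in"), pv("theta"), pv("v_reset"),
    pv("t_ref"), pv("i_const"), tau_s,
    st$step, st$neuron, st$chan, st$w,
    as.integer(r_ptr), as.integer(rt$dst - 1L), as.integer(rt$chan - 1L),
    rt$w, p("noise_sd"), record, as.integer(record_unit - 1L)))

  unit <- res$spike_neuron + 1L
  time_us <- floor(res$spike_step * dt_us)
  out <- list(events = event_stream(vc$src_phys[unit], time_us),
              spike_unit = unit, spike_time_us = time_us)
  if (record) {
    out$v_trace <- res$v_trace
    out$i_trace <- res$i_trace
  }
  out
}

# ---- the hard-wired sWTA multi-neuron chip ---------------------------------

#' Build the virtual soft winner-take-all multi-neuron chip
#'
#' A linear array of `n_exc` excitatory neurons with hard-wired
#' nearest-neighbour excitatory connections at the given ring-free
#' (line-boundary) distances, plus `n_inh` inhibitory neurons that receive
#' excitation from every excitatory neuron and inhibit all of them. The
#' default sizes reproduce the 124 + 4 configuration of the bundled
#' `ifslwta` chip file.
#'
#' @param n_exc number of excitatory neurons (>= `2 * max(neighbor_orders) + 1`).
#' @param n_inh number of inhibitory neurons.
#' @param neighbor_orders integer vector of neighbour distances wired with
#'   lateral excitation.
#' @param params named list overriding the default dynamics parameters.
#' @return a [virtual_chip()] whose description matches the bundled
#'   `ifslwta.nhml` fixture at default sizes.
#' @export
build_swta_chip <- function(n_exc = 124, n_inh = 4, neighbor_orders = 1:3,
                            params = list()) {
  if (n_exc < 2 * max(neighbor_orders) + 1)
    stop(sprintf("n_exc = %d too small for neighbour orders up to %d",
                 n_exc, max(neighbor_orders)))
  if (n_inh < 1) stop("n_inh must be >= 1")
  defaults <- list(w_ee = 0.12, w_ei = 0.15, w_ie = -0.4)
  defaults[names(params)] <- params
  desc <- make_lif_chip_description(
    "ifslwta", n_exc + n_inh,
    soma_blocks = data.frame(label = c("excitatory", "inhibitory"),
                             offset = c(0L, n_exc), extent = c(n_exc, n_inh)),
    params = defaults)
  # extra weight parameters for the hard-wired topology
  extra <- list(
    parameter_spec("lateral excitatory weight", "A", defaults$w_ee, "w_ee"),
    parameter_spec("excitatory-to-inhibitory weight", "A", defaults$w_ei, "w_ei"),
    parameter_spec("inhibitory-to-excitatory weight", "A", defaults$w_ie, "w_ie"))
  desc$parameters <- c(desc$parameters[!vapply(desc$parameters, function(p)
    p$access_key %in% c("w_ee", "w_ei", "w_ie"), logical(1))], extra)
  validate_chip(desc)

  exc <- seq_len(n_exc)
  inh <- n_exc + seq_len(n_inh)
  nb <- do.call(rbind, lapply(neighbor_orders, function(d) {
    i <- exc[exc + d <= n_exc]
    rbind(data.frame(src = i, dst = i + d),
          data.frame(src = i + d, dst = i))
  }))
  internal <- rbind(
    data.frame(src = nb$src, dst = nb$dst, chan = 1L, wkey = "w_ee"),
    data.frame(src = rep(exc, each = n_inh), dst = rep(inh, times = n_exc),
               chan = 1L, wkey = "w_ei"),
    data.frame(src = rep(inh, each = n_exc), dst = rep(exc, times = n_inh),
               chan = 2L, wkey = "w_ie"))
  virtual_chip(desc, internal)
}

#' Winner selection between competing input groups on a sWTA chip
#'
#' Drives disjoint groups of excitatory neurons with independent Poisson
#' trains on their excitatory synapses, simulates the chip, and reports the
#' group whose somas fired most in the scoring window.
#'
#' @param vc a [build_swta_chip()] result.
#' @param groups list of 1-based excitatory-neuron index vectors (disjoint).
#' @param rates_hz per-neuron Poisson input rate for each group.
#' @param duration_s trial length in seconds.
#' @param seed RNG seed (input trains and chip noise).
#' @param score_window_s length of the scoring window at the end of the
#'   trial (default: second half).
#' @return list with `winner` (group index), `rates_hz` (per-group mean
#'   soma rate in the window) and the monitored `events`.
#' @export
swta_select <- function(vc, groups, rates_hz, duration_s = 1, seed = 1L,
                        score_window_s = duration_s / 2) {
  stopifnot(length(groups) == length(rates_hz))
  if (length(unique(unlist(groups))) != length(unlist(groups)))
    stop("input groups must be disjoint")
  dst <- enumerate_addresses(vc$chip, "destination", "excitatory")
  dst_phys <- spec_encode(vc$chip$dest_spec, dst)
  stim <- with_seed(seed, {
    ev <- lapply(seq_along(groups), function(g) {
      do.call(rbind, lapply(groups[[g]], function(i) {
        times <- poisson_times(rates_hz[[g]], duration_s)
        if (length(times) == 0L) return(NULL)
        data.frame(address = dst_phys[match(i - 1L, dst$neuron)],
                   timestamp_us = times)
      }))
    })
    do.call(rbind, ev)
  })
  stim <- if (is.null(stim)) event_stream() else
    event_stream(stim$address, stim$timestamp_us)
  res <- simulate_chip(vc, stim, duration_s, seed = seed + 1L)
  t0 <- (duration_s - score_window_s) * 1e6
  rates <- vapply(groups, function(g) {
    sum(res$spike_unit %in% g & res$spike_time_us >= t0) /
      (length(g) * score_window_s)
  }, numeric(1))
  list(winner = which.max(rates), rates_hz = rates, events = res$events)
}

# homogeneous Poisson spike times in [0, duration), integer microseconds
poisson_times <- function(rate_hz, duration_s) {
  if (rate_hz < 0) stop("rate must be >= 0")
  if (rate_hz == 0) return(numeric(0))
  n_guess <- max(10, ceiling(rate_hz * duration_s + 5 * sqrt(rate_hz * duration_s)))
  t <- cumsum(rexp(n_guess, rate_hz))
  while (length(t) && t[length(t)] < duration_s)
    t <- c(t, t[length(t)] + cumsum(rexp(n_guess, rate_hz)))
  floor(t[t < duration_s] * 1e6)
}

# ---- software mapper -------------------------------------------------------

#' Route produced events through a connection LUT
#'
#' Pure software mapper: each source event yields one routed event per
#' matching LUT entry (fan-out), carrying the entry's destination address
#' and the source event's timestamp. Events whose address matches no entry
#' are dropped and counted, never silently lost:
#' `n_events(routed) + fanout-weighted matches` is exactly conserved.
#'
#' @param lut a [connection_lut()].
#' @param events an `event_stream` of source addresses.
#' @return list with `routed` (`event_stream`), `n_unmatched` and
#'   `n_matched`.
#' @export
software_mapper_route <- function(lut, events) {
  if (nrow(events) == 0L || nrow(lut) == 0L)
    return(list(routed = event_stream(), n_unmatched = nrow(events),
                n_matched = 0L))
  fan <- split(lut$destination, lut$source)
  key <- match(as.character(events$address), names(fan))
  matched <- !is.na(key)
  dests <- fan[key[matched]]
  counts <- lengths(dests)
  routed <- event_stream(unlist(dests, use.names = FALSE),
                         rep(events$timestamp_us[matched], counts))
  list(routed = routed, n_unmatched = sum(!matched),
       n_matched = sum(matched))
}
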