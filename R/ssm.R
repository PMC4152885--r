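# End-to-end demo 2: soft state machines. A finite-state machine is
# synthesised onto coupled soft winner-take-all circuits: state
# populations hold the current state as persistent activity under mutual
# competition; transition populations fire only on the coincidence of an
# active state and an external input symbol and steer the competition to
# the next state; detection-flagged transitions also drive an output
# population whose rate crossing signals the detection.

#' Finite-state machine specification
#'
#' @param transitions data.frame with columns `state`, `symbol`,
#'   `next_state` and optional logical `detect`.
#' @param initial initial state (default `"Idle"`).
#' @param reset_symbol the invalid-cue symbol that maps every state to the
#'   initial state; reset transitions are added automatically for states
#'   without an explicit one.
#' @return an object of class `fsm_spec` with `states`, `symbols`,
#'   `transitions`, `initial`, `reset_symbol`.
#' @export
fsm_spec <- function(transitions, initial = "Idle", reset_symbol = "x") {
  tr <- as.data.frame(transitions, stringsAsFactors = FALSE)
  stopifnot(all(c("state", "symbol", "next_state") %in% names(tr)))
  if (is.null(tr$detect)) tr$detect <- FALSE
  tr$detect <- as.logical(tr$detect)
  states <- unique(c(initial, tr$state, tr$next_state))
  # the reset symbol maps every state to the initial state
  for (s in states) {
    if (!any(tr$state == s & tr$symbol == reset_symbol))
      tr <- rbind(tr, data.frame(state = s, symbol = reset_symbol,
                                 next_state = initial, detect = FALSE))
  }
  if (any(tr$symbol == reset_symbol & tr$next_state != initial))
    stop(sprintf("the reset symbol '%s' must map every state to '%s'",
                 reset_symbol, initial))
  if (anyDuplicated(tr[, c("state", "symbol")]))
    stop("duplicate (state, symbol) transition")
  symbols <- unique(c(tr$symbol, reset_symbol))
  rownames(tr) <- NULL
  structure(list(states = states, symbols = symbols, transitions = tr,
                 initial = initial, reset_symbol = reset_symbol),
            class = "fsm_spec")
}

#' @export
print.fsm_spec <- function(x, ...) {
  cat(sprintf("<fsm> %d states (%s), %d symbols, %d transitions (%d detecting)\n",
              length(x$states), paste(x$states, collapse = ", "),
              length(x$symbols), nrow(x$transitions),
              sum(x$transitions$detect)))
  invisible(x)
}

#' Read an FSM specification file
#'
#' Plain-text format: optional header lines `initial,<state>` and
#' `reset,<symbol>`, then one transition per line as
#' `state,symbol,next_state[,detect]`. Lines starting with `#` are
#' comments.
#'
#' @param file path.
#' @return an [fsm_spec()].
#' @export
read_fsm <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  initial <- "Idle"; reset <- "x"
  rows <- list()
  for (i in seq_along(lines)) {
    p <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
    if (length(p) == 2 && p[1] == "initial") initial <- p[2]
    else if (length(p) == 2 && p[1] == "reset") reset <- p[2]
    else if (length(p) %in% 3:4)
      rows[[length(rows) + 1L]] <-
        data.frame(state = p[1], symbol = p[2], next_state = p[3],
                   detect = length(p) == 4 && p[4] == "detect")
    else stop(sprintf("'%s' line %d: cannot parse '%s'", file, i, lines[i]))
  }
  if (length(rows) == 0L) stop(sprintf("'%s' declares no transitions", file))
  fsm_spec(do.call(rbind, rows), initial = initial, reset_symbol = reset)
}

#' Bundled sequence-detector FSM
#'
#' The two-symbol sequence detector used by the soft-state-machine demo:
#' from Idle the cue CA (detect L then R) or CB (detect R then L) selects
#' the sequence to watch for; the reset symbol x returns to Idle; the
#' second symbol of a valid sequence triggers a detection.
#'
#' @return an [fsm_spec()].
#' @export
seqdet_fsm <- function() {
  read_fsm(system.file("extdata", "seqdet.fsm", package = "aerkit"))
}

#' Reference FSM walk (pure transition-table oracle)
#'
#' Deterministic walk of the transition table: undefined (state, symbol)
#' pairs leave the state unchanged.
#'
#' @param fsm an [fsm_spec()].
#' @param symbols character vector of input symbols.
#' @return list with `states` (length `length(symbols) + 1`, starting at
#'   the initial state) and `detect` (logical per step).
#' @export
fsm_oracle <- function(fsm, symbols) {
  unknown <- setdiff(symbols, fsm$symbols)
  if (length(unknown))
    stop(sprintf("unknown symbol(s): %s", paste(unknown, collapse = ", ")))
  s <- fsm$initial
  states <- character(length(symbols) + 1L)
  detect <- logical(length(symbols))
  states[1] <- s
  for (k in seq_along(symbols)) {
    i <- which(fsm$transitions$state == s &
                 fsm$transitions$symbol == symbols[k])
    if (length(i) == 1L) {
      detect[k] <- fsm$transitions$detect[i]
      s <- fsm$transitions$next_state[i]
    }
    states[k + 1L] <- s
  }
  list(states = states, detect = detect)
}

# ---- synthesis -------------------------------------------------------------

# single-chip setup wrapper for a programmatically built chip
single_chip_setup <- function(chip, channel_offset = 16L) {
  structure(list(name = paste0(chip$chip_id, "_setup"),
                 channels = structure(0L, names = chip$chip_id),
                 chips = structure(list(chip), names = chip$chip_id),
                 api_plugins = c(communicator = "virtual",
                                 configurator = "virtual",
                                 mapper = "virtual"),
                 channel_offset = as.integer(channel_offset)),
            class = "setup_description")
}

#' Synthesise a soft state machine network
#'
#' Maps an FSM onto a spiking network of coupled winner-take-all circuits
#' on one virtual LIF chip, wiring via LUT entries (entry multiplicity
#' realises connection strength by event fan-out):
#' \enumerate{
#'   \item recurrent all-to-all excitation within each state population;
#'   \item mutual inhibition between state populations via a shared
#'     inhibitory pool;
#'   \item each transition population receives sparse excitation from its
#'     state population and from its symbol's external input line, with
#'     weights such that neither alone reaches threshold (coincidence
#'     detection);
#'   \item transition populations excite their target state population
#'     strongly enough to win the state competition;
#'   \item detection-flagged transitions also excite a dedicated output
#'     population.
#' }
#' Transition populations exist for every non-self-loop (state, symbol)
#' arrow, including the automatic reset arrows.
#'
#' @param fsm an [fsm_spec()].
#' @param n_state neurons per state population.
#' @param n_trans neurons per transition population.
#' @param n_out neurons per output population.
#' @param n_inh neurons in the shared inhibitory pool.
#' @param mult named multiplicities of the synthesis rules: `rec`
#'   (recurrent), `sp` (state to pool), `ps` (pool to state, inhibitory),
#'   `ts` (transition to next state), `out` (transition to output).
#' @param k_sparse state-population fan-in per transition neuron.
#' @param params overrides for the chip's dynamics parameters.
#' @param block_params per-role parameter overrides (soma blocks `state`,
#'   `pool`, `trans`, `out`); by default the inhibitory pool integrates
#'   more slowly (`tau_m` 40 ms) with a longer refractory period, which
#'   damps the excitatory-inhibitory population oscillation.
#' @return an object of class `ssm_network`: the `neuro_setup`, the
#'   synthesis `lut`, population index ranges (`pops`), the per-symbol
#'   input synapse addresses (`symbol_inputs`) and the sizes used.
#' @export
build_ssm <- function(fsm, n_state = 32, n_trans = 16, n_out = 16,
                      n_inh = 16,
                      mult = c(rec = 1, sp = 1, ps = 1, ts = 3, out = 1),
                      k_sparse = 15, params = list(), block_params = list()) {
  stopifnot(inherits(fsm, "fsm_spec"))
  tr <- fsm$transitions
  arrows <- tr[tr$state != tr$next_state, , drop = FALSE]
  rownames(arrows) <- NULL
  n_arrow <- nrow(arrows)
  n_det <- sum(arrows$detect)
  n_states <- length(fsm$states)

  n_total <- n_states * n_state + n_inh + n_arrow * n_trans + n_det * n_out
  # dynamics defaults, tuned once and frozen: long (NMDA-like) excitatory
  # synapses stabilise persistent activity against synchrony; the slow,
  # low-threshold pool supplies smoothly graded competition; per-block
  # receiving weights set the coincidence and ignition margins.
  defaults <- list(tau_s_exc = 0.05, tau_s_inh = 0.05, noise_sd = 2.5,
                   w_exc = 0.08, w_inh = -0.05)
  defaults[names(params)] <- params
  bdefaults <- list(state = list(t_ref = 0.02, w_exc = 0.08),
                    pool = list(t_ref = 0.005, w_exc = 0.025),
                    trans = list(w_exc = 0.025),
                    out = list(w_exc = 0.08))
  bdefaults[names(block_params)] <- block_params
  off <- c(0L, n_states * n_state, n_states * n_state + n_inh,
           n_states * n_state + n_inh + n_arrow * n_trans)
  ext <- c(n_states * n_state, n_inh, n_arrow * n_trans, n_det * n_out)
  blocks <- data.frame(label = c("state", "pool", "trans", "out"),
                       offset = off, extent = ext)
  blocks <- blocks[blocks$extent > 0L, , drop = FALSE]
  chip <- make_lif_chip_description("ssm", n_total, soma_blocks = blocks,
                                    params = defaults,
                                    block_params = bdefaults)
  setup <- single_chip_setup(chip)
  vc <- virtual_chip(chip)
  ns <- load_plugins(setup, options = list(chip_models = list(ssm = vc)))
  ca <- ns$ca

  # population layout: state pops | inhibitory pool | transition pops | outputs
  cursor <- 0L
  take <- function(k) { r <- cursor + seq_len(k); cursor <<- cursor + k; r }
  pops <- list()
  for (s in fsm$states) pops[[paste0("state:", s)]] <- take(n_state)
  pops[["pool"]] <- take(n_inh)
  for (a in seq_len(n_arrow))
    pops[[paste0("trans:", arrows$state[a], ":", arrows$symbol[a])]] <-
      take(n_trans)
  det_idx <- which(arrows$detect)
  for (a in det_idx)
    pops[[paste0("out:", arrows$state[a], ":", arrows$symbol[a])]] <-
      take(n_out)
  stopifnot(cursor == n_total)

  exc <- function(units) encode_address(ca, 0, data.frame(neuron = units - 1L,
                                                          synapse = 0L),
                                        "destination")
  inh <- function(units) encode_address(ca, 0, data.frame(neuron = units - 1L,
                                                          synapse = 1L),
                                        "destination")
  som <- function(units) encode_address(ca, 0, data.frame(neuron = units - 1L),
                                        "source")
  pairs_all <- function(src_units, dst_addr, m, no_self = FALSE) {
    s <- rep(som(src_units), each = length(dst_addr))
    d <- rep(dst_addr, times = length(src_units))
    if (no_self) {
      keep <- rep(src_units, each = length(dst_addr)) !=
        rep(attr(dst_addr, "units"), times = length(src_units))
      s <- s[keep]; d <- d[keep]
    }
    data.frame(source = rep(s, m), destination = rep(d, m))
  }

  entries <- list()
  add <- function(df) entries[[length(entries) + 1L]] <<- df
  pool <- pops[["pool"]]
  for (s in fsm$states) {
    st <- pops[[paste0("state:", s)]]
    ex_addr <- exc(st); attr(ex_addr, "units") <- st
    add(pairs_all(st, ex_addr, mult[["rec"]], no_self = TRUE))     # (a)
    add(pairs_all(st, exc(pool), mult[["sp"]]))                    # (b) up
    add(pairs_all(pool, inh(st), mult[["ps"]]))                    # (b) down
  }
  for (a in seq_len(n_arrow)) {
    tpop <- pops[[paste0("trans:", arrows$state[a], ":", arrows$symbol[a])]]
    spop <- pops[[paste0("state:", arrows$state[a])]]
    # (c) sparse state -> transition: k_sparse sources per transition neuron
    src <- unlist(lapply(seq_along(tpop), function(j)
      spop[((j - 1L + seq_len(k_sparse) - 1L) %% length(spop)) + 1L]))
    add(data.frame(source = som(src),
                   destination = rep(exc(tpop), each = k_sparse)))
    npop <- pops[[paste0("state:", arrows$next_state[a])]]
    add(pairs_all(tpop, exc(npop), mult[["ts"]]))                  # (d)
    if (arrows$detect[a]) {                                        # (e)
      opop <- pops[[paste0("out:", arrows$state[a], ":", arrows$symbol[a])]]
      add(pairs_all(tpop, exc(opop), mult[["out"]]))
    }
  }
  ent <- do.call(rbind, entries)
  lut <- connection_lut(ent$source, ent$destination, multiplicity = TRUE)

  symbol_inputs <- lapply(fsm$symbols, function(sym) {
    tp <- unlist(pops[paste0("trans:", arrows$state[arrows$symbol == sym],
                             ":", sym)], use.names = FALSE)
    if (length(tp)) exc(tp) else numeric(0)
  })
  names(symbol_inputs) <- fsm$symbols

  structure(list(fsm = fsm, ns = ns, lut = lut, pops = pops,
                 symbol_inputs = symbol_inputs,
                 init_inputs = exc(pops[[paste0("state:", fsm$initial)]]),
                 sizes = c(n_state = n_state, n_trans = n_trans,
                           n_out = n_out, n_inh = n_inh, total = n_total),
                 arrows = arrows),
            class = "ssm_network")
}

#' @export
print.ssm_network <- function(x, ...) {
  cat(sprintf("<ssm_network> %d states x %d, %d transitions x %d, %d outputs x %d, pool %d; %d LUT entries\n",
              length(x$fsm$states), x$sizes[["n_state"]], nrow(x$arrows),
              x$sizes[["n_trans"]], sum(x$arrows$detect), x$sizes[["n_out"]],
              x$sizes[["n_inh"]], nrow(x$lut)))
  invisible(x)
}

#' Run a symbol sequence through a soft state machine
#'
#' The network is initialised by an excitation volley to the initial state
#' population; each symbol is then delivered as a fixed-duration Poisson
#' volley to its transition populations' input synapses, separated by
#' silent gaps. The decoded state of each step is the state population
#' with the highest firing rate in the second half of the following gap;
#' a detection is reported when an output population's rate crosses the
#' threshold during a step.
#'
#' @param net a [build_ssm()] network.
#' @param symbols character vector of input symbols.
#' @param seed RNG seed (input volleys).
#' @param symbol_dur_s,gap_s volley length and inter-symbol gap (seconds).
#' @param rate_hz per-neuron Poisson rate of a symbol volley.
#' @param init_rate_hz,init_mult rate and event multiplicity of the
#'   initialisation volley.
#' @param detect_threshold_hz output-population rate threshold.
#' @return list with `states` (decoded trajectory, length
#'   `length(symbols) + 1`), `detect` (logical per step), `detections`
#'   (data.frame `step`, `output`, `time_us`), `rates` (state-population
#'   rate per decode window) and the monitored `events`.
#' @export
run_ssm <- function(net, symbols, seed = 1L, symbol_dur_s = 0.2,
                    gap_s = 0.3, rate_hz = 480, init_rate_hz = 800,
                    init_mult = 1, detect_threshold_hz = 20) {
  stopifnot(inherits(net, "ssm_network"))
  unknown <- setdiff(symbols, net$fsm$symbols)
  if (length(unknown))
    stop(sprintf("unknown symbol(s): %s", paste(unknown, collapse = ", ")))
  period <- symbol_dur_s + gap_s
  init_dur <- symbol_dur_s + gap_s
  t_sym <- init_dur + (seq_along(symbols) - 1) * period
  duration_s <- init_dur + length(symbols) * period

  volley <- function(addrs, t0, dur, rate, m = 1) {
    if (length(addrs) == 0L) return(NULL)
    times <- lapply(seq_along(addrs), function(i) poisson_times(rate, dur))
    a <- rep(rep(addrs, lengths(times)), m)
    t <- rep(unlist(times) + t0 * 1e6, m)
    data.frame(address = a, timestamp_us = t)
  }
  stim <- with_seed(seed, {
    parts <- list(volley(net$init_inputs, 0, symbol_dur_s, init_rate_hz,
                         init_mult))
    for (k in seq_along(symbols))
      parts[[k + 1L]] <- volley(net$symbol_inputs[[symbols[k]]], t_sym[k],
                                symbol_dur_s, rate_hz)
    df <- do.call(rbind, parts)
    event_stream(df$address, df$timestamp_us)
  })

  monitored <- setup_run(net$ns, net$lut, stim, duration_s, seed = seed)

  ca <- net$ns$ca
  dec <- decode_address(ca, monitored$address, "source")
  unit <- dec$neuron + 1L
  tms <- monitored$timestamp_us

  rate_in <- function(units, t0, t1) {
    sum(unit %in% units & tms >= t0 * 1e6 & tms < t1 * 1e6) /
      (length(units) * (t1 - t0))
  }
  state_names <- net$fsm$states
  windows <- rbind(c(init_dur - gap_s / 2, init_dur),
                   cbind(t_sym + symbol_dur_s + gap_s / 2,
                         t_sym + period))
  rates <- matrix(0, nrow = nrow(windows), ncol = length(state_names),
                  dimnames = list(NULL, state_names))
  states <- character(nrow(windows))
  prev <- net$fsm$initial
  for (w in seq_len(nrow(windows))) {
    for (s in state_names)
      rates[w, s] <- rate_in(net$pops[[paste0("state:", s)]],
                             windows[w, 1], windows[w, 2])
    states[w] <- if (max(rates[w, ]) == 0) prev else
      state_names[which.max(rates[w, ])]
    prev <- states[w]
  }

  det <- logical(length(symbols))
  det_rows <- list()
  out_names <- grep("^out:", names(net$pops), value = TRUE)
  for (k in seq_along(symbols)) {
    t0 <- t_sym[k]; t1 <- t_sym[k] + period
    for (o in out_names) {
      bins <- seq(t0, t1 - 0.05, by = 0.05)
      r <- vapply(bins, function(b)
        rate_in(net$pops[[o]], b, b + 0.05), numeric(1))
      hit <- which(r > detect_threshold_hz)
      if (length(hit)) {
        det[k] <- TRUE
        det_rows[[length(det_rows) + 1L]] <-
          data.frame(step = k, output = sub("^out:", "", o),
                     time_us = floor((bins[hit[1]]) * 1e6))
      }
    }
  }
  list(states = states, detect = det,
       detections = if (length(det_rows)) do.call(rbind, det_rows)
       else data.frame(step = integer(0), output = character(0),
                       time_us = numeric(0)),
       rates = rates, events = monitored, windows = windows)
}
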