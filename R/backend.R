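# Abstract backend contracts (communicator / configurator / mapper), the
# plugin registry, and batch-run orchestration. All addresses crossing the
# contract boundary are board-level physical integers; translation is the
# front-end's business.

.plugin_registry <- new.env(parent = emptyenv())

#' Register a backend plugin
#'
#' A plugin is a factory `function(setup, options)` returning a list with
#' any of the elements `communicator`, `configurator`, `mapper`. One
#' factory call serves all roles a setup assigns to the plugin name.
#'
#' @param name plugin name as referenced by setup files.
#' @param factory the factory function.
#' @return invisibly, the name.
#' @export
register_plugin <- function(name, factory) {
  assign(name, factory, envir = .plugin_registry)
  invisible(name)
}

#' Names of registered backend plugins
#' @return character vector.
#' @export
plugin_names <- function() sort(ls(.plugin_registry))

#' Load backend plugins and wire a NeuroSetup
#'
#' Instantiates the communicator, configurator and mapper named by the
#' setup description's `api_plugins` and binds them, with the channel
#' addressing, into the gateway object used for all hardware operations.
#'
#' @param setup a `setup_description`.
#' @param options named list passed to each plugin factory. The virtual
#'   backend understands `chip_models` (named list chip_id ->
#'   [virtual_chip()]) and `dt`.
#' @return an object of class `neuro_setup` with elements `setup`, `ca`,
#'   `communicator`, `configurator`, `mapper`.
#' @export
load_plugins <- function(setup, options = list()) {
  stopifnot(inherits(setup, "setup_description"))
  wanted <- setup$api_plugins
  missing <- setdiff(unique(wanted), plugin_names())
  if (length(missing))
    stop(sprintf("unknown plugin(s) %s; registered plugins: %s",
                 paste(sQuote(missing), collapse = ", "),
                 paste(plugin_names(), collapse = ", ")))
  instances <- list()
  parts <- list()
  for (role in names(wanted)) {
    nm <- wanted[[role]]
    if (is.null(instances[[nm]]))
      instances[[nm]] <- get(nm, envir = .plugin_registry)(setup, options)
    obj <- instances[[nm]][[role]]
    if (is.null(obj))
      stop(sprintf("plugin '%s' does not provide a %s", nm, role))
    parts[[role]] <- obj
  }
  structure(list(setup = setup, ca = channel_addressing(setup),
                 communicator = parts$communicator,
                 configurator = parts$configurator,
                 mapper = parts$mapper),
            class = "neuro_setup")
}

#' @export
print.neuro_setup <- function(x, ...) {
  cat(sprintf("<neuro_setup '%s'> plugins: %s\n", x$setup$name,
              paste(names(x$setup$api_plugins), x$setup$api_plugins,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Runtime context (exception-safe bracket around a run)
#'
#' @param enter,exit zero-argument functions executed around the hardware
#'   run; `exit` runs even when the run fails.
#' @return an object of class `runtime_context`.
#' @export
runtime_context <- function(enter = function() NULL, exit = function() NULL) {
  structure(list(enter = enter, exit = exit), class = "runtime_context")
}

#' Batch experiment run
#'
#' Executes, in order: `mapper$program(lut)`, configurator flush, context
#' enter, `communicator$run(stimulus, ...)`, context exit. The context exit
#' action runs even if the communicator fails; a backend error is
#' re-raised only after the exit action has run. Both the stimulus and the
#' returned monitored stream carry physical addresses only.
#'
#' @param ns a [load_plugins()] result.
#' @param lut a [connection_lut()] (may be empty).
#' @param stimulus `event_stream`; timestamps must lie in
#'   `[0, duration_s * 1e6]`.
#' @param duration_s run duration in seconds.
#' @param context optional [runtime_context()].
#' @param seed RNG seed forwarded to the backend.
#' @return monitored `event_stream`, sorted by timestamp.
#' @export
setup_run <- function(ns, lut = connection_lut(), stimulus = event_stream(),
                      duration_s, context = NULL, seed = 0L) {
  stopifnot(inherits(ns, "neuro_setup"), inherits(stimulus, "event_stream"))
  if (nrow(stimulus) && max(stimulus$timestamp_us) > duration_s * 1e6)
    stop("stimulus extends beyond the run duration")
  if (!is.null(context) && !inherits(context, "runtime_context"))
    stop("context must be a runtime_context")
  ns$mapper$program(lut)
  ns$configurator$flush()
  if (!is.null(context)) context$enter()
  err <- NULL
  out <- tryCatch(ns$communicator$run(stimulus, duration_s, seed),
                  error = function(e) { err <<- e; NULL })
  if (!is.null(context)) {
    exit_err <- tryCatch({ context$exit(); NULL }, error = function(e) e)
    if (!is.null(exit_err) && is.null(err))
      warning(sprintf("context exit failed: %s", conditionMessage(exit_err)))
  }
  if (!is.null(err)) stop(err)
  out
}

#' Get / set a chip parameter through the configurator
#'
#' Parameters (firing thresholds, leak time constants, synaptic weights,
#' ...) are addressed by the access keys declared in the chip's NHML
#' parameter list; on the virtual backend a set followed by a get returns
#' the set value, and defaults are the NHML typical values.
#'
#' @param ns a [load_plugins()] result.
#' @param chip_id chip identifier.
#' @param access_key parameter access key.
#' @param value numeric value to set.
#' @return `get_parameter` returns the value; `set_parameter` returns it
#'   invisibly.
#' @export
get_parameter <- function(ns, chip_id, access_key) {
  ns$configurator$get(chip_id, access_key)
}

#' @rdname get_parameter
#' @export
set_parameter <- function(ns, chip_id, access_key, value) {
  ns$configurator$set(chip_id, access_key, value)
  invisible(value)
}

# ---- virtual backend -------------------------------------------------------

virtual_system <- function(setup, options) {
  sys <- new.env(parent = emptyenv())
  sys$setup <- setup
  sys$ca <- channel_addressing(setup)
  sys$dt <- options$dt %||% 1e-4
  sys$running <- FALSE
  sys$lut <- connection_lut()
  sys$unmatched <- 0L
  models <- options$chip_models %||% list()
  sys$models <- list()
  sys$params <- list()
  for (id in names(setup$chips)) {
    chip <- setup$chips[[id]]
    keys <- vapply(chip_parameters(chip), `[[`, character(1), "access_key")
    if (!is.null(models[[id]])) {
      vc <- models[[id]]
      if (!identical(vc$chip$chip_id, id))
        stop(sprintf("chip model supplied for '%s' describes chip '%s'", id,
                     vc$chip$chip_id))
      sys$models[[id]] <- vc
      sys$params[[id]] <- vc$params          # shared: configurator edits bite
    } else if (all(LIF_PARAM_KEYS %in% keys)) {
      vc <- virtual_chip(chip)               # plain unwired LIF array
      sys$models[[id]] <- vc
      sys$params[[id]] <- vc$params
    } else {
      e <- new.env(parent = emptyenv())      # pure event source (sensor)
      for (ps in chip_parameters(chip))
        assign(ps$access_key, ps$typical_value, envir = e)
      sys$params[[id]] <- e
    }
  }
  sys
}

virtual_run <- function(sys, stimulus, duration_s, seed) {
  if (sys$running) stop("a run is already in progress")
  sys$running <- TRUE
  on.exit(sys$running <- FALSE)
  ca <- sys$ca
  duration_us <- duration_s * 1e6
  lut <- sys$lut

  dec_dst <- decode_address(ca, stimulus$address, "destination",
                            on_invalid = "mark")
  dec_src <- decode_address(ca, stimulus$address, "source",
                            on_invalid = "mark")
  is_dst <- dec_dst$valid
  is_src <- !is_dst & dec_src$valid
  if (!all(is_dst | is_src)) {
    bad <- which(!(is_dst | is_src))[1L]
    stop(sprintf("stimulus address %s is neither a destination nor a source address of the setup",
                 format(stimulus$address[bad], scientific = FALSE)))
  }
  src_ev <- event_stream(stimulus$address[is_src],
                         stimulus$timestamp_us[is_src])
  routed <- software_mapper_route(lut, src_ev)
  sys$unmatched <- routed$n_unmatched
  dest_ev <- bind_events(
    event_stream(stimulus$address[is_dst], stimulus$timestamp_us[is_dst]),
    routed$routed)

  out_parts <- list(src_ev)
  dchan <- dest_ev$address %/% 2^ca$channel_offset
  for (id in names(sys$setup$chips)) {
    channel <- sys$setup$channels[[id]]
    mine <- dchan == channel
    vc <- sys$models[[id]]
    if (is.null(vc)) {
      if (any(mine))
        stop(sprintf("chip '%s' is a pure event source and cannot be stimulated", id))
      next
    }
    base <- channel * 2^ca$channel_offset
    # feedback: LUT entries sourced at this chip's own somas
    fb <- NULL
    if (nrow(lut)) {
      own <- lut$source %in% (vc$src_phys + base)
      if (any(own)) {
        fdst <- lut$destination[own] %/% 2^ca$channel_offset
        if (any(fdst != channel))
          stop(sprintf("LUT routes chip '%s' output to another dynamical chip; closed loops must stay on-chip", id))
        fb <- connection_lut(lut$source[own] - base,
                             lut$destination[own] - base,
                             multiplicity = TRUE)
      }
    }
    local_stim <- event_stream(dest_ev$address[mine] - base,
                               dest_ev$timestamp_us[mine])
    res <- simulate_chip(vc, local_stim, duration_s,
                         seed = seed + channel, feedback_lut = fb,
                         dt = sys$dt)
    if (nrow(res$events))
      out_parts[[length(out_parts) + 1L]] <-
        event_stream(res$events$address + base, res$events$timestamp_us)
  }
  mon <- do.call(bind_events, out_parts)
  event_stream(mon$address[mon$timestamp_us <= duration_us],
               mon$timestamp_us[mon$timestamp_us <= duration_us])
}

virtual_plugin_factory <- function(setup, options) {
  sys <- virtual_system(setup, options)
  communicator <- list(
    capabilities = c(can_sequence = TRUE, can_monitor = TRUE),
    system = sys,
    run = function(stimulus, duration_s, seed = 0L)
      virtual_run(sys, stimulus, duration_s, seed),
    # online mode: batch-computed, incrementally fetched
    start = function(stimulus, duration_s, seed = 0L) {
      sys$online <- virtual_run(sys, stimulus, duration_s, seed)
      sys$online_cursor <- 0
      invisible(TRUE)
    },
    fetch = function(up_to_us) {
      if (is.null(sys$online)) stop("no online run in progress")
      sel <- sys$online$timestamp_us > sys$online_cursor &
        sys$online$timestamp_us <= up_to_us
      sys$online_cursor <- up_to_us
      event_stream(sys$online$address[sel], sys$online$timestamp_us[sel])
    },
    stop = function() { sys$online <- NULL; invisible(TRUE) })
  configurator <- list(
    system = sys,
    get = function(chip_id, key) {
      e <- sys$params[[chip_id]]
      if (is.null(e)) stop(sprintf("unknown chip '%s'", chip_id))
      if (!exists(key, envir = e, inherits = FALSE))
        stop(sprintf("chip '%s': unknown parameter key '%s' (has: %s)",
                     chip_id, key, paste(sort(ls(e)), collapse = ", ")))
      get(key, envir = e)
    },
    set = function(chip_id, key, value) {
      if (sys$running)
        stop("parameters cannot be changed while a batch run is in progress")
      e <- sys$params[[chip_id]]
      if (is.null(e)) stop(sprintf("unknown chip '%s'", chip_id))
      if (!exists(key, envir = e, inherits = FALSE))
        stop(sprintf("chip '%s': unknown parameter key '%s' (has: %s)",
                     chip_id, key, paste(sort(ls(e)), collapse = ", ")))
      assign(key, value, envir = e)
    },
    flush = function() invisible(TRUE))
  mapper <- list(
    system = sys,
    program = function(lut) {
      stopifnot(inherits(lut, "connection_lut"))
      sys$lut <- lut
      invisible(TRUE)
    },
    clear = function() { sys$lut <- connection_lut(); invisible(TRUE) },
    installed = function() sys$lut,
    route = function(events) software_mapper_route(sys$lut, events))
  list(communicator = communicator, configurator = configurator,
       mapper = mapper)
}

# TCP transport plugin: sequences a stimulus packet to the peer and
# monitors by receiving one packet back. Configuration/mapping stay local
# (virtual), matching a remote-retina / local-chip deployment split.
tcp_plugin_factory <- function(setup, options) {
  con <- options$tcp_con
  communicator <- list(
    capabilities = c(can_sequence = TRUE, can_monitor = TRUE),
    run = function(stimulus, duration_s, seed = 0L) {
      if (is.null(con)) stop("tcp communicator needs options$tcp_con")
      tcp_send_events(con, stimulus)
      tcp_receive_events(con)
    })
  virt <- virtual_plugin_factory(setup, options)
  list(communicator = communicator, configurator = virt$configurator,
       mapper = virt$mapper)
}

.onLoad <- function(libname, pkgname) {
  register_plugin("virtual", virtual_plugin_factory)
  register_plugin("tcp", tcp_plugin_factory)
}
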