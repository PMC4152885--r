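# Translation between physical integer address-events and human-readable
# coordinate tuples, with channel multiplexing for multi-chip boards.
# Convention: bit i of a coordinate is carried by the i-th listed bit
# position of its field; channel bits occupy positions >= channel_offset.

#' Channel addressing for a multi-chip setup
#'
#' Bundles the per-channel source and destination address specifications of
#' a setup together with the board's channel offset, and provides the
#' context every encode/decode operation needs. Board-level physical
#' addresses are `(channel << channel_offset) | chip_address`.
#'
#' @param setup a `setup_description` from [parse_setup()].
#' @return an object of class `channel_addressing`.
#' @export
channel_addressing <- function(setup) {
  stopifnot(inherits(setup, "setup_description"))
  specs <- lapply(names(setup$channels), function(id) {
    chip <- setup$chips[[id]]
    list(chip_id = id, channel = setup$channels[[id]],
         source = chip$source_spec, destination = chip$dest_spec)
  })
  names(specs) <- as.character(unname(setup$channels))
  structure(list(setup = setup, channel_offset = setup$channel_offset,
                 specs = specs),
            class = "channel_addressing")
}

ca_spec <- function(ca, channel, direction) {
  s <- ca$specs[[as.character(channel)]]
  if (is.null(s))
    stop(sprintf("unknown channel %s (setup has channels %s)", channel,
                 paste(names(ca$specs), collapse = ", ")))
  spec <- s[[direction]]
  if (is.null(spec))
    stop(sprintf("chip '%s' on channel %s has no %s addresses",
                 s$chip_id, channel, direction))
  spec
}

#' Encode human-readable coordinates to physical addresses
#'
#' Scatters each coordinate's binary representation into its field's bit
#' positions (coordinate LSB to the first listed bit) and ORs in the
#' channel bits.
#'
#' @param ca a [channel_addressing()].
#' @param channel channel index (scalar).
#' @param coords data.frame (or coercible) with one column per field of the
#'   channel's specification; extra columns are ignored.
#' @param direction `"source"` or `"destination"`.
#' @return numeric vector of board-level physical addresses.
#' @export
encode_address <- function(ca, channel, coords,
                           direction = c("source", "destination")) {
  direction <- match.arg(direction)
  spec <- ca_spec(ca, channel, direction)
  spec_encode(spec, coords) + as.numeric(channel) * 2^ca$channel_offset
}

#' Decode physical addresses to human-readable coordinates
#'
#' The channel is extracted from the high bits, the remaining bits gathered
#' per field of that channel's specification. An address is invalid if its
#' channel is not in the setup, a decoded coordinate exceeds its field's
#' range, or bits outside every field are set.
#'
#' @param ca a [channel_addressing()].
#' @param phys numeric vector of physical addresses.
#' @param direction `"source"` or `"destination"`.
#' @param on_invalid `"error"` (default) or `"mark"`: with `"mark"`, a
#'   logical column `valid` flags undecodable addresses instead of failing
#'   (their coordinate columns are NA).
#' @return data.frame with columns `channel`, one column per field (union
#'   of all channels' fields; NA where a field does not exist on the
#'   event's channel) and, with `on_invalid = "mark"`, `valid`.
#' @export
decode_address <- function(ca, phys, direction = c("source", "destination"),
                           on_invalid = c("error", "mark")) {
  direction <- match.arg(direction)
  on_invalid <- match.arg(on_invalid)
  phys <- as.numeric(phys)
  n <- length(phys)
  all_fields <- unique(unlist(lapply(ca$specs, function(s)
    c(names(s$source$fields),
      if (!is.null(s$destination)) names(s$destination$fields)))))
  out <- data.frame(channel = rep(NA_integer_, n))
  for (f in all_fields) out[[f]] <- rep(NA_integer_, n)
  valid <- rep(FALSE, n)
  if (n == 0L) { out$valid <- logical(0); return(out) }

  chan <- phys %/% 2^ca$channel_offset
  rest <- phys %% 2^ca$channel_offset
  for (key in names(ca$specs)) {
    s <- ca$specs[[key]]
    idx <- which(chan == s$channel)
    if (length(idx) == 0L) next
    spec <- s[[direction]]
    if (is.null(spec)) next  # channel exists but has no such direction
    coords <- spec_decode(spec, rest[idx])
    ok <- rep(TRUE, length(idx))
    for (f in spec$fields) ok <- ok & coords[[f$name]] <= f$range
    # bits outside every field must be clear
    ok <- ok & (rest[idx] - spec_encode(spec, coords) == 0)
    for (nm in names(coords)) out[[nm]][idx[ok]] <- coords[[nm]][ok]
    out$channel[idx] <- as.integer(s$channel)
    valid[idx] <- ok
  }
  unknown_chan <- !(chan %in% vapply(ca$specs, `[[`, numeric(1), "channel"))
  if (on_invalid == "error") {
    if (any(unknown_chan))
      stop(sprintf("unknown channel %d for address %s",
                   chan[unknown_chan][1L],
                   format(phys[unknown_chan][1L], scientific = FALSE)))
    if (!all(valid))
      stop(sprintf("invalid address %s on channel %d",
                   format(phys[!valid][1L], scientific = FALSE),
                   chan[!valid][1L]))
  } else {
    out$channel[unknown_chan] <- NA_integer_
    out$valid <- valid
  }
  out
}

# ---- translation tables ----------------------------------------------------

coord_key <- function(coords, fields) {
  do.call(paste, c(lapply(fields, function(f) coords[[f]]), sep = "/"))
}

#' Build a cached translation table for one channel
#'
#' Enumerates every address of the channel's chip (optionally restricted to
#' named blocks) and precomputes the forward (HR to physical) and backward
#' (physical to HR) maps. The two maps are mutually inverse bijections.
#'
#' @param ca a [channel_addressing()].
#' @param channel channel index.
#' @param direction `"source"` or `"destination"`.
#' @param blocks optional block labels, as in [enumerate_addresses()].
#' @param cap maximum number of entries (default `2^24`); beyond it the
#'   arithmetic codec should be used directly.
#' @return an object of class `translation_table` with the entry
#'   data.frame in `$entries` (fields, `block`, `phys`).
#' @export
build_translation_table <- function(ca, channel,
                                    direction = c("source", "destination"),
                                    blocks = NULL, cap = 2^24) {
  direction <- match.arg(direction)
  spec <- ca_spec(ca, channel, direction)
  chip <- setup_chip_for_channel(ca$setup, channel)
  coords <- enumerate_addresses(chip, direction, blocks)
  if (nrow(coords) > cap)
    stop(sprintf("translation table would hold %d entries (cap %d); use the direct codec",
                 nrow(coords), cap))
  entries <- coords
  entries$block <- attr(coords, "block")
  entries$phys <- encode_address(ca, channel, coords, direction)
  structure(list(channel = as.integer(channel), direction = direction,
                 fields = names(spec$fields), entries = entries),
            class = "translation_table")
}

#' Forward lookup (HR coordinates to physical) in a translation table
#' @param tt a `translation_table`.
#' @param coords data.frame of coordinates.
#' @return numeric physical addresses (NA for entries not in the table).
#' @export
tt_encode <- function(tt, coords) {
  i <- match(coord_key(coords, tt$fields), coord_key(tt$entries, tt$fields))
  tt$entries$phys[i]
}

#' Backward lookup (physical to HR coordinates) in a translation table
#' @param tt a `translation_table`.
#' @param phys numeric physical addresses.
#' @return data.frame of coordinates (NA rows for unknown addresses).
#' @export
tt_decode <- function(tt, phys) {
  i <- match(phys, tt$entries$phys)
  tt$entries[i, c(tt$fields, "block"), drop = FALSE]
}

# ---- stream translation ----------------------------------------------------

#' Translate a raw event stream into per-channel coordinate streams
#'
#' Events are partitioned by decoded channel, order preserved within each
#' channel. Undecodable events are quarantined in a rejected stream with a
#' counter -- never silently dropped: `n_events(input)` always equals the
#' sum of translated and rejected counts.
#'
#' @param es an `event_stream` of physical addresses.
#' @param ca a [channel_addressing()].
#' @param direction `"source"` or `"destination"`.
#' @return list with `channels` (per-chip-id data.frames of coordinates
#'   plus `timestamp_us`), `rejected` (an `event_stream`) and `n_rejected`.
#' @export
translate_stream <- function(es, ca, direction = c("source", "destination")) {
  direction <- match.arg(direction)
  dec <- decode_address(ca, es$address, direction, on_invalid = "mark")
  out <- list()
  for (key in names(ca$specs)) {
    s <- ca$specs[[key]]
    spec <- s[[direction]]
    if (is.null(spec)) next
    idx <- which(dec$valid & dec$channel == s$channel)
    df <- dec[idx, names(spec$fields), drop = FALSE]
    df$timestamp_us <- es$timestamp_us[idx]
    rownames(df) <- NULL
    out[[s$chip_id]] <- df
  }
  rejected <- event_stream(es$address[!dec$valid], es$timestamp_us[!dec$valid])
  list(channels = out, rejected = rejected, n_rejected = nrow(rejected))
}
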