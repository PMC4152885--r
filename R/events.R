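# Event streams: ordered (physical address, timestamp) pairs, the universal
# currency of sequencing and monitoring. Timestamps are integer microseconds
# held as doubles (addresses can exceed 32-bit integer range once channel
# bits are prepended).

#' Construct an event stream
#'
#' Sorts by timestamp; simultaneous events are ordered by ascending address
#' so that streams are bit-exactly reproducible.
#'
#' @param address numeric vector of physical addresses (non-negative
#'   integers stored as doubles).
#' @param timestamp_us numeric vector of non-negative integer microseconds.
#' @return a data.frame of class `event_stream` with columns `address`,
#'   `timestamp_us`.
#' @export
event_stream <- function(address = numeric(0), timestamp_us = numeric(0)) {
  stopifnot(length(address) == length(timestamp_us))
  address <- as.numeric(address)
  timestamp_us <- floor(as.numeric(timestamp_us))
  if (any(timestamp_us < 0)) stop("timestamps must be non-negative")
  if (any(address < 0)) stop("addresses must be non-negative")
  o <- order(timestamp_us, address)
  structure(data.frame(address = address[o], timestamp_us = timestamp_us[o]),
            class = c("event_stream", "data.frame"))
}

as_event_stream <- function(df) {
  event_stream(df$address, df$timestamp_us)
}

#' Number of events in a stream
#' @param es an `event_stream`.
#' @return integer count.
#' @export
n_events <- function(es) nrow(es)

#' Concatenate event streams (re-sorted)
#' @param ... `event_stream` objects.
#' @return merged `event_stream`.
#' @export
bind_events <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0, logical(1))]
  if (length(parts) == 0L) return(event_stream())
  event_stream(unlist(lapply(parts, `[[`, "address")),
               unlist(lapply(parts, `[[`, "timestamp_us")))
}

#' Read / write event streams as CSV
#'
#' The interchange format is a two-column CSV with header
#' `address,timestamp_us`, addresses as decimal integers and timestamps as
#' integer microseconds. Round trips are bit-exact.
#'
#' @param file path.
#' @return [read_events()] returns an `event_stream`.
#' @export
read_events <- function(file) {
  df <- read.csv(file, colClasses = c("numeric", "numeric"))
  if (!identical(names(df), c("address", "timestamp_us")))
    stop(sprintf("'%s': expected header 'address,timestamp_us'", file))
  event_stream(df$address, df$timestamp_us)
}

#' @param es an `event_stream` to write.
#' @rdname read_events
#' @export
write_events <- function(es, file) {
  df <- data.frame(address = format(es$address, scientific = FALSE, trim = TRUE),
                   timestamp_us = format(es$timestamp_us, scientific = FALSE,
                                         trim = TRUE))
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
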