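# TCP event transport: address events travel as length-prefixed packets of
# little-endian 64-bit integers (address, timestamp_us per event), the
# packet prefix being the event count as a 64-bit little-endian integer.
# Values are held as R doubles; the transport is bit-exact for integers
# below 2^53, far beyond any address width used here.

write_u64le <- function(con, values) {
  lo <- values %% 2^32
  hi <- values %/% 2^32
  ints <- as.vector(rbind(lo, hi))             # lo word first: little-endian
  ints <- ifelse(ints >= 2^31, ints - 2^32, ints)
  writeBin(as.integer(ints), con, size = 4L, endian = "little")
}

read_u64le <- function(con, n) {
  raw <- readBin(con, "integer", n = 2L * n, size = 4L, endian = "little")
  if (length(raw) < 2L * n)
    return(structure(numeric(0), short = TRUE, got = length(raw) %/% 2L))
  u <- ifelse(raw < 0, raw + 2^32, raw)
  u[seq(1, length(u), 2)] + u[seq(2, length(u), 2)] * 2^32
}

#' Send an event stream over a binary connection
#'
#' Wire format: one packet per call -- a 64-bit little-endian event count,
#' then per event a 64-bit little-endian address and a 64-bit little-endian
#' timestamp in microseconds.
#'
#' @param con a binary-mode connection (e.g. a socket).
#' @param es an `event_stream`.
#' @return the number of events sent, invisibly.
#' @export
tcp_send_events <- function(con, es) {
  write_u64le(con, nrow(es))
  if (nrow(es) > 0L)
    write_u64le(con, as.vector(rbind(es$address, es$timestamp_us)))
  flush(con)
  invisible(nrow(es))
}

#' Receive one event packet from a binary connection
#'
#' Blocks until a full packet is read. A connection that closes mid-packet
#' raises a transport error of class `aerkit_transport_error` whose
#' `delivered` field counts the events received intact before the loss.
#'
#' @param con a binary-mode connection.
#' @return an `event_stream`.
#' @export
tcp_receive_events <- function(con) {
  cnt <- read_u64le(con, 1L)
  if (length(cnt) == 0L)
    stop(transport_error("connection closed before packet header", 0L))
  n <- cnt[1]
  if (n == 0) return(event_stream())
  vals <- read_u64le(con, 2 * n)
  if (length(vals) == 0L)
    stop(transport_error(
      sprintf("connection lost mid-packet (%d of %d events delivered)",
              attr(vals, "got") %/% 2L, n), attr(vals, "got") %/% 2L))
  idx <- seq(1, length(vals), 2)
  event_stream(vals[idx], vals[idx + 1])
}

transport_error <- function(msg, delivered) {
  structure(class = c("aerkit_transport_error", "error", "condition"),
            list(message = msg, call = sys.call(-1), delivered = delivered))
}

#' Loopback TCP event channel
#'
#' Opens a server socket on `127.0.0.1`, connects a client to it and
#' accepts the connection, returning both endpoints -- the harness used to
#' exercise the TCP transport without hardware or a remote peer.
#'
#' @param port TCP port; 0 tries random high ports until one is free.
#' @return list with binary connections `client` and `server` and a
#'   `close()` function releasing both.
#' @export
tcp_loopback <- function(port = 0) {
  if (port == 0) {
    srv <- NULL
    for (i in 1:20) {
      port <- sample(20000:60000, 1)
      srv <- tryCatch(serverSocket(port), error = function(e) NULL)
      if (!is.null(srv)) break
    }
    if (is.null(srv)) stop("could not find a free loopback port")
  } else srv <- serverSocket(port)
  on_fail <- function(e) { close(srv); stop(e) }
  client <- tryCatch(
    socketConnection("127.0.0.1", port, blocking = TRUE, open = "w+b",
                     timeout = 10),
    error = on_fail)
  server <- tryCatch(socketAccept(srv, blocking = TRUE, open = "w+b",
                                  timeout = 10),
                     error = function(e) { close(client); on_fail(e) })
  close(srv)
  list(client = client, server = server,
       close = function() {
         try(close(client), silent = TRUE)
         try(close(server), silent = TRUE)
       })
}
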