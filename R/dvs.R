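# Virtual dynamic vision sensor: per-pixel log-intensity change
# accumulators with threshold-and-subtract event generation (single
# polarity; the tracking demo projects columns and is polarity-blind).

#' Encode grayscale frames into retina address events
#'
#' For every pixel the absolute log-intensity change between consecutive
#' frames is accumulated; each time the accumulator reaches the contrast
#' threshold `C` one event is emitted at the frame's timestamp and `C` is
#' subtracted. Simultaneous events are ordered by raster order (which
#' coincides with ascending physical address for the bundled retina's
#' y-major address layout). Fully deterministic.
#'
#' @param frames 3-d array `[rows, cols, n_frames]` of intensities in
#'   `[0, 1]` (or a list of equal-size matrices).
#' @param times_us strictly increasing frame timestamps in microseconds.
#' @param C contrast threshold in log-intensity units; defaults to the
#'   chip's `c_thr` typical value.
#' @param chip the sensor's `chip_description` (default: the bundled
#'   64 x 64 retina). Its source fields must be `x` (columns) and `y`
#'   (rows).
#' @param eps intensity floor inside the logarithm.
#' @return `event_stream` of chip-local physical source addresses.
#' @export
dvs_encode <- function(frames, times_us, C = NULL, chip = retina_description(),
                       eps = 0.01) {
  if (is.list(frames)) frames <- simplify2array(frames)
  stopifnot(length(dim(frames)) == 3L)
  nr <- dim(frames)[1]; nc <- dim(frames)[2]; nf <- dim(frames)[3]
  if (length(times_us) != nf) stop("one timestamp per frame required")
  if (nf > 1 && any(diff(times_us) <= 0)) stop("frame times must be increasing")
  fx <- chip$source_spec$fields[["x"]]; fy <- chip$source_spec$fields[["y"]]
  if (is.null(fx) || is.null(fy))
    stop("sensor chip must have source fields 'x' and 'y'")
  if (nc != fx$range + 1 || nr != fy$range + 1)
    stop(sprintf("frame resolution %dx%d does not match the %dx%d sensor",
                 nr, nc, fy$range + 1, fx$range + 1))
  if (is.null(C)) {
    i <- match("c_thr", vapply(chip_parameters(chip), `[[`, character(1),
                               "access_key"))
    C <- if (is.na(i)) 0.1 else chip_parameters(chip)[[i]]$typical_value
  }
  if (C <= 0) stop("contrast threshold must be > 0")

  # physical addresses in raster order (row-major: y, then x)
  grid <- expand.grid(x = 0:(nc - 1), y = 0:(nr - 1), KEEP.OUT.ATTRS = FALSE)
  phys <- spec_encode(chip$source_spec, grid)  # index = y * nc + x + 1

  acc <- matrix(0, nr, nc)
  addr <- vector("list", nf)
  ts <- vector("list", nf)
  prev <- log(frames[, , 1] + eps)
  for (f in seq_len(nf)[-1]) {
    cur <- log(frames[, , f] + eps)
    acc <- acc + abs(cur - prev)
    prev <- cur
    k <- floor(acc / C)
    acc <- acc - k * C
    if (any(k > 0)) {
      idx <- which(k > 0)                      # column-major: y fastest
      x <- (idx - 1) %/% nr
      y <- (idx - 1) %% nr
      raster <- order(y, x)
      a <- rep(phys[y[raster] * nc + x[raster] + 1], k[idx][raster])
      addr[[f]] <- a
      ts[[f]] <- rep(times_us[f], length(a))
    }
  }
  event_stream(unlist(addr), unlist(ts))
}

#' Bundled chip descriptions
#'
#' Convenience accessors for the chip files shipped with the package: the
#' 124 + 4 neuron sWTA transceiver and the 64 x 64 silicon retina.
#'
#' @return a `chip_description`.
#' @export
retina_description <- function() {
  parse_nhml(system.file("extdata", "retina.nhml", package = "aerkit"))
}

#' @rdname retina_description
#' @export
ifslwta_description <- function() {
  parse_nhml(system.file("extdata", "ifslwta.nhml", package = "aerkit"))
}

#' Bundled two-chip demo setup (sWTA chip + retina)
#' @return a `setup_description`.
#' @export
demo_setup <- function() {
  parse_setup(system.file("extdata", "setup_demo.xml", package = "aerkit"))
}
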