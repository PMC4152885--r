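# Populations over chip address space and generation of connectivity
# look-up tables (the mapping between source and destination addresses).

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Ordered group of human-readable addresses on one chip
#'
#' @param chip_id owning chip identifier.
#' @param channel channel index of the chip in its setup.
#' @param direction `"source"` or `"destination"`.
#' @param coords data.frame of coordinates (one column per address field).
#' @param label free-text label.
#' @return an object of class `addr_group`; supports `length()` and `[`.
#' @export
addr_group <- function(chip_id, channel, direction, coords, label = "") {
  coords <- as.data.frame(coords)
  attr(coords, "block") <- NULL
  rownames(coords) <- NULL
  structure(list(chip_id = chip_id, channel = channel, direction = direction,
                 coords = coords, label = label),
            class = "addr_group")
}

#' @export
length.addr_group <- function(x) nrow(x$coords)

#' @export
`[.addr_group` <- function(x, i) {
  g <- addr_group(x$chip_id, x$channel, x$direction,
                  x$coords[i, , drop = FALSE], x$label)
  u <- attr(x, "unit")
  if (!is.null(u)) attr(g, "unit") <- u[i]
  g
}

#' @export
print.addr_group <- function(x, ...) {
  cat(sprintf("<addr_group '%s'> %d %s address(es) on chip '%s' (channel %d)\n",
              x$label, length(x), x$direction, x$chip_id, x$channel))
  invisible(x)
}

# shared coordinate fields between source and destination specs identify
# the neuron a synapse belongs to
neuron_fields <- function(chip) {
  intersect(names(chip$source_spec$fields),
            if (is.null(chip$dest_spec)) character(0) else names(chip$dest_spec$fields))
}

# derive per-label synapse groups physically wired to the given soma rows
derive_synapses <- function(chip, ca, channel, soma_coords) {
  if (length(chip$synapse_blocks) == 0L) return(list())
  nf <- neuron_fields(chip)
  soma_key <- coord_key(soma_coords, nf)
  out <- list()
  for (b in chip$synapse_blocks) {
    all_syn <- enumerate_addresses(chip, "destination", b$label)
    unit <- match(coord_key(all_syn, nf), soma_key)
    keep <- !is.na(unit)
    # order: by owning soma row, then enumeration order
    o <- order(unit[keep])
    coords <- all_syn[keep, , drop = FALSE][o, , drop = FALSE]
    g <- addr_group(chip$chip_id, channel, "destination", coords, b$label)
    attr(g, "unit") <- unit[keep][o]
    out[[b$label]] <- g
  }
  out
}

new_population <- function(name, chip, ca, channel, soma_coords, soma_labels) {
  soma <- addr_group(chip$chip_id, channel, "source", soma_coords, "soma")
  attr(soma, "block") <- soma_labels
  structure(list(name = name, chip_id = chip$chip_id, channel = channel,
                 chip = chip, ca = ca, soma = soma,
                 synapses = derive_synapses(chip, ca, channel, soma_coords)),
            class = "population")
}

#' @export
length.population <- function(x) length(x$soma)

#' @export
`[.population` <- function(x, i) {
  coords <- x$soma$coords[i, , drop = FALSE]
  labels <- attr(x$soma, "block")[i]
  new_population(x$name, x$chip, x$ca, x$channel, coords, labels)
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population '%s'> %d neuron(s) on chip '%s', synapse labels: %s\n",
              x$name, length(x), x$chip_id,
              paste(names(x$synapses), collapse = ", ") %||% "(none)"))
  invisible(x)
}

#' Linear population placement
#'
#' Selects the first `n` source addresses of a chip in enumeration order
#' (optionally restricted to blocks) and derives the synapse groups
#' physically wired to them.
#'
#' @param chip a `chip_description`.
#' @param ca the setup's [channel_addressing()].
#' @param n number of neurons requested.
#' @param blocks optional soma block labels to draw from.
#' @param name population name.
#' @return an object of class `population`.
#' @export
populate_linear <- function(chip, ca, n, blocks = NULL, name = "pop") {
  avail <- enumerate_addresses(chip, "source", blocks)
  if (n > nrow(avail))
    stop(sprintf("resource exhausted: requested %d neurons but only %d available on chip '%s'",
                 n, nrow(avail), chip$chip_id))
  idx <- seq_len(n)
  channel <- unname(ca$setup$channels[[chip$chip_id]])
  new_population(name, chip, ca, channel,
                 avail[idx, , drop = FALSE], attr(avail, "block")[idx])
}

#' Explicit population placement
#'
#' Builds a population over exactly the given soma coordinates, order
#' preserved, giving the modeler direct control over placement.
#'
#' @param chip a `chip_description`.
#' @param ca the setup's [channel_addressing()].
#' @param coords data.frame of soma coordinates (one column per source
#'   field of the chip).
#' @param name population name.
#' @return an object of class `population`.
#' @export
populate_explicit <- function(chip, ca, coords, name = "pop") {
  coords <- as.data.frame(coords)
  avail <- enumerate_addresses(chip, "source")
  fn <- names(chip$source_spec$fields)
  if (!all(fn %in% names(coords)))
    stop(sprintf("coordinates must have columns: %s", paste(fn, collapse = ", ")))
  key <- coord_key(coords, fn)
  if (anyDuplicated(key))
    stop("duplicate address in explicit placement")
  i <- match(key, coord_key(avail, fn))
  if (anyNA(i))
    stop(sprintf("address (%s) is not a source address of chip '%s'",
                 key[which(is.na(i))[1L]], chip$chip_id))
  channel <- unname(ca$setup$channels[[chip$chip_id]])
  new_population(name, chip, ca, channel,
                 avail[i, , drop = FALSE], attr(avail, "block")[i])
}

# board-level physical addresses of a population's soma / synapse group
soma_phys <- function(pop) {
  encode_address(pop$ca, pop$channel, pop$soma$coords, "source")
}
synapse_phys <- function(pop, label) {
  g <- pop$synapses[[label]]
  if (is.null(g))
    stop(sprintf("population '%s' has no synapse label '%s' (has: %s)",
                 pop$name, label, paste(names(pop$synapses), collapse = ", ")))
  encode_address(pop$ca, pop$channel, g$coords, "destination")
}

# ---- connection LUTs -------------------------------------------------------

#' Connection look-up table
#'
#' The canonical form of network connectivity: an ordered list of (source
#' physical address, destination physical address) pairs. Duplicated pairs
#' model connection weight by event fan-out and are only permitted when
#' `multiplicity = TRUE`.
#'
#' @param source,destination numeric vectors of physical addresses.
#' @param multiplicity allow duplicate pairs.
#' @return data.frame of class `connection_lut` with columns `source`,
#'   `destination`.
#' @export
connection_lut <- function(source = numeric(0), destination = numeric(0),
                           multiplicity = FALSE) {
  stopifnot(length(source) == length(destination))
  df <- data.frame(source = as.numeric(source),
                   destination = as.numeric(destination))
  if (!multiplicity && anyDuplicated(df))
    stop("duplicate (source, destination) pair; set multiplicity = TRUE to model weight by fan-out")
  structure(df, class = c("connection_lut", "data.frame"),
            multiplicity = multiplicity)
}

#' Connect two populations
#'
#' Generates the LUT entries pairing source soma addresses with destination
#' synapse addresses of the given label. When a target neuron owns several
#' synapse addresses of the label, successive connections onto it are
#' assigned round-robin over them (hardware synapses are a finite, shared
#' resource).
#'
#' @param src,dst `population` objects.
#' @param synapse synapse label on `dst` (e.g. `"excitatory"`).
#' @param scheme `"one_to_one"` (pairs i-th with i-th; sizes must match),
#'   `"all_to_all"`, or `"random_p"` (each ordered pair included
#'   independently with probability `p`).
#' @param p connection probability for `"random_p"`.
#' @param seed RNG seed, required for `"random_p"`; the result is
#'   deterministic given the seed.
#' @param exclude_self drop pairs whose source and target are the same
#'   physical neuron (only meaningful when the populations overlap).
#' @return a [connection_lut()].
#' @export
connect <- function(src, dst, synapse,
                    scheme = c("one_to_one", "all_to_all", "random_p"),
                    p = NULL, seed = NULL, exclude_self = FALSE) {
  scheme <- match.arg(scheme)
  n <- length(src); m <- length(dst)
  pairs <- switch(scheme,
    one_to_one = {
      if (n != m)
        stop(sprintf("one_to_one requires equal sizes (|src| = %d, |dst| = %d)",
                     n, m))
      cbind(seq_len(n), seq_len(n))
    },
    all_to_all = cbind(rep(seq_len(n), each = m), rep(seq_len(m), times = n)),
    random_p = {
      if (is.null(p) || p < 0 || p > 1)
        stop("random_p requires a probability p in [0, 1]")
      if (is.null(seed)) stop("random_p requires a seed")
      keep <- with_seed(seed, runif(n * m) < p)
      cbind(rep(seq_len(n), each = m), rep(seq_len(m), times = n))[keep, ,
                                                                   drop = FALSE]
    })
  sp <- soma_phys(src)
  g <- dst$synapses[[synapse]]
  if (is.null(g))
    stop(sprintf("population '%s' has no synapse label '%s' (has: %s)",
                 dst$name, synapse, paste(names(dst$synapses), collapse = ", ")))
  all_syn_phys <- synapse_phys(dst, synapse)
  unit <- attr(g, "unit")
  syn_by_unit <- split(all_syn_phys, unit)

  if (exclude_self && src$chip_id == dst$chip_id) {
    dp <- soma_phys(dst)
    pairs <- pairs[sp[pairs[, 1]] != dp[pairs[, 2]], , drop = FALSE]
  }
  if (nrow(pairs) == 0L) return(connection_lut())

  # round-robin synapse assignment per target neuron, in pair order
  j <- pairs[, 2]
  ord_within <- stats::ave(seq_along(j), j, FUN = seq_along) - 1L
  dest <- vapply(seq_along(j), function(k) {
    syn <- syn_by_unit[[as.character(j[k])]]
    syn[(ord_within[k] %% length(syn)) + 1L]
  }, numeric(1))
  connection_lut(sp[pairs[, 1]], dest)
}

#' Merge connection LUTs
#'
#' Concatenates in order; optionally de-duplicates repeated pairs (keeping
#' first occurrences).
#'
#' @param luts list of `connection_lut`.
#' @param deduplicate drop duplicate pairs.
#' @param multiplicity multiplicity flag of the result (default: inherited
#'   if any input allows duplicates and `deduplicate` is FALSE).
#' @return a [connection_lut()].
#' @export
merge_luts <- function(luts, deduplicate = FALSE, multiplicity = NULL) {
  if (length(luts) == 0L) return(connection_lut())
  stopifnot(all(vapply(luts, inherits, logical(1), "connection_lut")))
  src <- unlist(lapply(luts, `[[`, "source"))
  dst <- unlist(lapply(luts, `[[`, "destination"))
  if (is.null(multiplicity))
    multiplicity <- !deduplicate &&
      any(vapply(luts, function(l) isTRUE(attr(l, "multiplicity")), logical(1)))
  if (deduplicate) {
    keep <- !duplicated(data.frame(src, dst))
    src <- src[keep]; dst <- dst[keep]
  }
  if (!multiplicity && anyDuplicated(data.frame(src, dst)))
    stop("merged LUT contains duplicate pairs; set deduplicate or multiplicity")
  connection_lut(src, dst, multiplicity = multiplicity)
}

#' Read / write a connection LUT as CSV
#'
#' Two-column decimal CSV with header `source,destination`; round trips are
#' exact.
#'
#' @param file path.
#' @param multiplicity passed to [connection_lut()] when reading.
#' @return [read_lut()] returns a `connection_lut`.
#' @export
read_lut <- function(file, multiplicity = FALSE) {
  lines <- readLines(file)
  if (length(lines) == 0L || trimws(lines[1]) != "source,destination")
    stop(sprintf("'%s': expected header 'source,destination'", file))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) return(connection_lut(multiplicity = multiplicity))
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop(sprintf("'%s' line %d: expected two comma-separated columns", file,
                 bad[1L] + 1L))
  src <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
  dst <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  nn <- which(is.na(src) | is.na(dst))
  if (length(nn))
    stop(sprintf("'%s' line %d: not a decimal address", file, nn[1L] + 1L))
  connection_lut(src, dst, multiplicity = multiplicity)
}

#' @param lut a `connection_lut` to write.
#' @rdname read_lut
#' @export
write_lut <- function(lut, file) {
  writeLines(c("source,destination",
               if (nrow(lut)) paste(format(lut$source, scientific = FALSE,
                                           trim = TRUE),
                                    format(lut$destination, scientific = FALSE,
                                           trim = TRUE), sep = ",")),
             file)
  invisible(file)
}
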