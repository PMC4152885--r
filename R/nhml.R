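#' @useDynLib aerkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rexp rnorm runif
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

# ---- domain types ----------------------------------------------------------

#' Bit-field specification for one address coordinate
#'
#' A `field_spec` describes how one coordinate of a human-readable address
#' (e.g. the neuron index, or a pixel's x position) is laid out inside the
#' physical integer address word. `bits` lists the bit positions, least
#' significant first: bit `i` of the coordinate is carried by `bits[i + 1]`
#' of the physical word.
#'
#' @param name identifier of the coordinate dimension.
#' @param bits integer vector of distinct bit positions (LSB of the word = 0).
#' @param range maximum coordinate value; the coordinate spans `0:range`.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(name, bits, range) {
  bits <- as.integer(bits)
  range <- as.integer(range)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("field name must be a non-empty string")
  if (anyDuplicated(bits))
    stop(sprintf("field '%s': bit positions must be distinct", name))
  if (any(bits < 0L))
    stop(sprintf("field '%s': bit positions must be >= 0", name))
  if (range < 0L)
    stop(sprintf("field '%s': range must be >= 0", name))
  need <- if (range == 0L) 0L else ceiling(log2(range + 1))
  if (length(bits) < need)
    stop(sprintf("field '%s': %d bits cannot encode range %d", name,
                 length(bits), range))
  structure(list(name = name, bits = bits, range = range),
            class = "field_spec")
}

#' Address specification: ordered bit fields of a physical word
#'
#' @param direction `"source"` (events the chip emits) or `"destination"`
#'   (synapse addresses the chip accepts).
#' @param fields list of [field_spec()] objects; their declared order is the
#'   canonical coordinate order used throughout (enumeration is row-major
#'   with the last field varying fastest).
#' @param width total bit width of the physical word; defaults to one more
#'   than the highest used bit.
#' @return an object of class `address_spec`.
#' @export
address_spec <- function(direction = c("source", "destination"), fields,
                         width = NULL) {
  direction <- match.arg(direction)
  if (length(fields) < 1L)
    stop("address specification needs at least one field")
  stopifnot(all(vapply(fields, inherits, logical(1), "field_spec")))
  allbits <- unlist(lapply(fields, `[[`, "bits"))
  if (anyDuplicated(allbits)) {
    bad <- allbits[duplicated(allbits)][1L]
    owner <- vapply(fields, function(f) bad %in% f$bits, logical(1))
    stop(sprintf("overlapping bit position %d (field '%s')", bad,
                 fields[[which(owner)[2L] %||% which(owner)[1L]]]$name))
  }
  if (is.null(width)) width <- max(allbits) + 1L
  width <- as.integer(width)
  if (any(allbits >= width))
    stop("field bit position exceeds declared word width")
  names(fields) <- vapply(fields, `[[`, character(1), "name")
  if (anyDuplicated(names(fields)))
    stop("duplicate field name in address specification")
  structure(list(direction = direction, fields = fields, width = width),
            class = "address_spec")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Circuit or block parameter
#'
#' @param name identifier, unique within the owning chip.
#' @param units free-text units.
#' @param typical_value default numeric value applied when a backend is
#'   initialised.
#' @param access_key opaque key the configurator backend uses to address the
#'   parameter; defaults to `name`.
#' @return an object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, units = "", typical_value = NA_real_,
                           access_key = name) {
  structure(list(name = name, units = units,
                 typical_value = as.numeric(typical_value),
                 access_key = access_key),
            class = "parameter_spec")
}

#' Soma or synapse block of a chip
#'
#' A block selects a rectangular region of the chip's address space: for
#' every field of the governing address specification it gives an `offset`
#' and an `extent`, and its addresses are the cartesian product of the
#' per-field windows `offset:(offset + extent - 1)`.
#'
#' @param kind `"soma"` (source addresses) or `"synapse"` (destinations).
#' @param label block label, e.g. `"excitatory"`.
#' @param dims data.frame with columns `name`, `offset`, `extent`.
#' @param parameters list of [parameter_spec()] local to the block.
#' @return an object of class `block_spec`.
#' @export
block_spec <- function(kind = c("soma", "synapse"), label, dims,
                       parameters = list()) {
  kind <- match.arg(kind)
  dims <- as.data.frame(dims, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "offset", "extent") %in% names(dims)))
  dims$offset <- as.integer(dims$offset)
  dims$extent <- as.integer(dims$extent)
  if (any(dims$extent < 1L))
    stop(sprintf("block '%s': extents must be >= 1", label))
  if (any(dims$offset < 0L))
    stop(sprintf("block '%s': offsets must be >= 0", label))
  structure(list(kind = kind, label = label, dims = dims,
                 parameters = parameters),
            class = "block_spec")
}

#' Chip description
#'
#' The parsed form of an NHML chip file: the chip's soma blocks (possible
#' source address events), synapse blocks (targetable destination
#' addresses), the address specifications used for encoding/decoding, and
#' its parameter list.
#'
#' @param chip_id chip identifier.
#' @param soma_blocks list of [block_spec()] with kind `"soma"`.
#' @param synapse_blocks list of [block_spec()] with kind `"synapse"` (may
#'   be empty, e.g. for a pure sensor).
#' @param source_spec [address_spec()] with direction `"source"`.
#' @param dest_spec [address_spec()] with direction `"destination"`, or
#'   `NULL` for a chip with no synapse blocks.
#' @param parameters list of chip-level [parameter_spec()].
#' @return an object of class `chip_description`.
#' @export
chip_description <- function(chip_id, soma_blocks, synapse_blocks = list(),
                             source_spec, dest_spec = NULL,
                             parameters = list()) {
  chip <- structure(list(chip_id = chip_id, soma_blocks = soma_blocks,
                         synapse_blocks = synapse_blocks,
                         source_spec = source_spec, dest_spec = dest_spec,
                         parameters = parameters),
                    class = "chip_description")
  validate_chip(chip)
  chip
}

#' Validate a chip description against its invariants
#'
#' Checks block/field consistency, per-field windows against field ranges,
#' distinctness of the enumerable source and destination address sets, and
#' uniqueness of parameter access keys. Called by [chip_description()] and
#' [parse_nhml()]; exported for use by the `validate-chip` command line.
#'
#' @param chip a `chip_description`.
#' @return the chip, invisibly; errors describe the first violation found.
#' @export
validate_chip <- function(chip) {
  stopifnot(inherits(chip, "chip_description"))
  if (length(chip$soma_blocks) < 1L)
    stop(sprintf("chip '%s': at least one soma block required", chip$chip_id))
  if (length(chip$synapse_blocks) > 0L && is.null(chip$dest_spec))
    stop(sprintf("chip '%s': synapse blocks need a destination address specification",
                 chip$chip_id))
  check_blocks <- function(blocks, spec, what) {
    for (b in blocks) {
      if (b$kind != what)
        stop(sprintf("block '%s': expected kind '%s'", b$label, what))
      fn <- names(spec$fields)
      if (!setequal(b$dims$name, fn))
        stop(sprintf("chip '%s' block '%s': dimensions {%s} do not match %s fields {%s}",
                     chip$chip_id, b$label, paste(b$dims$name, collapse = ","),
                     spec$direction, paste(fn, collapse = ",")))
      for (i in seq_len(nrow(b$dims))) {
        f <- spec$fields[[b$dims$name[i]]]
        hi <- b$dims$offset[i] + b$dims$extent[i] - 1L
        if (hi > f$range)
          stop(sprintf("chip '%s' block '%s': window for field '%s' exceeds its range %d",
                       chip$chip_id, b$label, f$name, f$range))
      }
    }
  }
  check_blocks(chip$soma_blocks, chip$source_spec, "soma")
  if (length(chip$synapse_blocks) > 0L)
    check_blocks(chip$synapse_blocks, chip$dest_spec, "synapse")
  src <- enumerate_addresses(chip, "source")
  if (anyDuplicated(spec_encode(chip$source_spec, src)))
    stop(sprintf("chip '%s': source addresses are not distinct", chip$chip_id))
  if (length(chip$synapse_blocks) > 0L) {
    dst <- enumerate_addresses(chip, "destination")
    if (anyDuplicated(spec_encode(chip$dest_spec, dst)))
      stop(sprintf("chip '%s': destination addresses are not distinct",
                   chip$chip_id))
  }
  keys <- vapply(chip_parameters(chip), `[[`, character(1), "access_key")
  if (anyDuplicated(keys))
    stop(sprintf("chip '%s': duplicate parameter access key '%s'",
                 chip$chip_id, keys[duplicated(keys)][1L]))
  invisible(chip)
}

#' All parameters of a chip (chip-level plus block-level)
#' @param chip a `chip_description`.
#' @return flat list of `parameter_spec`.
#' @export
chip_parameters <- function(chip) {
  c(chip$parameters,
    unlist(lapply(c(chip$soma_blocks, chip$synapse_blocks),
                  `[[`, "parameters"), recursive = FALSE))
}

#' @export
print.chip_description <- function(x, ...) {
  nsrc <- nrow(enumerate_addresses(x, "source"))
  ndst <- if (length(x$synapse_blocks)) nrow(enumerate_addresses(x, "destination")) else 0L
  cat(sprintf("<chip '%s'> %d soma block(s) (%d source addresses), %d synapse block(s) (%d destination addresses), %d parameter(s)\n",
              x$chip_id, length(x$soma_blocks), nsrc,
              length(x$synapse_blocks), ndst, length(chip_parameters(x))))
  invisible(x)
}

# ---- chip-level scatter/gather codec (no channel bits) ---------------------

# scatter each coordinate's bits into its field positions and OR fields
spec_encode <- function(spec, coords) {
  coords <- as.data.frame(coords)
  out <- numeric(nrow(coords))
  for (f in spec$fields) {
    v <- coords[[f$name]]
    if (is.null(v)) stop(sprintf("missing coordinate '%s'", f$name))
    if (any(v < 0 | v > f$range))
      stop(sprintf("coordinate out of range for field '%s'", f$name))
    for (i in seq_along(f$bits))
      out <- out + (v %/% 2^(i - 1) %% 2) * 2^f$bits[i]
  }
  out
}

# inverse of spec_encode; does not check residual bits (caller's job)
spec_decode <- function(spec, phys) {
  out <- lapply(spec$fields, function(f) {
    v <- numeric(length(phys))
    for (i in seq_along(f$bits))
      v <- v + (phys %/% 2^f$bits[i] %% 2) * 2^(i - 1)
    as.integer(v)
  })
  as.data.frame(out, col.names = names(spec$fields), optional = TRUE)
}

# ---- enumeration -----------------------------------------------------------

#' Enumerate the human-readable addresses of a chip
#'
#' Produces the full cartesian enumeration of coordinates over the selected
#' blocks in the address specification's declared field order, the first
#' field varying fastest, blocks in declaration order.
#'
#' @param chip a `chip_description`.
#' @param direction `"source"` or `"destination"`.
#' @param blocks optional character vector of block labels to include;
#'   `NULL` selects all blocks of the direction.
#' @return data.frame with one column per field of the governing address
#'   specification and attribute `"block"` giving each row's block label.
#' @export
enumerate_addresses <- function(chip, direction = c("source", "destination"),
                                blocks = NULL) {
  direction <- match.arg(direction)
  if (direction == "source") {
    all_blocks <- chip$soma_blocks; spec <- chip$source_spec
  } else {
    all_blocks <- chip$synapse_blocks; spec <- chip$dest_spec
    if (length(all_blocks) == 0L)
      stop(sprintf("chip '%s' has no destination addresses", chip$chip_id))
  }
  labels <- vapply(all_blocks, `[[`, character(1), "label")
  if (!is.null(blocks)) {
    missing <- setdiff(blocks, labels)
    if (length(missing))
      stop(sprintf("unknown block label(s): %s", paste(missing, collapse = ", ")))
    all_blocks <- all_blocks[labels %in% blocks]
    labels <- labels[labels %in% blocks]
  }
  fn <- names(spec$fields)
  parts <- lapply(all_blocks, function(b) {
    wins <- lapply(fn, function(nm) {
      i <- match(nm, b$dims$name)
      seq.int(b$dims$offset[i], length.out = b$dims$extent[i])
    })
    # first declared field varies fastest: with LSB-first field layouts
    # this coincides with ascending physical address within a block
    g <- expand.grid(wins, KEEP.OUT.ATTRS = FALSE)
    names(g) <- fn
    g
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "block") <- rep(labels, vapply(parts, nrow, integer(1)))
  out
}

# ---- NHML parse / serialize ------------------------------------------------

#' Parse an NHML chip description
#'
#' Reads the XML chip-description dialect used by this package: a root
#' `<chip id=...>` containing one or two `<addressSpecification>` elements
#' (`direction` of `source` / `destination`, each with `<field name bits
#' range>` children, `bits` as comma-separated positions), `<soma>` and
#' `<synapse>` blocks with `<dim name offset extent>` children, and
#' `<parameters>` lists of `<parameter name units value key>`. Unknown
#' elements are ignored with a warning.
#'
#' @param x NHML document: a file path or a length-1 character XML string.
#' @return a validated [chip_description()].
#' @export
parse_nhml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e)
    stop(sprintf("malformed NHML document: %s", conditionMessage(e)), call. = FALSE))
  root <- xml2::xml_name(doc)
  if (root != "chip")
    stop(sprintf("expected root element <chip>, found <%s>", root))
  chip_id <- xml2::xml_attr(doc, "id")
  if (is.na(chip_id)) stop("<chip> element lacks an 'id' attribute")

  known <- c("addressSpecification", "soma", "synapse", "parameters")
  kids <- xml2::xml_children(doc)
  unk <- setdiff(unique(xml2::xml_name(kids)), known)
  if (length(unk))
    warning(sprintf("chip '%s': ignoring unknown element(s): %s", chip_id,
                    paste(unk, collapse = ", ")), call. = FALSE)

  parse_spec <- function(node) {
    dir <- xml2::xml_attr(node, "direction")
    flds <- lapply(xml2::xml_find_all(node, "field"), function(f) {
      bits <- as.integer(strsplit(xml2::xml_attr(f, "bits"), ",")[[1]])
      field_spec(xml2::xml_attr(f, "name"), bits,
                 as.integer(xml2::xml_attr(f, "range")))
    })
    w <- xml2::xml_attr(node, "width")
    address_spec(dir, flds, width = if (is.na(w)) NULL else as.integer(w))
  }
  parse_params <- function(node) {
    if (length(node) == 0L) return(list())
    lapply(xml2::xml_find_all(node[[1]], "parameter"), function(p) {
      key <- xml2::xml_attr(p, "key")
      nm <- xml2::xml_attr(p, "name")
      parameter_spec(nm, xml2::xml_attr(p, "units") %||% "",
                     as.numeric(xml2::xml_attr(p, "value")),
                     if (is.na(key)) nm else key)
    })
  }
  parse_block <- function(node, kind) {
    dims <- do.call(rbind, lapply(xml2::xml_find_all(node, "dim"), function(d) {
      off <- xml2::xml_attr(d, "offset")
      data.frame(name = xml2::xml_attr(d, "name"),
                 offset = if (is.na(off)) 0L else as.integer(off),
                 extent = as.integer(xml2::xml_attr(d, "extent")),
                 stringsAsFactors = FALSE)
    }))
    block_spec(kind, xml2::xml_attr(node, "label"), dims,
               parse_params(xml2::xml_find_all(node, "parameters")))
  }

  specs <- lapply(xml2::xml_find_all(doc, "addressSpecification"), parse_spec)
  dirs <- vapply(specs, `[[`, character(1), "direction")
  if (sum(dirs == "source") != 1L)
    stop(sprintf("chip '%s': exactly one source address specification required",
                 chip_id))
  src_spec <- specs[[which(dirs == "source")]]
  dst_spec <- if (any(dirs == "destination")) specs[[which(dirs == "destination")[1]]] else NULL

  soma <- lapply(xml2::xml_find_all(doc, "soma"), parse_block, kind = "soma")
  syn <- lapply(xml2::xml_find_all(doc, "synapse"), parse_block, kind = "synapse")
  pars <- parse_params(xml2::xml_find_all(doc, "./parameters"))

  chip_description(chip_id, soma, syn, src_spec, dst_spec, pars)
}

#' Serialize a chip description to NHML text
#'
#' @param chip a `chip_description`.
#' @return length-1 character: an XML document that [parse_nhml()] parses
#'   back to an equal chip description.
#' @export
serialize_nhml <- function(chip) {
  stopifnot(inherits(chip, "chip_description"))
  doc <- xml2::xml_new_root("chip", id = chip$chip_id)
  add_spec <- function(spec) {
    n <- xml2::xml_add_child(doc, "addressSpecification",
                             direction = spec$direction,
                             width = as.character(spec$width))
    for (f in spec$fields)
      xml2::xml_add_child(n, "field", name = f$name,
                          bits = paste(f$bits, collapse = ","),
                          range = as.character(f$range))
  }
  add_params <- function(parent, params) {
    if (length(params) == 0L) return()
    n <- xml2::xml_add_child(parent, "parameters")
    for (p in params)
      xml2::xml_add_child(n, "parameter", name = p$name, units = p$units,
                          value = format(p$typical_value, digits = 17),
                          key = p$access_key)
  }
  add_block <- function(b) {
    n <- xml2::xml_add_child(doc, b$kind, label = b$label)
    for (i in seq_len(nrow(b$dims)))
      xml2::xml_add_child(n, "dim", name = b$dims$name[i],
                          offset = as.character(b$dims$offset[i]),
                          extent = as.character(b$dims$extent[i]))
    add_params(n, b$parameters)
  }
  add_spec(chip$source_spec)
  if (!is.null(chip$dest_spec)) add_spec(chip$dest_spec)
  for (b in chip$soma_blocks) add_block(b)
  for (b in chip$synapse_blocks) add_block(b)
  add_params(doc, chip$parameters)
  as.character(doc)
}
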