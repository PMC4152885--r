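# Multi-chip setup descriptions: which chip sits on which AER channel, which
# backend plugins drive the boards, and where the channel bits live in a
# board-level address word.

#' Parse a multi-chip setup description
#'
#' A setup document names the chips of a board-level AER system, one per
#' channel, and the backend plugins used to talk to it:
#' ```xml
#' <setup name="demo" channelOffset="16">
#'   <chip id="ifslwta" channel="0" file="ifslwta.nhml"/>
#'   <chip id="retina"  channel="1" file="retina.nhml"/>
#'   <api communicator="virtual" configurator="virtual" mapper="virtual"/>
#' </setup>
#' ```
#' Board-level addresses are `(channel << channelOffset) | chip_address`.
#'
#' @param x setup document: file path or XML string.
#' @param resolver function mapping a chip `file` reference to something
#'   [parse_nhml()] accepts (path or XML text). Defaults to resolving paths
#'   relative to the setup file's directory when `x` is a path.
#' @return an object of class `setup_description` with elements `name`,
#'   `channels` (named integer vector channel -> chip_id), `chips` (list
#'   chip_id -> `chip_description`), `api_plugins` (named character) and
#'   `channel_offset`.
#' @export
parse_setup <- function(x, resolver = NULL) {
  is_path <- length(x) == 1L && !grepl("<", x, fixed = TRUE)
  if (is.null(resolver)) {
    base <- if (is_path) dirname(x) else "."
    resolver <- function(ref) {
      p <- if (file.exists(ref)) ref else file.path(base, ref)
      if (!file.exists(p))
        stop(sprintf("cannot resolve chip file '%s'", ref), call. = FALSE)
      p
    }
  }
  doc <- tryCatch(xml2::read_xml(x), error = function(e)
    stop(sprintf("malformed setup document: %s", conditionMessage(e)),
         call. = FALSE))
  if (xml2::xml_name(doc) != "setup")
    stop("expected root element <setup>")
  off <- as.integer(xml2::xml_attr(doc, "channelOffset"))
  if (is.na(off)) stop("<setup> lacks a 'channelOffset' attribute")

  chip_nodes <- xml2::xml_find_all(doc, "chip")
  if (length(chip_nodes) == 0L) stop("setup declares no chips")
  ch <- vapply(chip_nodes, function(n) as.integer(xml2::xml_attr(n, "channel")),
               integer(1))
  ids <- vapply(chip_nodes, function(n) xml2::xml_attr(n, "id"), character(1))
  files <- vapply(chip_nodes, function(n) xml2::xml_attr(n, "file"), character(1))
  if (anyDuplicated(ch))
    stop(sprintf("duplicate channel index %d in setup", ch[duplicated(ch)][1L]))
  if (anyDuplicated(ids))
    stop("duplicate chip id in setup")

  chips <- lapply(files, function(f) parse_nhml(resolver(f)))
  names(chips) <- ids
  for (i in seq_along(chips))
    if (chips[[i]]$chip_id != ids[i])
      stop(sprintf("chip file for '%s' declares id '%s'", ids[i],
                   chips[[i]]$chip_id))

  widths <- vapply(chips, function(c)
    max(c$source_spec$width, if (is.null(c$dest_spec)) 0L else c$dest_spec$width),
    integer(1))
  if (off < max(widths))
    stop(sprintf("channelOffset %d is below the widest chip address (%d bits)",
                 off, max(widths)))

  api_node <- xml2::xml_find_first(doc, "api")
  plugins <- c(communicator = "virtual", configurator = "virtual",
               mapper = "virtual")
  if (!inherits(api_node, "xml_missing")) {
    for (k in names(plugins)) {
      v <- xml2::xml_attr(api_node, k)
      if (!is.na(v)) plugins[[k]] <- v
    }
  }
  channels <- ch
  names(channels) <- ids
  structure(list(name = xml2::xml_attr(doc, "name") %||% "setup",
                 channels = channels, chips = chips,
                 api_plugins = plugins, channel_offset = off),
            class = "setup_description")
}

#' @export
print.setup_description <- function(x, ...) {
  cat(sprintf("<setup '%s'> channelOffset=%d\n", x$name, x$channel_offset))
  for (id in names(x$channels))
    cat(sprintf("  channel %d: chip '%s'\n", x$channels[[id]], id))
  cat(sprintf("  plugins: %s\n",
              paste(names(x$api_plugins), x$api_plugins, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

# chip_description for a given channel index
setup_chip_for_channel <- function(setup, channel) {
  i <- match(channel, setup$channels)
  if (is.na(i)) stop(sprintf("unknown channel %s in setup", channel))
  setup$chips[[names(setup$channels)[i]]]
}
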