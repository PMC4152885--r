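# Shared fixtures built in code: tiny chips, random chip generator for
# round-trip property tests, and a minimal two-chip setup.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

tiny_chip <- function(n = 4, chip_id = "tiny") {
  make_lif_chip_description(chip_id, n)
}

# smallest valid chip: one soma block, one neuron, 1-bit source spec
minimal_chip_xml <- paste0(
  '<chip id="mini">',
  '<addressSpecification direction="source" width="1">',
  '<field name="neuron" bits="0" range="0"/></addressSpecification>',
  '<soma label="only"><dim name="neuron" offset="0" extent="1"/></soma>',
  '</chip>')

# random valid chip description (for serialisation round trips)
random_chip <- function(seed) {
  with_seed(seed, {
    n_fields <- sample(1:3, 1)
    bits_pool <- sample(0:11)
    used <- 0L
    fields <- list()
    for (i in seq_len(n_fields)) {
      nb <- sample(1:3, 1)
      b <- bits_pool[used + seq_len(nb)]
      used <- used + nb
      rng <- sample(seq_len(2^nb) - 1L, 1)
      fields[[i]] <- field_spec(paste0("f", i), b, rng)
    }
    spec <- address_spec("source", fields, width = 12L)
    # one or two non-overlapping soma blocks along the first field
    f1max <- fields[[1]]$range
    e1 <- sample(seq_len(f1max + 1L), 1)
    dims1 <- do.call(rbind, lapply(fields, function(f)
      data.frame(name = f$name, offset = 0L,
                 extent = if (f$name == "f1") e1 else f$range + 1L)))
    blocks <- list(block_spec("soma", "a", dims1))
    if (e1 <= f1max && runif(1) < 0.5) {
      e2 <- sample(seq_len(f1max + 1L - e1), 1)
      dims2 <- dims1
      dims2$offset[dims2$name == "f1"] <- e1
      dims2$extent[dims2$name == "f1"] <- e2
      blocks <- c(blocks, list(block_spec("soma", "b", dims2)))
    }
    params <- if (runif(1) < 0.5)
      list(parameter_spec("bias one", "A", round(runif(1), 3), "b1"))
    else list()
    chip_description(paste0("rand", seed), blocks, list(), spec,
                     parameters = params)
  })
}

# in-memory two-chip setup (sWTA fixture chip + retina fixture chip)
demo_ca <- function() channel_addressing(demo_setup())

expect_equal_chip <- function(a, b) {
  expect_equal(a, b)
}

make_setup_xml <- function(dir, chips = c(ifslwta = 0L, retina = 1L),
                           offset = 16L) {
  src <- system.file("extdata", package = "aerkit")
  for (f in paste0(names(chips), ".nhml"))
    file.copy(file.path(src, f), file.path(dir, f), overwrite = TRUE)
  lines <- c(sprintf('<setup name="t" channelOffset="%d">', offset),
             sprintf('<chip id="%s" channel="%d" file="%s.nhml"/>',
                     names(chips), chips, names(chips)),
             '</setup>')
  path <- file.path(dir, "setup.xml")
  writeLines(lines, path)
  path
}
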