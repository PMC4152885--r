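# Chip and setup description parsing, validation, enumeration and
# serialisation round trips.

test_that("the bundled sWTA chip file yields the hardware's address counts", {
  chip <- ifslwta_description()
  expect_equal(nrow(enumerate_addresses(chip, "source", "excitatory")), 124)
  expect_equal(nrow(enumerate_addresses(chip, "source", "inhibitory")), 4)
  expect_equal(nrow(enumerate_addresses(chip, "source")), 128)
  expect_equal(nrow(enumerate_addresses(chip, "destination")), 256)
})

test_that("the bundled retina file yields a 64x64 pure event source", {
  chip <- retina_description()
  addrs <- enumerate_addresses(chip, "source")
  expect_equal(nrow(addrs), 64 * 64)
  expect_false(anyDuplicated(addrs) > 0)
  expect_equal(length(chip$synapse_blocks), 0L)
  expect_error(enumerate_addresses(chip, "destination"),
               "no destination addresses")
})

test_that("a minimal one-neuron document parses to a single source address", {
  chip <- parse_nhml(minimal_chip_xml)
  expect_s3_class(chip, "chip_description")
  expect_equal(nrow(enumerate_addresses(chip, "source")), 1L)
})

test_that("enumeration is row-major over declared fields, blocks in order", {
  chip <- ifslwta_description()
  src <- enumerate_addresses(chip, "source")
  expect_equal(src$neuron, 0:127)
  expect_equal(attr(src, "block"), rep(c("excitatory", "inhibitory"),
                                       c(124, 4)))
  # destination: neuron varies, then synapse fixed per block
  dst <- enumerate_addresses(chip, "destination", "inhibitory")
  expect_equal(unique(dst$synapse), 1L)
  expect_equal(dst$neuron, 0:127)
  # enumeration length = product of extents, summed over blocks
  ret <- retina_description()
  px <- enumerate_addresses(ret, "source")
  expect_equal(nrow(px), 64 * 64)
  expect_equal(px$x[1:3], 0:2)       # last declared field (x) varies fastest
  expect_equal(px$y[1:3], c(0L, 0L, 0L))
  expect_error(enumerate_addresses(chip, "source", "bogus"),
               "unknown block")
})

test_that("serialisation round-trips randomly generated chips", {
  for (seed in 1:50) {
    chip <- random_chip(seed)
    expect_equal(parse_nhml(serialize_nhml(chip)), chip,
                 label = sprintf("random chip %d", seed))
  }
  # fixtures round trip too, including block-level structure
  for (f in c("ifslwta.nhml", "retina.nhml")) {
    chip <- parse_nhml(system.file("extdata", f, package = "aerkit"))
    expect_equal(parse_nhml(serialize_nhml(chip)), chip)
  }
})

test_that("a sensor chip serialises without synapse elements", {
  txt <- serialize_nhml(retina_description())
  expect_false(grepl("<synapse", txt, fixed = TRUE))
})

test_that("validation rejects malformed or inconsistent descriptions", {
  expect_error(parse_nhml("<chip id='x'><oops"), "malformed")
  # overlapping bit positions across fields
  expect_error(address_spec("source",
                            list(field_spec("a", c(0, 1), 3),
                                 field_spec("b", c(1, 2), 3))),
               "overlapping bit position")
  # random corruptions: duplicate a bit of an existing spec
  for (seed in 1:20) {
    chip <- random_chip(seed)
    flds <- chip$source_spec$fields
    if (length(flds) < 2) next
    corrupt <- with_seed(seed, {
      i <- sample(seq_along(flds)[-1], 1)
      flds[[i]]$bits[1] <- flds[[1]]$bits[1]
      flds
    })
    expect_error(address_spec("source", corrupt), "overlapping",
                 label = sprintf("corruption %d", seed))
  }
  # too few bits for the range
  expect_error(field_spec("n", 0, 2), "cannot encode")
  # block window beyond the field range
  expect_error(
    chip_description("c",
                     list(block_spec("soma", "s",
                                     data.frame(name = "neuron", offset = 1L,
                                                extent = 2L))),
                     list(),
                     address_spec("source",
                                  list(field_spec("neuron", 0, 1)))),
    "exceeds its range")
  # dimension/field mismatch
  expect_error(
    chip_description("c",
                     list(block_spec("soma", "s",
                                     data.frame(name = "wrong", offset = 0L,
                                                extent = 1L))),
                     list(),
                     address_spec("source",
                                  list(field_spec("neuron", 0, 1)))),
    "do not match")
})

test_that("unknown NHML elements warn but do not fail", {
  txt <- sub("</chip>", "<gizmo/></chip>", minimal_chip_xml)
  expect_warning(chip <- parse_nhml(txt), "unknown element")
  expect_equal(chip$chip_id, "mini")
})

test_that("setup descriptions parse, resolve chips and validate channels", {
  dir <- withr::local_tempdir()
  s <- parse_setup(make_setup_xml(dir))
  expect_equal(length(s$channels), 2L)
  expect_equal(unname(s$channels[c("ifslwta", "retina")]), c(0L, 1L))
  expect_s3_class(s$chips$retina, "chip_description")

  s1 <- parse_setup(make_setup_xml(dir, chips = c(ifslwta = 0L)))
  expect_equal(length(s1$channels), 1L)

  # dangling chip file
  writeLines(c('<setup name="t" channelOffset="16">',
               '<chip id="gone" channel="0" file="gone.nhml"/></setup>'),
             file.path(dir, "bad.xml"))
  expect_error(parse_setup(file.path(dir, "bad.xml")), "cannot resolve")

  # duplicate channel index
  writeLines(c('<setup name="t" channelOffset="16">',
               '<chip id="ifslwta" channel="0" file="ifslwta.nhml"/>',
               '<chip id="retina" channel="0" file="retina.nhml"/></setup>'),
             file.path(dir, "dup.xml"))
  expect_error(parse_setup(file.path(dir, "dup.xml")), "duplicate channel")

  # channel offset below the widest chip
  expect_error(parse_setup(make_setup_xml(dir, offset = 4L)),
               "below the widest")
})
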