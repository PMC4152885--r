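# Populations, placement, slicing and LUT generation.

make_pops <- function(n_src = 4, n_dst = 4) {
  ca <- demo_ca()
  chip <- ca$setup$chips$ifslwta
  list(ca = ca,
       src = populate_linear(chip, ca, n_src, blocks = "excitatory", "src"),
       dst = populate_explicit(chip, ca,
                               data.frame(neuron = 60 + seq_len(n_dst) - 1L),
                               "dst"))
}

test_that("linear placement takes the first n addresses and enforces limits", {
  ca <- demo_ca()
  chip <- ca$setup$chips$ifslwta
  p <- populate_linear(chip, ca, 124, blocks = "excitatory")
  expect_equal(length(p), 124)
  expect_equal(p$soma$coords$neuron, 0:123)
  expect_named(p$synapses, c("excitatory", "inhibitory"))
  expect_equal(length(p$synapses$excitatory), 124)

  expect_equal(length(populate_linear(chip, ca, 0)), 0)
  expect_error(populate_linear(chip, ca, 125, blocks = "excitatory"),
               "resource exhausted")
})

test_that("explicit placement preserves order and validates addresses", {
  ca <- demo_ca()
  chip <- ca$setup$chips$ifslwta
  pe <- populate_explicit(chip, ca, data.frame(neuron = c(0L, 5L, 9L)))
  expect_equal(pe$soma$coords$neuron, c(0L, 5L, 9L))
  expect_equal(length(pe), 3)
  # equals linear selection when given the same addresses
  pl <- populate_linear(chip, ca, 3, blocks = "excitatory")
  pe2 <- populate_explicit(chip, ca, data.frame(neuron = 0:2))
  expect_equal(pe2$soma$coords, pl$soma$coords)

  expect_error(populate_explicit(chip, ca, data.frame(neuron = c(1L, 1L))),
               "duplicate")
  expect_error(populate_explicit(chip, ca, data.frame(neuron = 500L)),
               "not a source address")
  expect_error(populate_explicit(retina_description(), ca,
                                 data.frame(neuron = 0L)),
               "columns")
})

test_that("population slices are consistent subpopulations", {
  ca <- demo_ca()
  chip <- ca$setup$chips$ifslwta
  p <- populate_linear(chip, ca, 10, blocks = "excitatory")
  s <- p[c(2, 5, 7)]
  expect_equal(length(s), 3)
  expect_equal(s$soma$coords$neuron, c(1L, 4L, 6L))
  # synapse groups follow the selected somas
  expect_equal(s$synapses$excitatory$coords$neuron, c(1L, 4L, 6L))
  expect_equal(s$synapses$inhibitory$coords$neuron, c(1L, 4L, 6L))
})

test_that("one_to_one pairs i-th with i-th and rejects size mismatch", {
  ps <- make_pops(4, 4)
  lut <- connect(ps$src, ps$dst, "excitatory", "one_to_one")
  expect_equal(nrow(lut), 4)
  expect_equal(lut$source, soma_phys <- encode_address(ps$ca, 0,
                                                       data.frame(neuron = 0:3),
                                                       "source"))
  expect_equal(lut$destination,
               encode_address(ps$ca, 0,
                              data.frame(neuron = 60:63, synapse = 0L),
                              "destination"))
  ps2 <- make_pops(3, 5)
  expect_error(connect(ps2$src, ps2$dst, "excitatory", "one_to_one"),
               "equal sizes")
  expect_error(connect(ps$src, ps$dst, "plastic", "one_to_one"),
               "no synapse label")
})

test_that("all_to_all yields exactly n x m entries", {
  ps <- make_pops(3, 5)
  lut <- connect(ps$src, ps$dst, "excitatory", "all_to_all")
  expect_equal(nrow(lut), 15)
  expect_false(anyDuplicated(lut) > 0)
  for (nm in list(c(1, 1), c(2, 7), c(6, 6))) {
    ps2 <- make_pops(nm[1], nm[2])
    expect_equal(nrow(connect(ps2$src, ps2$dst, "inhibitory", "all_to_all")),
                 nm[1] * nm[2])
  }
})

test_that("random_p is seed-deterministic with per-pair Bernoulli counts", {
  ps <- make_pops(8, 8)
  a <- connect(ps$src, ps$dst, "excitatory", "random_p", p = 0.5, seed = 11)
  b <- connect(ps$src, ps$dst, "excitatory", "random_p", p = 0.5, seed = 11)
  expect_identical(a, b)
  c_ <- connect(ps$src, ps$dst, "excitatory", "random_p", p = 0.5, seed = 12)
  expect_false(identical(a, c_))
  expect_equal(nrow(connect(ps$src, ps$dst, "excitatory", "random_p",
                            p = 0, seed = 1)), 0)
  expect_equal(nrow(connect(ps$src, ps$dst, "excitatory", "random_p",
                            p = 1, seed = 1)), 64)
  expect_error(connect(ps$src, ps$dst, "excitatory", "random_p", p = 2,
                       seed = 1), "probability")
  expect_error(connect(ps$src, ps$dst, "excitatory", "random_p", p = 0.5),
               "seed")

  # empirical mean count within 3 sigma of Binomial(n*m, p) over 60 seeds
  n_pairs <- 64; p <- 0.3; n_seeds <- 60
  counts <- vapply(seq_len(n_seeds), function(s)
    nrow(connect(ps$src, ps$dst, "excitatory", "random_p", p = p, seed = s)),
    numeric(1))
  se <- sqrt(n_pairs * p * (1 - p) / n_seeds)
  expect_lt(abs(mean(counts) - n_pairs * p), 3 * se)
})

test_that("self-connections are included by default, excluded on request", {
  ps <- make_pops(4, 4)
  ca <- ps$ca
  chip <- ca$setup$chips$ifslwta
  same <- populate_linear(chip, ca, 4, blocks = "excitatory")
  full <- connect(same, same, "excitatory", "all_to_all")
  noself <- connect(same, same, "excitatory", "all_to_all",
                    exclude_self = TRUE)
  expect_equal(nrow(full), 16)
  expect_equal(nrow(noself), 12)
})

test_that("merging LUTs conserves entries and de-duplication is idempotent", {
  ps <- make_pops(3, 3)
  a <- connect(ps$src, ps$dst, "excitatory", "one_to_one")
  b <- connect(ps$src, ps$dst, "excitatory", "all_to_all")
  expect_equal(nrow(merge_luts(list())), 0)
  m <- merge_luts(list(a, b), multiplicity = TRUE)
  expect_equal(nrow(m), nrow(a) + nrow(b))
  # de-dup of two identical LUTs gives back the original
  dd <- merge_luts(list(a, a), deduplicate = TRUE)
  expect_equal(dd$source, a$source)
  expect_equal(dd$destination, a$destination)
  expect_error(merge_luts(list(a, a)), "duplicate")
})

test_that("LUT CSV round-trips exactly and rejects malformed lines", {
  ps <- make_pops(5, 5)
  lut <- connect(ps$src, ps$dst, "excitatory", "random_p", p = 0.7, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_lut(lut, f)
  back <- read_lut(f)
  expect_equal(back$source, lut$source)
  expect_equal(back$destination, lut$destination)

  writeLines("source,destination", f)
  expect_equal(nrow(read_lut(f)), 0)
  writeLines(c("source,destination", "1,2,3"), f)
  expect_error(read_lut(f), "line 2")
  writeLines(c("source,destination", "1,x"), f)
  expect_error(read_lut(f), "decimal")
  writeLines("nope", f)
  expect_error(read_lut(f), "header")
})
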