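# Virtual hardware: LIF dynamics against the closed form, sWTA topology
# and competition, DVS encoding, software mapper, TCP transport.

test_that("constant-current firing matches the closed-form LIF rate within 2%", {
  # rate = 1 / (t_ref + tau_m * ln(R I / (R I - theta)))
  for (i_const in c(1.2, 2, 4)) {
    vc <- virtual_chip(make_lif_chip_description("t", 2,
                                                 params = list(i_const = i_const)))
    res <- simulate_chip(vc, event_stream(), duration_s = 10, seed = 1)
    rate <- sum(res$spike_unit == 1) / 10
    expected <- 1 / (0.002 + 0.02 * log(i_const / (i_const - 1)))
    expect_lt(abs(rate - expected) / expected, 0.02,
              label = sprintf("I = %g: %.2f vs %.2f Hz", i_const, rate,
                              expected))
  }
})

test_that("silence in, silence out; one input spike, one current transient", {
  vc <- virtual_chip(make_lif_chip_description("t", 3))
  expect_equal(n_events(simulate_chip(vc, event_stream(), 1, seed = 1)$events),
               0)
  st <- event_stream(address = 1, timestamp_us = 5000)   # neuron 1, exc syn
  r <- simulate_chip(vc, st, 0.1, record = TRUE, record_unit = 2)
  expect_equal(max(r$i_trace), 0.5)                      # one deposit of w_exc
  expect_equal(sum(abs(diff(r$i_trace)) > 0.1), 1)       # a single jump
  expect_equal(length(r$spike_unit), 0)                  # subthreshold
  expect_error(simulate_chip(vc, event_stream(900, 0), 0.1),
               "not a destination")
})

test_that("identical seeds give bit-identical event streams", {
  vc <- build_swta_chip(n_exc = 12, n_inh = 2)
  stim <- with_seed(3, event_stream(sample(0:11, 500, replace = TRUE),
                                    sort(sample(0:999999, 500))))
  a <- simulate_chip(vc, stim, 1, seed = 9)
  b <- simulate_chip(vc, stim, 1, seed = 9)
  expect_identical(a$events, b$events)
})

test_that("sWTA wiring has the hardware's neighbourhood structure", {
  vc <- build_swta_chip()
  expect_equal(vc$n, 128)
  int <- vc$internal
  out_of <- function(i) int[int$src == i, ]
  # interior excitatory neuron: 6 lateral neighbours + 4 inhibitory targets
  mid <- out_of(60)
  expect_equal(sum(mid$wkey == "w_ee"), 6)
  expect_setequal(mid$dst[mid$wkey == "w_ee"], 60 + c(-3:-1, 1:3))
  expect_equal(sum(mid$wkey == "w_ei"), 4)
  # boundary neuron has fewer neighbours (line, not ring)
  expect_equal(sum(out_of(1)$wkey == "w_ee"), 3)
  # inhibitory neuron inhibits every excitatory neuron
  expect_equal(sum(out_of(125)$wkey == "w_ie"), 124)

  # small build: orders = 1 gives interior neurons 2 neighbours
  vs <- build_swta_chip(n_exc = 5, n_inh = 1, neighbor_orders = 1)
  expect_equal(sum(vs$internal$src == 3 & vs$internal$wkey == "w_ee"), 2)
  # lateral adjacency is symmetric
  ee <- vc$internal[vc$internal$wkey == "w_ee", c("src", "dst")]
  expect_setequal(paste(ee$src, ee$dst), paste(ee$dst, ee$src))
  expect_error(build_swta_chip(n_exc = 5, n_inh = 1), "too small")
})

test_that("the stronger of two inputs wins the sWTA competition", {
  vc <- build_swta_chip()
  g <- list(21:30, 81:90)
  sel <- swta_select(vc, g, c(800, 200), seed = 42)
  expect_equal(sel$winner, 1L)
  expect_gt(sel$rates_hz[1], 5 * sel$rates_hz[2])
  # single input: that group always wins
  solo <- swta_select(vc, g, c(500, 0), seed = 7)
  expect_equal(solo$winner, 1L)
  expect_error(swta_select(vc, list(1:5, 3:8), c(1, 1)), "disjoint")
})

test_that("DVS encodes log-contrast threshold crossings deterministically", {
  # identical frames: no events
  f <- array(0.5, dim = c(64, 64, 5))
  expect_equal(n_events(dvs_encode(f, (0:4) * 1e4)), 0)

  # single pixel step: exactly floor(delta_log / C) events at that pixel
  f2 <- array(0.0, dim = c(64, 64, 2))
  f2[11, 21, 2] <- 1
  C <- 0.1; eps <- 0.01
  ev <- dvs_encode(f2, c(0, 1e4), C = C, eps = eps)
  k_expected <- floor(abs(log(1 + eps) - log(eps)) / C)
  expect_equal(n_events(ev), k_expected)
  ret_ca <- retina_description()
  dec <- aerkit:::spec_decode(ret_ca$source_spec, unique(ev$address))
  expect_equal(dec$x, 20)
  expect_equal(dec$y, 10)
  expect_true(all(ev$timestamp_us == 1e4))

  # determinism
  ev2 <- dvs_encode(f2, c(0, 1e4), C = C, eps = eps)
  expect_identical(ev, ev2)
  expect_error(dvs_encode(array(0, c(10, 10, 2)), c(0, 1)), "resolution")
  expect_error(dvs_encode(f2, c(1e4, 0)), "increasing")
})

test_that("moving-bar events concentrate on the bar edges", {
  st <- make_bars_stimulus(duration_s = 0.5)
  ev <- dvs_encode(st$frames, st$times_us)
  dec <- aerkit:::spec_decode(retina_description()$source_spec, ev$address)
  # an event is edge-adjacent if within 1 column of either bar's position
  frame_of <- match(ev$timestamp_us, st$times_us)
  long <- which.max(st$lengths)
  ok <- abs(dec$x - st$truth$x[frame_of]) <= 1
  # also allow the short bar's edges
  short_x <- vapply(seq_len(dim(st$frames)[3]), function(f) {
    xs <- which(st$frames[st$y_pos[2] + 1, , f] > 0)
    if (length(xs)) xs[1] - 1L else NA_integer_
  }, integer(1))
  ok <- ok | abs(dec$x - short_x[frame_of]) <= 1
  expect_gt(mean(ok), 0.95)
})

test_that("the software mapper conserves fan-out exactly", {
  lut <- connection_lut(c(1, 1, 1, 2), c(10, 11, 12, 20),
                        multiplicity = TRUE)
  ev <- event_stream(c(1, 2, 3, 1), c(10, 20, 30, 40))
  out <- software_mapper_route(lut, ev)
  expect_equal(n_events(out$routed), 2 * 3 + 1)  # two spikes of 1, one of 2
  expect_equal(out$n_unmatched, 1)               # address 3 unmatched
  expect_equal(out$n_matched, 3)

  none <- software_mapper_route(connection_lut(), ev)
  expect_equal(n_events(none$routed), 0)
  expect_equal(none$n_unmatched, 4)

  # identity LUT echoes input addresses
  idlut <- connection_lut(1:5, 1:5)
  echo <- software_mapper_route(idlut, event_stream(1:5, rep(1, 5)))
  expect_equal(sort(echo$routed$address), 1:5)
})

test_that("TCP loopback delivers packets in order and bit-exact", {
  lb <- tcp_loopback()
  on.exit(lb$close())
  es <- with_seed(5, event_stream(sample(0:2^20, 1000, replace = TRUE),
                                  sort(sample(0:1e7, 1000, replace = TRUE))))
  tcp_send_events(lb$client, es)
  got <- tcp_receive_events(lb$server)
  expect_equal(got, es)
  # empty send -> empty receive
  tcp_send_events(lb$server, event_stream())
  expect_equal(n_events(tcp_receive_events(lb$client)), 0)
})

test_that("a mid-stream disconnect raises a transport error with the prefix intact", {
  lb <- tcp_loopback()
  on.exit(lb$close(), add = TRUE)
  # write a header promising 10 events but deliver only 3, then close
  aerkit:::write_u64le(lb$client, 10)
  aerkit:::write_u64le(lb$client, as.vector(rbind(1:3, 101:103)))
  flush(lb$client)
  close(lb$client)
  err <- tryCatch(tcp_receive_events(lb$server), error = function(e) e)
  expect_s3_class(err, "aerkit_transport_error")
  expect_equal(err$delivered, 3)
})
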