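# End-to-end experiments: bar stimulus geometry, FSM oracle, SSM synthesis
# book-keeping and the spiking runs at reduced scale.

test_that("the bar stimulus renders the declared geometry", {
  st <- make_bars_stimulus(duration_s = 0.5)
  # rendered pixel count per frame equals the summed bar lengths
  px <- apply(st$frames, 3, sum)
  expect_true(all(px == sum(st$lengths)))
  # ground truth of a +1 px/frame bar is a line of slope +1 until a bounce
  expect_equal(diff(st$truth$x[1:20]), rep(1L, 19))
  # static bars produce no events after the first frame
  stat <- make_bars_stimulus(velocity = c(0, 0), duration_s = 0.2)
  expect_equal(n_events(dvs_encode(stat$frames, stat$times_us)), 0)
  expect_error(make_bars_stimulus(lengths = c(5, 5)), "different lengths")
  expect_error(make_bars_stimulus(y_pos = c(60, 40)), "fit vertically")
})

test_that("the FSM oracle walks the sequence-detector diagram", {
  fsm <- seqdet_fsm()
  expect_setequal(fsm$states, c("Idle", "A0", "A1", "B0", "B1"))
  expect_setequal(fsm$symbols, c("L", "R", "CA", "CB", "x"))

  r <- fsm_oracle(fsm, c("CB", "R", "L"))
  expect_equal(r$states, c("Idle", "B0", "B1", "Idle"))
  expect_equal(which(r$detect), 3L)

  r2 <- fsm_oracle(fsm, c("CA", "L", "R"))
  expect_equal(r2$states, c("Idle", "A0", "A1", "Idle"))
  expect_equal(which(r2$detect), 3L)

  # undefined pairs leave the state unchanged; reset works from anywhere
  expect_equal(fsm_oracle(fsm, c("x"))$states, c("Idle", "Idle"))
  expect_equal(fsm_oracle(fsm, c("CA", "R"))$states, c("Idle", "A0", "A0"))
  r3 <- fsm_oracle(fsm, c("CA", "L", "x"))
  expect_equal(r3$states[4], "Idle")
  expect_false(any(r3$detect))
  expect_error(fsm_oracle(fsm, "Q"), "unknown symbol")
})

test_that("FSM files parse with headers, detection flags and error reporting", {
  f <- withr::local_tempfile(fileext = ".fsm")
  writeLines(c("# comment", "initial,S", "reset,z", "S,a,T", "T,b,S,detect"),
             f)
  fsm <- read_fsm(f)
  expect_equal(fsm$initial, "S")
  expect_equal(fsm$reset_symbol, "z")
  expect_equal(sum(fsm$transitions$detect), 1)
  # automatic reset arrows exist for every state
  expect_true(all(c("S", "T") %in%
                    fsm$transitions$state[fsm$transitions$symbol == "z"]))
  writeLines("S,a", f)
  expect_error(read_fsm(f), "cannot parse")
  expect_error(fsm_spec(data.frame(state = "S", symbol = "x",
                                   next_state = "T"),
                        initial = "S"),
               "must map every state")
})

test_that("SSM synthesis allocates the configured populations and LUT entries", {
  fsm <- seqdet_fsm()
  net <- build_ssm(fsm)
  expect_equal(unname(net$sizes["n_state"]), 32)
  expect_equal(unname(net$sizes["n_trans"]), 16)
  state_pops <- grep("^state:", names(net$pops), value = TRUE)
  expect_equal(length(state_pops), 5)
  expect_true(all(lengths(net$pops[state_pops]) == 32))
  # one transition population per non-self-loop arrow (6 explicit + 4 resets)
  trans_pops <- grep("^trans:", names(net$pops), value = TRUE)
  expect_equal(length(trans_pops), 10)
  expect_true(all(lengths(net$pops[trans_pops]) == 16))
  expect_equal(length(grep("^out:", names(net$pops))), 2)

  # LUT entry count matches the closed-form sum over the synthesis rules
  n_state <- 32; n_inh <- 16; n_trans <- 16; n_out <- 16
  n_states <- 5; n_arrow <- 10; n_det <- 2
  mult <- c(rec = 1, sp = 1, ps = 1, ts = 3, out = 1); k <- 15
  expected <- n_states * (n_state * (n_state - 1) * mult["rec"] +
                            n_state * n_inh * mult["sp"] +
                            n_inh * n_state * mult["ps"]) +
    n_arrow * (n_trans * k + n_trans * n_state * mult["ts"]) +
    n_det * n_trans * n_out * mult["out"]
  expect_equal(nrow(net$lut), unname(expected))

  # a one-state FSM with only the reset symbol: no transition populations
  one <- fsm_spec(data.frame(state = "Idle", symbol = "x",
                             next_state = "Idle"))
  net1 <- build_ssm(one)
  expect_equal(length(grep("^trans:", names(net1$pops))), 0)
  expect_equal(length(grep("^state:", names(net1$pops))), 1)
})

test_that("the spiking SSM follows the oracle on a short sequence", {
  net <- build_ssm(seqdet_fsm())
  r <- run_ssm(net, c("CA", "L", "R"), seed = 3)
  expect_equal(r$states, c("Idle", "A0", "A1", "Idle"))
  expect_equal(which(r$detect), 3L)
  expect_equal(r$detections$output, "A1:R")
  expect_error(run_ssm(net, "Q"), "unknown symbol")
})

test_that("a state population persists alone after inputs cease", {
  net <- build_ssm(seqdet_fsm())
  r <- run_ssm(net, "x", seed = 2, gap_s = 2.3)   # init volley, then silence
  ca <- net$ns$ca
  dec <- decode_address(ca, r$events$address, "source")
  unit <- dec$neuron + 1L
  late <- r$events$timestamp_us >= 0.5e6 & r$events$timestamp_us < 2.5e6
  idle_rate <- sum(unit %in% net$pops[["state:Idle"]] & late) / (32 * 2)
  others <- vapply(setdiff(grep("^state:", names(net$pops), value = TRUE),
                           "state:Idle"),
                   function(o) sum(unit %in% net$pops[[o]] & late) / (32 * 2),
                   numeric(1))
  expect_gt(idle_rate, 10)
  expect_gt(idle_rate, 5 * max(others, 0.1))
})

test_that("tracking follows the longer bar at reduced duration", {
  st <- make_bars_stimulus(duration_s = 1)
  tr <- run_tracking(st, seed = 1)
  expect_lte(tr$median_error, 2)
  expect_error(run_tracking(st, columns_per_neuron = 7), "divisible")
})
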