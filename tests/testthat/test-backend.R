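# Backend contracts: plugin loading, batch-run orchestration, bracket
# safety, parameter read-back and batch purity.

load_demo <- function(...) {
  load_plugins(demo_setup(),
               options = list(chip_models = list(ifslwta = build_swta_chip()),
                              ...))
}

test_that("plugin loading wires the named backends and rejects unknown ones", {
  ns <- load_demo()
  expect_s3_class(ns, "neuro_setup")
  expect_true(all(ns$communicator$capabilities))
  expect_true(is.function(ns$mapper$program))

  s <- demo_setup()
  s$api_plugins[["communicator"]] <- "tcp"
  ns2 <- load_plugins(s)
  expect_true(all(ns2$communicator$capabilities))

  s$api_plugins[["communicator"]] <- "nonexistent"
  expect_error(load_plugins(s), "registered plugins")
  expect_true(all(c("virtual", "tcp") %in% plugin_names()))
})

test_that("an empty run on a passive chip is silent", {
  ns <- load_demo()
  out <- setup_run(ns, connection_lut(), event_stream(), duration_s = 0.2)
  expect_equal(n_events(out), 0)
})

test_that("driving one synapse reproduces the direct chip simulation", {
  vc <- build_swta_chip()
  ns <- load_plugins(demo_setup(),
                     options = list(chip_models = list(ifslwta = vc)))
  ca <- ns$ca
  pop <- populate_linear(demo_setup()$chips$ifslwta, ca, 10,
                         blocks = "excitatory")
  stim <- poisson_trains(pop[3], 800, 0.5, seed = 6, target = "excitatory")
  out <- setup_run(ns, connection_lut(), stim, duration_s = 0.5, seed = 4)
  dec <- decode_address(ca, out$address, "source")
  expect_true(2 %in% dec$neuron)          # the driven neuron fires

  # the orchestrated run equals the bare simulation (seed offset by channel)
  base <- 0 * 2^16
  direct <- simulate_chip(vc, event_stream(stim$address - base,
                                           stim$timestamp_us),
                          0.5, seed = 4 + 0)
  expect_equal(out$address, direct$events$address + base)
  expect_equal(out$timestamp_us, direct$events$timestamp_us)
})

test_that("batch runs are pure: identical inputs give identical streams", {
  ns <- load_demo()
  pop <- populate_linear(demo_setup()$chips$ifslwta, ns$ca, 5,
                         blocks = "excitatory")
  stim <- poisson_trains(pop, 600, 0.3, seed = 2, target = "excitatory")
  a <- setup_run(ns, connection_lut(), stim, 0.3, seed = 11)
  b <- setup_run(ns, connection_lut(), stim, 0.3, seed = 11)
  expect_identical(a, b)
})

test_that("the runtime context exit runs even when the backend fails", {
  ns <- load_demo()
  log <- character(0)
  ctx <- runtime_context(enter = function() log <<- c(log, "enter"),
                         exit = function() log <<- c(log, "exit"))
  out <- setup_run(ns, connection_lut(), event_stream(), 0.1, context = ctx)
  expect_equal(log, c("enter", "exit"))

  # a stimulus with an unknown address makes the communicator fail after
  # context entry; the exit action must still run and the error propagate
  log <- character(0)
  bad <- event_stream(9 * 2^16 + 1, 0)
  expect_error(setup_run(ns, connection_lut(), bad, 0.1, context = ctx),
               "neither a destination nor a source")
  expect_equal(log, c("enter", "exit"))

  # a failing exit after a successful run surfaces as a warning
  ctx2 <- runtime_context(exit = function() stop("exit boom"))
  expect_warning(setup_run(ns, connection_lut(), event_stream(), 0.1,
                           context = ctx2), "exit boom")
})

test_that("stimulus beyond the run duration is rejected", {
  ns <- load_demo()
  late <- event_stream(0, 2e6)
  expect_error(setup_run(ns, connection_lut(), late, duration_s = 1),
               "beyond the run duration")
})

test_that("parameters default to NHML typical values with set/get read-back", {
  ns <- load_demo()
  chip <- demo_setup()$chips$ifslwta
  for (p in chip_parameters(chip))
    expect_equal(get_parameter(ns, "ifslwta", p$access_key), p$typical_value,
                 label = p$access_key)
  set_parameter(ns, "ifslwta", "theta", 1.5)
  expect_equal(get_parameter(ns, "ifslwta", "theta"), 1.5)
  expect_equal(get_parameter(ns, "retina", "c_thr"), 0.1)
  err <- tryCatch(get_parameter(ns, "ifslwta", "zap"), error = function(e) e)
  expect_match(conditionMessage(err), "unknown parameter key")
  expect_match(conditionMessage(err), "tau_m")       # lists available keys
  expect_error(set_parameter(ns, "ifslwta", "zap", 1), "unknown parameter")
})

test_that("configured parameters change the simulated dynamics", {
  ns <- load_demo()
  # raise the bias current above threshold: neurons fire with no stimulus
  set_parameter(ns, "ifslwta", "i_const", 1.5)
  set_parameter(ns, "ifslwta", "w_ie", 0)            # disable competition
  out <- setup_run(ns, connection_lut(), event_stream(), 0.3, seed = 1)
  expect_gt(n_events(out), 100)
})

test_that("online interaction delivers the same events incrementally", {
  ns <- load_demo()
  pop <- populate_linear(demo_setup()$chips$ifslwta, ns$ca, 3,
                         blocks = "excitatory")
  stim <- poisson_trains(pop, 700, 0.4, seed = 8, target = "excitatory")
  batch <- setup_run(ns, connection_lut(), stim, 0.4, seed = 2)
  ns$communicator$start(stim, 0.4, seed = 2)
  first <- ns$communicator$fetch(2e5)
  rest <- ns$communicator$fetch(4e5)
  ns$communicator$stop()
  expect_equal(bind_events(first, rest), batch)
})
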