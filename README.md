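# aerkit

A microkernel-style R toolkit for defining, configuring and running
spike-based **neuromorphic hardware setups** built on the Address Event
Representation (AER) — and a deterministic **virtual backend** that makes
the whole stack runnable and testable on a desktop with no hardware
attached.

Neuromorphic boards combine multi-neuron chips, event cameras and
programmable routers that all speak AER: every spike travels as the
integer address of the element that produced it, and network
connectivity is a routing table from source addresses to destination
synapse addresses. The software that drives such boards is usually a
monolith welded to one lab's hardware. `aerkit` instead separates the
layers the way an operating-system kernel does:

* **Hardware description** — an XML dialect describing each chip as
  soma blocks (source addresses), synapse blocks (destination
  addresses), bit-field *address specifications* and a typed parameter
  list; plus multi-chip *setup* files that put chips on bus channels and
  name the backend plugins that drive them
  (`parse_nhml()`, `serialize_nhml()`, `parse_setup()`).
* **Address codec** — bijective translation between physical integer
  events and human-readable coordinate tuples, with channel
  multiplexing, cached translation tables and loss-accounted stream
  translation (`encode_address()`, `decode_address()`,
  `build_translation_table()`, `translate_stream()`).
* **Network model** — neuron populations placed over chip address
  space and connectivity compiled to look-up tables:
  one-to-one, all-to-all and seeded per-pair Bernoulli wiring
  (`populate_linear()`, `populate_explicit()`, `connect()`,
  `read_lut()`/`write_lut()`).
* **Backend contracts** — communicator (sequence/monitor),
  configurator (keyed parameter get/set) and mapper (LUT programming)
  plugin interfaces, with exception-safe runtime contexts and a batch
  `setup_run()` orchestrator (`load_plugins()`, `set_parameter()`).
* **Virtual hardware** — leaky integrate-and-fire transceiver chips
  with current-based exponential synapses
  (`dv/dt = (−v + R·I)/τ_m`; threshold θ, reset, refractory period), a
  hard-wired soft winner-take-all (sWTA) multi-neuron chip (124
  excitatory + 4 inhibitory neurons), a 64×64 event-camera model, a
  software mapper and a bit-exact TCP event transport
  (`build_swta_chip()`, `simulate_chip()`, `dvs_encode()`,
  `tcp_send_events()`).
* **Experiments** — two end-to-end replications: a retina-driven sWTA
  that selects and tracks the stronger of two moving visual stimuli
  (`run_tracking()`), and *soft state machines*: finite-state machines
  synthesised from coupled winner-take-all circuits, with state held as
  persistent activity and transitions fired by state–symbol coincidence
  detection (`build_ssm()`, `run_ssm()`, `fsm_oracle()`).

## Worked example

```r
library(aerkit)

## the bundled multi-neuron chip file
chip <- ifslwta_description()
print(chip)
#> <chip 'ifslwta'> 2 soma block(s) (128 source addresses),
#>   2 synapse block(s) (256 destination addresses), 14 parameter(s)

## random 50% wiring between two 64-neuron populations
setup <- demo_setup()
ca    <- channel_addressing(setup)
p_ret <- populate_linear(setup$chips$ifslwta, ca, 64, blocks = "excitatory")
p_wta <- populate_linear(setup$chips$ifslwta, ca, 64, blocks = "excitatory")
lut   <- connect(p_ret, p_wta, "excitatory", scheme = "random_p",
                 p = 0.5, seed = 1)
nrow(lut)
#> [1] 2120        # of 4096 possible pairs, ~51.8%

## selective amplification on the virtual sWTA chip:
## two 10-neuron groups driven at 800 Hz vs 200 Hz
vc  <- build_swta_chip()
sel <- swta_select(vc, list(21:30, 81:90), c(800, 200), seed = 1)
#> winner: group 1   rates: 71.6 vs 0.2 Hz
```

The stronger input group fires at ~72 Hz while the weaker is almost
fully suppressed — the selective amplification that lets the chip track
the larger of two visual stimuli.

```r
## a soft state machine detecting the two-symbol sequence (R, L)
net <- build_ssm(seqdet_fsm())
print(net)
#> <ssm_network> 5 states x 32, 10 transitions x 16, 2 outputs x 16,
#>   pool 16; 28352 LUT entries

r <- run_ssm(net, c("CB", "R", "L"), seed = 1)
r$states
#> [1] "Idle" "B0"   "B1"   "Idle"
r$detections
#>   step output time_us
#> 1    3   B1:L 1600000
```

The spiking network walks `Idle → B0 → B1`, and the third symbol
completes the armed sequence: the output population crosses its
detection threshold at t = 1.6 s and the state returns to Idle — exactly
the trajectory of the pure finite-state-machine oracle
(`fsm_oracle(seqdet_fsm(), c("CB","R","L"))`).

A thin command line lives in `inst/cli/aerkit`
(`validate-chip`, `compile-lut`, `run-ssm`, `run-tracking`), e.g.

```sh
Rscript inst/cli/aerkit run-ssm --sequence "CB,R,L" --seed 2 --out-prefix ssm
```

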