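---
title: "aerkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aerkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The abstraction: chips as address-event transceivers

`aerkit` models a spike-based neuromorphic setup as a collection of
re-configurable *address-event transceivers*: devices that consume
destination address events (synaptic inputs) and/or produce source address
events (neuron or pixel spikes) over a shared asynchronous bus using the
Address Event Representation (AER). Everything the toolkit does — chip
description, address translation, population placement, look-up-table
routing, monitoring, sequencing — is phrased in terms of that minimal
contract, so the same front end drives a silicon multi-neuron array, an
event camera, or the bundled virtual backend.

A *chip file* (an XML dialect this package defines, with root `chip`,
`addressSpecification`, `soma`/`synapse` blocks and `parameters`) declares:

* **address specifications** — ordered bit fields mapping coordinate
  tuples to physical integer addresses. Convention: bit *i* of a
  coordinate is carried by the *i*-th listed bit position of its field
  (LSB first); channel-select bits for multi-chip boards occupy positions
  at and above the setup's `channelOffset`.
* **soma blocks** — rectangular windows (per-field `offset` + `extent`)
  of source addresses. Offsets are needed so that, e.g., 124 excitatory
  neurons at indices 0–123 and 4 inhibitory neurons at 124–127 enumerate
  without collisions.
* **synapse blocks** — destination address windows; a pure sensor such
  as the retina has none, and then has no destination address
  specification either.
* **parameters** — name, units, typical value and an opaque access key
  per parameter. Block-level parameters use access keys
  `"<block>.<key>"` and override the chip-level value for that block's
  neurons in the virtual backend.

Address enumeration is the cartesian product over the declared field
sequence with the **first declared field varying fastest**; for LSB-first
layouts this coincides with ascending physical address within a block,
and with raster order for the retina. All coordinates are 0-based.
Deterministic enumeration is what makes linear placement reproducible.

## Codec and data model

`encode_address()` scatters coordinates into bit fields and ORs in the
channel bits; `decode_address()` inverts it and treats as invalid any
address with an unknown channel, an out-of-range coordinate, or stray
bits outside every field. Stream translation never drops events
silently: undecodable events land in a rejected stream with a counter,
so `|input| = |translated| + |rejected|` always holds — real AER buses
glitch, and batch analyses must survive that.

Event streams are data frames of `(address, timestamp_us)` sorted by
time with ties broken by ascending address, which makes every output
bit-reproducible. Timestamps are integer microseconds held in doubles
(addresses can exceed 32-bit integer range once channel bits are
prepended; doubles are exact far beyond any width used here).

Connectivity is a look-up table (LUT) of `(source, destination)`
physical address pairs — the most explicit form of a routing table, to
which any compressed scheme can be reduced. Duplicated pairs model
connection strength by event fan-out and must be enabled explicitly
(`multiplicity = TRUE`). `connect()` supports one-to-one (equal sizes
required; silent truncation would hide placement bugs), all-to-all, and
per-pair Bernoulli wiring (`random_p`, seeded). When a target neuron
owns several synapse addresses of a label, successive connections are
assigned round-robin; the assignment wraps around, because a strict
no-reuse policy would make all-to-all impossible on chips with one
synapse circuit per type per neuron. Self-connections are kept by
default (`exclude_self = FALSE` flips this).

## The virtual backend

The silicon neuron and synapse circuits of the modelled chips are not
published as equations, so the virtual backend uses an explicit,
idealized stand-in whose fidelity claim is *behavioural* (selection,
persistence, tracking), not circuit-level:

* leaky integrate-and-fire somas,
  `dv/dt = (−v + R·I_total)/τ_m`, threshold `θ`, reset `v_reset`,
  refractory `t_ref`;
* two current-based exponential synapse channels per neuron
  (excitatory, inhibitory): an input event adds the receiving synapse's
  weight to the channel current, which decays with `τ_s`.

Integration is fixed-step forward Euler at `dt = 0.1 ms` with exact
exponential current decay, spikes propagating with a one-step delay, and
optional seeded Gaussian current noise. Fixed-step determinism was
chosen over event-driven elegance: bit-exact reproducibility is what the
test suite and the batch-purity contract need. Against the closed-form
noiseless LIF rate `1/(t_ref + τ_m ln(RI/(RI − θ)))` the simulator is
within 0.2% at the default `dt`, comfortably inside the 2% the
acceptance suite demands, and converges as `dt → 0`.

Chip-level defaults (`τ_m` 20 ms, `R` 1, `θ` 1 V, `v_reset` 0,
`t_ref` 2 ms, `τ_s` 5 ms) are ordinary cortical-neuron scales; weights
are per-fixture and documented below.

The virtual multi-neuron chip (`build_swta_chip()`) hard-wires the soft
winner-take-all topology: 124 excitatory neurons in a line (no
wrap-around — the array tracks a horizontal position, so a ring would
join the two screen edges) with 1st/2nd/3rd nearest-neighbour
excitation, and 4 inhibitory neurons that receive excitation from every
excitatory neuron and inhibit them all. The virtual DVS accumulates
per-pixel absolute log-intensity changes and emits one event per
threshold crossing (threshold-and-subtract, single polarity — the
tracking demo projects columns and is polarity blind). The software
mapper routes each produced event to every matching LUT entry with exact
fan-out accounting, and the TCP transport moves length-prefixed packets
of little-endian 64-bit `(address, timestamp)` words, bit-exactly.

Backend contracts are deliberately narrow: the communicator's `run`
expects and returns *physical* addresses only; the configurator is a
keyed get/set with read-back consistency and NHML typical values as
defaults; the mapper is `program`/`route`. `setup_run()` fixes the
orchestration order (program LUT → configurator flush → context enter →
run → context exit), the exit action being an exception-safe bracket:
it runs even when the backend fails, and the failure is re-raised only
afterwards. Parameter changes during a batch run are rejected — batch
runs are pure functions of (parameters, LUT, stimulus, seed), which the
suite verifies bit-exactly. A closed routing loop (LUT entries from a
chip's somas back to its own synapses) is simulated inside the chip's
integration loop with one-step delay; loops across two dynamical chips
would require co-simulation no demo needs and are rejected.

## Experiment 1: retina-driven tracking

`make_bars_stimulus()` renders two bright vertical bars of different
length (defaults 20 px and 6 px, 1 px wide) sliding horizontally in
opposite directions at 1 px/frame, 100 frames/s, bouncing at the frame
edges. Bars are vertical segments because the demo's signal is the
*column* projection: a moving vertical bar changes every pixel of its
leading and trailing columns each frame, so the event count per column
is proportional to bar length — the longer bar is the stronger stimulus.
(A solid horizontal bar moving horizontally only changes its two end
pixels and would make both bars equally strong.)

`run_tracking()` wires the full stack: DVS encoding → board-level
stimulus on the retina channel → a column-projection LUT (every pixel of
a column group to the excitatory synapse of one sWTA neuron; two columns
per neuron by default, so 32 of the 124 neurons are used) →
`setup_run()` → monitors. The decoded winner is the per-100-ms-bin
argmax of excitatory spike counts, scored as the median absolute
difference to the longer bar's ground-truth column group (median, not
maximum, because occasional jumps to the shorter bar are part of the
expected behaviour). Before the run the experiment sets three biases
through the configurator — retina input weight 0.0033, excitatory-to-
inhibitory weight 0.8, current noise 5 — because the dense DVS burst
drive (tens of events per pixel crossing) is roughly two orders of
magnitude stronger than the Poisson drive the chip file's typical
weights are sized for; configuring biases to the stimulus regime before
a run is part of the modelled workflow. With the defaults the median
winner error is ≈1 neuron index over 3-second runs.

## Experiment 2: soft state machines

A finite-state machine is synthesised onto coupled winner-take-all
circuits: one 32-neuron population per state holding the current state
as persistent activity, one 16-neuron transition population per
non-self-loop `(state, symbol)` arrow (including the automatic
reset-symbol arrows), 16-neuron output populations for detection-flagged
arrows, and a shared 16-neuron inhibitory pool. The synthesis LUT
implements: (a) all-to-all recurrent excitation within each state
population; (b) state → pool excitation and pool → state inhibition
(the competition); (c) sparse excitation from a state population plus
the external symbol line onto its transition population, each component
at ≈0.55–0.6 of threshold so only the coincidence fires it; (d) strong
(≈3× threshold) transition → next-state excitation; (e) transition →
output excitation. Connection strengths are realised by LUT entry
multiplicity over a per-block weight quantum.

Getting persistent activity stable in a spiking LIF network required
three deliberate choices, made once and frozen as defaults:

* **long excitatory synapses** (`τ_s` = 50 ms). With 5 ms synapses and a
  20 ms refractory period the state population synchronises into
  all-or-nothing bursts whose recurrent charge decays away during the
  refractory hold — the attractor cannot survive its own refractoriness.
  Slow (NMDA-like) excitation is the classical stabiliser of persistent
  activity, and it works here for the same reason.
* **a refractory rate cap on state neurons** (`t_ref` = 20 ms, max
  50 Hz). Operating the attractor in the refractory-dominated regime
  flattens the steep LIF f–I curve, which otherwise makes the fixed
  point knife-edged, and bounds runaway excitation.
* **mild membrane noise** (current s.d. 2.5, ≈0.125 of threshold after
  membrane filtering) to desynchronise the population and smooth the
  effective transfer function; subthreshold margins (≥3σ) keep false
  coincidences negligible.

The inhibitory pool is fast and low-threshold (refractory 5 ms, weight
quantum 0.025): nearly silent while one state is active, strongly
recruited when two are, which is exactly the switch dynamics rule (d)
relies on. The receiving-weight quanta (state 0.08, pool 0.025,
transition 0.025, output 0.08) and the rule multiplicities
(`rec` 1, `sp` 1, `ps` 1, `ts` 3, `out` 1, sparse fan-in 15) were
selected by a coarse grid search over the two state-side weights at four
seeds and then validated unchanged on unseen seeds and random symbol
sequences (exact oracle agreement, including detections).

Symbols are delivered as 200 ms Poisson volleys at 480 Hz per transition
neuron with 300 ms silent gaps (unstated in the source setting; chosen
so both persistence across the gap and switching within the volley
succeed), the network is initialised by one volley to the initial
state's population, and the decoded state of a step is the
highest-rate state population in the second half of the following gap
(all-zero windows keep the previous state). A detection is an output
population exceeding 20 Hz in any 50 ms bin of a step. Undefined
`(state, symbol)` pairs leave the state unchanged — the full transition
diagram of the source is not printed, so the stay-put rule is a declared
assumption, configurable through the FSM file; detections return to
Idle because the detection arrows themselves target Idle.

## What the synthetic data does and does not show

The generators (bar frames + DVS model, Poisson/regular trains, random
NHML documents) reproduce the *configurations* of the replicated setups:
the 124 + 4 sWTA array, the 64×64 retina, the 32/16-neuron SSM sizes,
the 50% random wiring example. They do not emulate analog device
mismatch, AER bus arbitration or collisions, transmission latency, or
sensor noise; passing tests therefore demonstrate that the kernel's
book-keeping (description, translation, routing, orchestration) is
exact and that the network-level behaviours are achievable under
idealized dynamics — not that a particular piece of silicon will
reproduce them with these constants.

## Numerical choices and degenerate inputs

* `dt` 0.1 ms; timestamps floor-quantised to integer microseconds.
* Equal-timestamp events order by ascending address everywhere.
* Empty streams, empty LUTs, empty populations and header-only CSV
  files are valid and round-trip.
* Translation tables are capped (default 2^24 entries) with an error
  advising the arithmetic codec.
* The Poisson generator draws i.i.d. exponential gaps and truncates at
  the duration; the regular generator floor-quantises `phase + k/rate`.
* Population rate series normalise the final partial bin by its actual
  width.

## Problem sizes in the test suite

The suite exercises the full fixture sizes for everything combinatorial
(all 128 + 4096 fixture addresses exhaustively; 200-seed connectivity
statistics; 10^4-event table-equivalence and TCP checks). The spiking
experiments run at the full fixture network sizes but desk-scale
durations: 1 s winner-take-all trials (150 of them), 20-symbol sequences
(~10 s of simulated time each, 20 seeds), 2.5 s persistence probes and
1–3 s tracking runs — sizes chosen so the statistical criteria are
well-powered while the whole suite stays in a couple of minutes.

## Known limitations

* One dynamical chip per closed routing loop (cross-chip feedback would
  need co-simulation).
* Monitor/sequencer address specifications may differ per direction and
  channel; no claim is made that real boards allow this.
* The TCP transport is exercised on loopback only; no real-time
  guarantees are modelled.
* No placement optimisation or parameter-calibration routines: the
  configurator exposes the surface such methods would use, but the
  algorithms are out of scope.
* Tagged event payloads (weights/delays in the event word) are not
  supported; the demos do not use them.
* The state machine's coincidence gate has bounded headroom: raising the
  symbol input rate well above the default (roughly doubling it) pushes
  the symbol drive alone past threshold and *degrades* accuracy rather
  than improving it. Making doubling safe (symbol ≤ 0.45, state ≥ 0.65
  of threshold) leaves the state drive too close to threshold for the
  default noise and destroys baseline reliability, so the margins are
  frozen for the default operating point.
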