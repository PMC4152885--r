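Package: aerkit
Title: Definition, Configuration and Virtual Emulation of Address-Event
    Neuromorphic Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A microkernel-style toolkit for spike-based neuromorphic
    hardware setups built on the Address Event Representation (AER).
    Provides an XML chip/setup description language with address
    specifications, bidirectional translation between physical integer
    addresses and human-readable coordinates, population placement over
    chip address space, look-up-table (LUT) connectivity generation,
    abstract communicator/configurator/mapper backend contracts, and a
    deterministic virtual backend (leaky integrate-and-fire transceiver
    chips, an event-camera model, a software mapper and a TCP event
    transport) so that complete experiments -- selective amplification
    and tracking with a soft winner-take-all network, and soft state
    machines performing sequence detection -- run on a desktop with no
    hardware attached.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
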