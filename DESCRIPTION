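Package: ctmsim
Title: Discrete-Time Simulation of the Conscious Turing Machine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time simulator of the Conscious Turing Machine (CTM),
    a formal Global-Workspace-style cognitive architecture in which many
    long-term-memory processors compete through a probabilistic binary
    tournament tree for a single short-term-memory slot whose content is
    globally broadcast every tick. Implements the chunk algebra (weight,
    intensity, mood), additive competition functions, the coin-flip-neuron
    tournament with an exact dynamic-programming win-probability oracle,
    Down-Tree broadcast, Hebbian-style link formation with unconscious
    link communication, Sleeping-Experts intensity adaptation, memory
    archives with salience pruning, a sleep/wake/dream state machine, and
    executable scenarios (blindsight, inattentional blindness, change
    blindness, dream creation, self/not-self attribution) that turn the
    architecture's qualitative predictions into assertable event traces.
    Traces are deterministic given a master seed and replay byte-exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
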