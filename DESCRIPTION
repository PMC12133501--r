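Package: exotremor
Title: Simulation and Reinforcement-Learning Control of Tremor-Suppressing
    Soft Exoskeletons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coupled seven degree-of-freedom biomechanical simulation of
    Parkinsonian tremor propagation in the human arm, a cable-driven soft
    exoskeleton actuation model, a gym-style reinforcement-learning
    environment with a five-term shaped reward and per-episode dynamics
    randomization, and a TD7 actor-critic learner (twin critics, learned
    state and state-action embeddings, loss-adjusted prioritized replay
    split into per-movement sub-buffers, pink-noise exploration, policy
    checkpointing) that learns to suppress synthetic two-harmonic tremors
    across shoulder and elbow joint axes during dynamic reference
    movements.  Includes an evaluation protocol computing tremor amplitude
    suppression and occurrence metrics over all tremor-axis combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
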