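Package: edsim
Title: Trust-Aware Discrete-Event Simulation of Emergency Department Task Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, reproducible discrete-event agent-based simulator of
    nurse task allocation in an emergency department. Doctors examine patients
    and broadcast nursing task requests with a difficulty level and an expected
    duration; nurses claim requests under either a first-in-first-out policy or
    a computational trust model in which each nurse tracks per-level trust
    weights from outcome feedback and self-assesses its own reliability.
    Staffing responses to a self-assessed low performer (difficulty capping,
    replacement by an extra high performer, or mentoring with gradual skill
    gain) are simulated over a shift, with per-run, per-doctor and per-nurse
    metrics (patients served, time damage, patient delay, task success and
    failure counts, utility, evaluation accuracy), an event log that fully
    determines the metrics, and a seeded batch-experimentation and
    statistical-comparison layer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
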