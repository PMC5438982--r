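Package: apisim
Title: Closed-Loop Aversive Visual Conditioning of Walking Bees: Protocols, Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for operant aversive visual-conditioning assays of walking
    honeybees in a two-field linear chamber (the APIS paradigm): builders for
    closed-loop trial and shock schedules, an agent-based random-walk simulator
    of phototactic, shock-avoiding bees with associative learning and a
    wavelength-dependent safety prior, readers and writers for position-trace
    and event-log files, the behavioral metric pipeline (preference index,
    actual and fictive shock counts, pre- and post-onset speeds, speed change,
    exclusion filtering, cohort summaries), saturating (Michaelis-Menten)
    intensity-preference curve fitting with zero-preference estimation, and
    simple group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
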