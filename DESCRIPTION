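Package: sedentr
Title: Smartphone Sedentary-Behaviour Context Mining
Version: 0.1.0
Authors@R:
    person("sedentr", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Desk-scale re-implementation of a two-stage smartphone
    sedentary-behaviour context miner. Tri-axial accelerometer windows are
    orientation-corrected (gravity/dynamic decomposition) and summarised by
    mean, standard deviation and energy features; a k-nearest-neighbour
    classifier labels each 3-second window as still or active. When a
    one-minute epoch is judged still, an 8-second sample of environmental
    audio is reduced to MFCC statistics and a second k-NN stage assigns a
    micro-context (watching TV, working on a PC, or sedentary-unknown),
    re-checked every fifteen minutes while sedentary. Includes a labelled
    synthetic sensor simulator, behaviour analytics (hourly/daily/weekly
    totals, short breaks, period comparisons), plain-text readers/writers
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
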