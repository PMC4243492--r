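Package: visattn
Title: Executive Control of a Selective-Tuning Visual Attention Hierarchy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A runnable model of executive control for covert and overt visual
    attention in the Selective Tuning tradition. Provides a small retinotopic
    feature pyramid with top-down priming, surround suppression and pathway
    inhibition; theta-winner-take-all selection and recurrent top-down
    localization producing attentional samples; fixation control with
    peripheral priority, fixation-history and history-biased priority maps
    implementing location- and object-based inhibition of return; associative
    method memory, a visual working-memory blackboard and a task notepad; and
    a script engine that executes cognitive-program graphs for discrimination,
    covert and overt search, localization and curve tracing on synthetic
    displays generated by the package's own stimulus laboratory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
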