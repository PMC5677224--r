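Package: contextfuse
Title: Multi-Level Cross-Domain Context Fusion for Behavior Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses multimodal low-level context streams (activity, location,
    emotion, food and clinical readings) into high-level physical-activity,
    nutrition and clinical health-state contexts, and derives weekly and daily
    behavioral contexts with a temporal rule engine.  Raw blood glucose, blood
    pressure and water-intake readings are banded into clinical context labels;
    concurrent events are synchronized per user with a sliding window;
    candidate high-level contexts are classified against declarative class
    definitions carrying existential and universal restrictions with automatic
    closure; and six conjunctive temporal rules with aggregation builtins turn
    the classified history into lifestyle labels such as Sedentary Behavior.
    Includes a seeded synthetic multi-user stream generator with ground truth,
    an evaluation module (confusion matrix, precision/recall/F), and a
    deterministic Turtle/N-Triples export of the context graph.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
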