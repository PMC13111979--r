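Package: fanmem
Title: Fan-Effect Memory Experiments, Skip-Gram Embeddings, and Spreading Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating fan-effect memory experiments and linking them to
    vector-space models of word meaning. Constructs classic and semantic fan stimulus
    designs (person-location study sentences with re-paired foils), trains skip-gram
    models with negative sampling on the resulting target-context pairs, extracts
    spreading-activation estimates as shifted dot products (a pointwise mutual
    information approximation), maps activation to predicted retrieval latency and
    accuracy through standard ACT-R linking functions, and provides a sign-binarized
    cue model for comparison. Includes generators for synthetic clustered embedding
    spaces and for behavioral trial data with shifted log-normal reaction times, plus
    the cleaning, exclusion, contrast-coding, and condition-summary steps used to
    analyze recognition data from such experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
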