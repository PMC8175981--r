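Package: wordtrust
Title: Bayesian Word Learning with Socially Informed Epistemic Trust
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A generative Bayesian model of early word learning in which
    speakers belong to social groups with characteristic knowledgeability.
    Knowledgeable speakers always produce the correct object label;
    unknowledgeable speakers commit to a single label chosen uniformly at
    random and repeat it consistently. The package provides exact posterior
    inference over the object category and per-speaker knowledgeability by
    enumeration, a Gibbs sampler for larger speaker sets,
    Kullback-Leibler-divergence measures of how informative a labeling
    event is about speaker knowledgeability (a looking-time index), a
    seeded synthetic-corpus generator, and turn-key runners for a familiar
    word recognition simulation and a Switch-task habituation simulation
    with single versus multiple speakers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
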