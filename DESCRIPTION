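Package: msrecap
Title: Age-Structured Multistate Capture-Recapture Models for Colony and
    Breeding-Status Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation for age-structured multistate
    (Arnason-Schwarz type) capture-recapture models in which marked females
    move among four live states defined by colony and breeding status, with
    an explicit dead state.  Provides a declarative model-notation language
    for effect structures on survival, first-breeding, dispersal and
    recapture probabilities, a product-multinomial likelihood evaluated by
    forward recursion, AIC ranking with Akaike weights and model averaging
    with unconditional standard errors, derived life-history summaries
    (mean age at first reproduction, life expectancy, reproductive years),
    and a capture-history simulator that reproduces the study design of a
    long-term two-colony mouse-eared bat monitoring programme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
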