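Package: hmmdissect
Title: Score Dissection and Statistical Re-Evaluation of Profile-HMM Domain Hits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects profile hidden Markov model sequence-to-domain alignment
    scores into fold-critical and remnant (non-globular) sums, re-evaluates each
    sum through the model's extreme-value statistics to obtain fold-critical and
    remnant E-values, rescues false-negative yet fold-related hits, and ranks
    merged glocal/local hits by an error-adjusted domain-coverage score and a
    total false-positive-rate stratification. Includes parsers and writers for
    HMMER2 and HMMER3 text profiles, per-column fold-critical/remnant annotation
    from DSSP strings or a weighted combination of sequence-property predictors
    (conservation, secondary structure, low complexity, globularity), empirical
    false-positive-rate calibration tables, and a synthetic fixture generator so
    the whole framework is testable without external binaries or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
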