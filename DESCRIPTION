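Package: intervalbias
Title: Interval Bias and Contraction-of-Memory Models for 2AFC Frequency Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two-alternative forced-choice (2AFC)
    tone-frequency discrimination experiments run under adaptive 3-down-1-up
    staircases. Implements history-sensitive probit observer models in which
    the remembered first tone is contracted toward a running memory trace of
    past first tones, maximum-likelihood fitting of observer noise with
    multistart derivative-free optimization, BIC model comparison, and the
    full battery of interval-bias statistics (reference-position and
    higher-tone performance splits, response-rate controls, Bias+/Bias- and
    Repeat/Alternate trial classifications, JND estimation and subset JND
    ratios). Reads deposited trial matrices in MAT 5.0 format and round-trips
    trial tables as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
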