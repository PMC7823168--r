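Package: cryptdrift
Title: Neutral-Drift Clone Dynamics and Bayesian Inference for
    Intestinal Lineage Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of pulse-chase lineage-tracing data from
    intestinal crypts and glands. Implements the neutral-drift model of stem
    cell replacement as a one-dimensional random walk with absorbing
    boundaries, including the closed-form clone-size distribution, survival
    conditioning, redistribution of clone sizes into eighths, and a
    label-accrual delay. Provides exact stochastic simulation of clone fates,
    Bayesian inference of stem cell number, replacement rate and delay from
    binned clone counts by Markov chain Monte Carlo, and a spatial pipeline
    that bins clones by distance from a tumour, tests each bin against
    wild-type drift via a Monte Carlo null distribution of the multinomial
    likelihood, and re-infers the replacement rate in divergent and
    consistent subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
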