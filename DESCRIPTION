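Package: discectomyCEA
Title: Cost-Effectiveness of Lumbar Discectomy with Worker-Productivity Offsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort cost-utility model comparing surgical (discectomy)
    and nonsurgical management of lumbar disc herniation in a working-age,
    privately insured population. Implements the full societal-perspective
    pipeline: a synthetic survey-microdata generator emulating the structure
    of national health-interview data, least-squares and negative-binomial
    (NB2) regressions linking a functional-limitations index to household
    earnings and missed workdays, human-capital valuation of productivity
    offsets, annual-cycle Markov simulation with revision surgery as a
    temporary state, incremental cost-effectiveness ratios with and without
    productivity offsets, time-horizon sweeps, and one-way sensitivity
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
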