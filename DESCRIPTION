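Package: wheatnr
Title: Nitrogen Responsiveness Analysis of Wheat Grain Filling and Yield
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the nitrogen (N) responsiveness of winter
    wheat cultivars from multi-environment field trials. Fits the
    four-parameter Richards growth equation to post-anthesis grain-weight
    series and decomposes grain filling into slow-, fast- and
    slight-increase phases with closed-form rates and phase boundaries;
    fits linear-plus-plateau yield-N response curves to estimate N
    responsiveness (Nr), critical N supply (Ncs) and maximum yield; derives
    the chlorophyll degradation rate from flag-leaf SPAD decline; computes
    nitrogen budgets (accumulation, translocation, nutrition index against
    a critical dilution curve) and N use-efficiency indices; estimates
    per-cultivar sensitivity slopes of traits to N supply and decomposes
    yield-component contributions by path analysis. A synthetic field-trial
    generator with known ground truth supports end-to-end testing of the
    full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
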