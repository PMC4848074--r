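Package: eslqueue
Title: Integrated Patient and Staff Satisfaction Modelling for Queueing-Based Care Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the trade-off between patient satisfaction with waiting
    time and staff satisfaction with service time in a single-server (M/G/1)
    care process. Provides hyperbolic-tangent satisfaction curve models for
    both parties, the Pollaczek-Khinchine queueing link between service time
    and waiting time, a discrete-event simulator as an independent check, a
    synthetic Likert survey generator emulating an accident-and-emergency
    staff interview design, nonlinear least-squares recovery of the
    double-tanh staff model, and the Effective Satisfaction Level (ESL)
    optimisation that locates the operating point best trading off both
    parties' satisfaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
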