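Package: cellsizer
Title: Simulation and Statistics for Cell-Size Homeostasis in Animal Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting cell-size sensing in proliferating animal
    cell populations. Provides an agent-based growth-and-division simulator
    with configurable size-sensing regimes (sizer, timer, adder; optional
    age-windowed growth-rate feedback), the snapshot variance analysis that
    yields the coefficient of growth-rate variation (Gcv) as a function of
    cell age, cell-cycle checkpoint contrasts, time-lapse track statistics
    (birth-size versus G1-length coupling with permutation nulls, lagged
    size-growth correlations, extreme-decile convergence), and bulk
    proliferation kinetics (exponential cell-cycle length fits, per-cell
    growth rate from bulk mass accumulation, and target-size invariance
    v * tau across perturbed conditions).
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
    withr
Config/testthat/edition: 3
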