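Package: nadphaxis
Title: Cofactor-Ledger Energetics of NAD+-Independent Glucose Oxidation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact-rational stoichiometric bookkeeping for metabolic cofactor
    ledgers, with a shipped pathway library covering the pentose phosphate
    pathway, futile fatty-acid cycling (idealized per-acetyl-CoA and exact
    palmitate modes), the citrate shuttle and glycolysis plus the citric acid
    cycle. Converts ledgers to ATP equivalents under configurable P/O ratios,
    solves the NADPH-balancing multiplicity that couples the pentose phosphate
    pathway to fatty-acid cycling (the NADPH-FADH2 axis), partitions the axis
    between liver and adipose tissue with ketone and lactate return transport
    and redox-closure checking, estimates the fraction of ingested glucose
    routed through the axis from whole-animal metabolic inefficiency, screens
    curated metabolic gene sets in differential-expression tables under
    platform-specific thresholds, and simulates scenario-driven synthetic
    expression tables for testing the screen.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
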