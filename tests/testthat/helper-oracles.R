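# Independent oracles (brute-force enumeration, grid search, expanded
# midrank ranks, lm() refits). Shipped with the package under inst/oracles
# so the acceptance script can reuse them; sourced here into the test
# environment.
source(system.file("oracles", "oracles.R", package = "binqtl"), local = TRUE)
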