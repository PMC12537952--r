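#!/usr/bin/env Rscript
# One-shot pipeline: simulate -> medians -> mixture fits + bootstrap ->
# rank tests -> bioenergetics indices -> respirometry states -> factorial
# contrasts, all into a single output directory with a JSON manifest.
suppressPackageStartupMessages(library(mitomotor))

run_pipeline("results/run_all", seed = 1, n_bootstrap = 1000)
cat("pipeline outputs:\n")
print(list.files("results/run_all"))
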