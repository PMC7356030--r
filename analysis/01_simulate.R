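#!/usr/bin/env Rscript

# Step 1: generate the synthetic bibliographic corpus that stands in
# for a Scopus export of honey bee literature (1957-2017), and write
# it to disk in the Scopus CSV dialect together with the injected
# synonym map and the generating ground truth.

suppressMessages(library(beemine))

seed <- 20260901L
data_dir <- "results/data"

cfg <- synth_config(seed = seed)
paths <- emit_fixture(cfg, data_dir)
gen <- attr(paths, "generated")

cat(sprintf(
  "simulated %d publications over %d-%d (regime change %d)\n",
  n_publications(gen$corpus), min(cfg$years), max(cfg$years), cfg$regime_year
))
cat(sprintf(
  "injected %d lexical variant forms (recorded in %s)\n",
  length(gen$synonyms), paths$synonyms
))
cat(sprintf("corpus written to %s\n", paths$corpus))
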