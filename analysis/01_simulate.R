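#!/usr/bin/env Rscript
# Stage 1: generate the synthetic screening release used by the downstream
# stages — the "recovery" scenario: 20 chemicals each of four planted
# mechanism archetypes (PPARgamma agonist, GR agonist, monoamine binder,
# broad cytotoxicant) among 400 null chemicals, over the panel formed by the
# six biological-process models plus the RAR companion and 40 distractor
# assays, with a dense/sparse two-tier testing structure.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(toxpiscreen))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20161

ds <- simulate_scenario("recovery", seed = seed)
print(ds)
cov <- coverage_stats(ds$matrix)
cat(sprintf("overall testing coverage: %.1f%% (dense tier: %d chemicals, sparse: %d)\n",
            100 * cov$fraction_tested, sum(ds$truth$tier == "dense"),
            sum(ds$truth$tier == "sparse")))

paths <- write_dataset(ds, "results/synthetic")
cat("wrote:", paste(paths, collapse = ", "), "\n")
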