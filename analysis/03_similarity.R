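#!/usr/bin/env Rscript
# Stage 3: chemical-chemical similarity profiling. Fingerprints are the
# six-category binned z-scores over the densely tested subset, correlated
# with pairwise-complete Pearson; ranked neighbour lists are printed for
# one planted chemical per archetype, with and without same-archetype
# exclusion (the analogue of restricting a drug's neighbour list to
# nonpharmaceuticals).
#
# Usage: Rscript analysis/03_similarity.R [seed]

suppressPackageStartupMessages(library(toxpiscreen))

x <- load_hts_table("results/synthetic/hts_results.csv")
truth <- read.delim("results/synthetic/truth.tsv")

binned <- build_binned_matrix(x, coverage_filter = 0.8)
cat(sprintf("coverage filter 0.8 keeps %d of %d chemicals\n",
            nrow(binned), nrow(truth)))
entries <- pairwise_pearson(binned, min_overlap = 10)

dir.create("results/similarity", showWarnings = FALSE, recursive = TRUE)
out <- entries
out$pearson_r <- round(out$pearson_r, 4)
write.table(out, "results/similarity/pairs.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

arch_of <- function(id) truth$archetype[match(id, truth$chemical_id)]
for (arch in c("pparg_agonist", "gr_agonist", "monoamine_binder")) {
  q <- intersect(truth$chemical_id[truth$archetype == arch], rownames(binned))[1]
  if (is.na(q)) next
  top <- top_similar(entries, q, k = 10)
  top$archetype <- arch_of(top$chemical_id)
  cat(sprintf("\ntop 10 most similar to %s:\n", q))
  print(top, row.names = FALSE)
  top_x <- top_similar(entries, q, k = 10,
                       exclude = function(id) identical(arch_of(id), arch))
  cat(sprintf("top 10 excluding other %s chemicals (lead-hopping view):\n", arch))
  print(utils::head(top_x, 3), row.names = FALSE)
  write.table(top, file.path("results/similarity", paste0("top_", arch, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
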