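#!/usr/bin/env Rscript
# Stage 4: profile clustering of the C. elegans feeding-behavior model's
# component scores — PCA keeping components that explain >= 5% of variance,
# seeded k-means (k = dimension of the reduced PC matrix, 10,000-iteration
# cap), and mean ToxPi profiles per cluster ranked by mean overall score.
#
# Usage: Rscript analysis/04_cluster.R [seed]

suppressPackageStartupMessages(library(toxpiscreen))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20161

x <- load_hts_table("results/synthetic/hts_results.csv")
truth <- read.delim("results/synthetic/truth.tsv")
model <- bundled_models()$feeding_behavior_celegans
res <- toxpi_scores(build_input_matrix(x), model)
ss <- as.matrix(res[, names(model$slices)])
rownames(ss) <- res$chemical_id

pca <- pca_reduce(ss, threshold = 0.05)
print(pca)
km <- kmeans_cluster(pca$coords, seed = seed)
print(km)

prof <- cluster_profiles(km, ss)
dir.create("results/clusters", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(chemical_id = names(km$assignments),
                       cluster = unname(km$assignments),
                       archetype = truth$archetype[
                         match(names(km$assignments), truth$chemical_id)]),
            "results/clusters/assignments.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
prof_out <- prof
prof_out[, -(1:2)] <- round(prof_out[, -(1:2)], 4)
write.table(prof_out, "results/clusters/profiles.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("\nmean ToxPi profiles per cluster (by mean overall score):\n")
print(prof_out, row.names = FALSE)
big <- prof$cluster[which.max(prof$size)]
cat(sprintf("\nlargest cluster (%d): %d chemicals, mean overall score %.4f — the negligible-activity bulk\n",
            big, max(prof$size), prof$mean_overall[prof$cluster == big]))
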