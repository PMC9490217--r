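#!/usr/bin/env Rscript
# Stage 3: ANI dereplication and novelty classification.
#
# Greedy best-genome-wins clustering of a simulated hierarchical ANI table at
# the 99% (strain-level) and 95% (species-level) thresholds, then novelty
# calls against a reference set: best qualifying hit (aligned fraction >=
# 65%) with ANI >= 99 is a known genome, 95 <= ANI < 99 a novel strain,
# < 95 (or no hit) a novel species.

suppressPackageStartupMessages(library(strainshare))
out <- "results"
dir.create(out, showWarnings = FALSE)

ani <- simulate_ani_table(n_species = 6, strains_per_species = 3,
  genomes_per_strain = 3, seed = 20260928L)
genomes <- sort(unique(c(ani$query_id, ani$target_id)))
# priority: simulated genome quality, as dRep prioritizes its representatives
set.seed(20260928L)
quality <- stats::setNames(
  quality_score(runif(length(genomes), 60, 100), runif(length(genomes), 0, 5),
    round(rlnorm(length(genomes), log(5e4), 1)) + 1),
  genomes
)

cl99 <- greedy_cluster(ani, 99, quality)
cl95 <- greedy_cluster(ani, 95, quality)
utils::write.table(cl99, file.path(out, "clusters99.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cl95, file.path(out, "clusters95.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf(
  "%d genomes -> %d strain-level (99%%) and %d species-level (95%%) clusters\n",
  length(genomes), length(unique(cl99$cluster_id)), length(unique(cl95$cluster_id))
))

# novelty of each strain representative against a simulated reference catalog
reps <- cl99$genome_id[cl99$is_representative]
set.seed(20260929L)
best_hits <- data.frame(
  genome_id = reps,
  ani = runif(length(reps), 90, 100),
  aligned_fraction = runif(length(reps), 40, 95)
)
qualifying <- ifelse(best_hits$aligned_fraction >= 65, best_hits$ani, NA_real_)
best_hits$novelty <- novelty_classify(qualifying)
utils::write.table(best_hits, file.path(out, "novelty.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
print(table(best_hits$novelty))
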