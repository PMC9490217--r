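#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohousing study.
#
# Emulates the target design: 15 goats and 15 pigs, six of each cohoused in
# one pen after weaning, goats sampled at rumen and cecum, pigs at cecum.
# Writes the sample metadata, strain abundances (CPM), coverage summaries,
# the per-position pileup and the planted-event truth table.

suppressPackageStartupMessages(library(strainshare))

out <- "results"
dir.create(out, showWarnings = FALSE)

config <- sim_config(seed = 20260928L)
study <- generate_study(config)

utils::write.table(study$metadata, file.path(out, "metadata.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
ab <- data.frame(strain_id = rownames(study$abundance), study$abundance,
  check.names = FALSE)
utils::write.table(ab, file.path(out, "abundance.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(study$coverage, file.path(out, "coverage.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(study$pileup, file.path(out, "pileup.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(study$truth$planted_events, file.path(out, "truth_events.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(
    config = unclass(config),
    strain_phyla = as.list(study$truth$strain_phyla),
    n_planted_events = nrow(study$truth$planted_events)
  ),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
)

cat(sprintf(
  "simulated %d strains x %d samples; %d pileup rows; %d planted events (%s)\n",
  config$n_strains, nrow(study$metadata), nrow(study$pileup),
  nrow(study$truth$planted_events),
  paste(names(table(study$truth$planted_events$event_type)),
    table(study$truth$planted_events$event_type), sep = "=", collapse = ", ")
))
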