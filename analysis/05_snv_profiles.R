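#!/usr/bin/env Rscript
# Stage 5: SNV profiles and allele incidence.
#
# Calls alleles from the pileup (>= 2 reads at Phred >= 15), applies the
# strain presence filter (breadth >= 10%, depth >= 0.15x) and computes each
# allele's incidence across the strain's screening samples with
# coverage-aware denominators.

suppressPackageStartupMessages(library(strainshare))
out <- "results"

pileup <- utils::read.delim(file.path(out, "pileup.tsv"))
coverage <- utils::read.delim(file.path(out, "coverage.tsv"))

called <- call_alleles_table(pileup)
screened <- presence_filter(coverage)
cat(sprintf(
  "presence filter kept %d / %d strain-sample profiles\n",
  attr(screened, "n_kept"), attr(screened, "n_kept") + attr(screened, "n_dropped")
))
utils::write.table(screened, file.path(out, "profiles.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

inc <- allele_incidence(called$calls, called$covered, screened)
utils::write.table(inc, file.path(out, "incidence.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
alt <- inc[inc$allele == "alt", ]
cat(sprintf(
  "incidence table: %d alleles over %d strains; alt-allele f quartiles %.2f / %.2f / %.2f\n",
  nrow(inc), length(unique(inc$strain_id)),
  stats::quantile(alt$f, 0.25), stats::median(alt$f), stats::quantile(alt$f, 0.75)
))
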