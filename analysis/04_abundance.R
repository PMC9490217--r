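#!/usr/bin/env Rscript
# Stage 4: community composition summaries.
#
# Phylum-level relative abundance per sample, Firmicutes/Bacteroidota ratio
# per gut habitat, and alpha diversity (Shannon, richness) compared between
# cohoused and control animals per habitat with the Wilcoxon rank-sum test.

suppressPackageStartupMessages(library(strainshare))
out <- "results"

md <- utils::read.delim(file.path(out, "metadata.tsv"))
ab <- utils::read.delim(file.path(out, "abundance.tsv"), check.names = FALSE)
mat <- as.matrix(ab[, -1]); rownames(mat) <- ab$strain_id
truth <- jsonlite::read_json(file.path(out, "truth.json"))
tax <- data.frame(
  mag_id = names(truth$strain_phyla),
  phylum = unlist(truth$strain_phyla)
)

fr <- phylum_relative_abundance(mat, tax)
utils::write.table(
  data.frame(phylum = rownames(fr), fr, check.names = FALSE),
  file.path(out, "phylum_fractions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
)

fb <- fb_ratio(fr)
habitat <- paste(md$host_species, md$gut_site)[match(colnames(fr), md$sample_id)]
cat("median Firmicutes/Bacteroidota ratio per habitat:\n")
print(round(tapply(fb, habitat, stats::median, na.rm = TRUE), 3))

alpha <- alpha_diversity(mat)
alpha$group <- md$group[match(alpha$sample_id, md$sample_id)]
alpha$habitat <- habitat[match(alpha$sample_id, colnames(fr))]
utils::write.table(alpha, file.path(out, "alpha.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

cat("\ncohoused vs control alpha diversity (Wilcoxon rank-sum):\n")
for (h in unique(alpha$habitat)) {
  sub <- alpha[alpha$habitat == h, ]
  if (length(unique(sub$group)) < 2) next
  w_sh <- wilcoxon_rank_sum(sub$shannon[sub$group == "cohoused"],
    sub$shannon[sub$group == "control"])
  w_ri <- wilcoxon_rank_sum(sub$richness[sub$group == "cohoused"],
    sub$richness[sub$group == "control"])
  cat(sprintf("  %-11s Shannon p = %.3f, richness p = %.3f\n", h, w_sh$p, w_ri$p))
}
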