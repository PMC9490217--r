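#' Counts-per-million normalization
#'
#' Scales per-contig read counts to contigs-per-million (CPM): each count is
#' divided by its sample total and multiplied by 1e6, so every sample column
#' sums to 1e6.
#'
#' @param counts Numeric matrix of non-negative read counts, contigs in rows
#'   and samples in columns (dimnames recommended).
#' @return Matrix of the same shape with CPM values.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    who <- colnames(counts)[zero] %||% which(zero)
    stop("sample(s) with all-zero counts: ", paste(who, collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' MAG abundance as median contig CPM
#'
#' Aggregates a contig-level CPM matrix to MAG level: the abundance of a MAG
#' in a sample is the median CPM over its contigs (even contig counts use the
#' midpoint of the two central values, as `stats::median` does).
#'
#' @param contig_cpm Contig x sample CPM matrix with contig rownames.
#' @param contig_map data.frame mapping `contig_id` to `mag_id`.
#' @return MAG x sample abundance matrix.
#' @export
mag_abundance <- function(contig_cpm, contig_map) {
  stopifnot(all(c("contig_id", "mag_id") %in% names(contig_map)))
  missing_contigs <- setdiff(contig_map$contig_id, rownames(contig_cpm))
  if (length(missing_contigs)) {
    stop("mapped contig(s) absent from CPM table: ", paste(missing_contigs, collapse = ", "))
  }
  mags <- unique(contig_map$mag_id)
  out <- matrix(NA_real_, length(mags), ncol(contig_cpm),
    dimnames = list(mags, colnames(contig_cpm))
  )
  for (m in mags) {
    contigs <- contig_map$contig_id[contig_map$mag_id == m]
    if (length(contigs) == 0) stop("MAG with zero contigs: ", m)
    out[m, ] <- apply(contig_cpm[contigs, , drop = FALSE], 2, stats::median)
  }
  out
}

#' Phylum-level relative abundance
#'
#' Sums MAG abundances within phyla and renormalizes each sample to sum to 1.
#' MAGs without a phylum label are pooled under `"unclassified"`.
#'
#' @param abundance MAG x sample abundance matrix.
#' @param taxonomy data.frame with `mag_id` and `phylum` columns.
#' @return Phylum x sample matrix of fractions (columns sum to 1).
#' @export
phylum_relative_abundance <- function(abundance, taxonomy) {
  stopifnot(all(c("mag_id", "phylum") %in% names(taxonomy)))
  phy <- stats::setNames(as.character(taxonomy$phylum), taxonomy$mag_id)
  labels <- phy[rownames(abundance)]
  labels[is.na(labels) | !nzchar(labels)] <- "unclassified"
  sums <- rowsum(abundance, labels)
  totals <- colSums(sums)
  if (any(totals == 0)) stop("sample(s) with zero total abundance")
  sweep(sums, 2, totals, "/")
}

#' Firmicutes-to-Bacteroidota ratio
#'
#' Sums the fractions of every phylum whose name starts with "Firmicutes"
#' (Firmicutes, Firmicutes_A, ...) and divides by the Bacteroidota fraction.
#' Samples with zero Bacteroidota get `NA`.
#'
#' @param phylum_fractions Phylum x sample fraction matrix as from
#'   [phylum_relative_abundance()].
#' @return Named numeric vector, one ratio per sample.
#' @export
fb_ratio <- function(phylum_fractions) {
  firmi <- startsWith(rownames(phylum_fractions), "Firmicutes")
  f <- colSums(phylum_fractions[firmi, , drop = FALSE])
  b <- if ("Bacteroidota" %in% rownames(phylum_fractions)) {
    phylum_fractions["Bacteroidota", ]
  } else {
    stats::setNames(rep(0, ncol(phylum_fractions)), colnames(phylum_fractions))
  }
  out <- ifelse(b > 0, f / b, NA_real_)
  stats::setNames(out, colnames(phylum_fractions))
}

#' Alpha diversity (Shannon and richness)
#'
#' Shannon index H = -sum(q log q) over positive relative abundances (natural
#' log, via `vegan::diversity`), and richness as the number of strains with
#' positive abundance.
#'
#' @param abundance Strain x sample abundance matrix (non-negative).
#' @return data.frame with `sample_id`, `shannon`, `richness`.
#' @export
alpha_diversity <- function(abundance) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundance must be non-negative")
  if (any(colSums(abundance) == 0)) stop("sample(s) with all-zero abundance")
  data.frame(
    sample_id = colnames(abundance) %||% as.character(seq_len(ncol(abundance))),
    shannon = unname(vegan::diversity(t(abundance), index = "shannon")),
    richness = unname(colSums(abundance > 0)),
    stringsAsFactors = FALSE
  )
}
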