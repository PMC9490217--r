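#' Greedy centroid clustering on a pairwise ANI table
#'
#' Dereplicates genomes at an average-nucleotide-identity threshold the way
#' dRep's "best genome wins" pass does: genomes are visited in order of
#' decreasing priority (genome-id lexicographic tie-break); each unassigned
#' genome becomes a cluster representative and absorbs every unassigned
#' genome whose ANI to it is at or above the threshold. The ANI relation is
#' treated as undirected (the larger of the two reported directions is used);
#' missing pairs count as below threshold.
#'
#' @param ani A data.frame with columns `query_id`, `target_id`, `ani`
#'   (percent) and optionally `aligned_fraction`.
#' @param threshold Percent ANI at or above which two genomes share a cluster
#'   (99 for strain-level, 95 for species-level bins).
#' @param priority Named numeric vector covering every genome; higher values
#'   are picked as representatives first. Typically [quality_score()].
#' @return A data.frame with columns `genome_id`, `cluster_id`,
#'   `is_representative`; exactly one representative per cluster.
#' @export
greedy_cluster <- function(ani, threshold, priority) {
  stopifnot(is.data.frame(ani), all(c("query_id", "target_id", "ani") %in% names(ani)))
  if (is.null(names(priority)) || any(!nzchar(names(priority)))) {
    stop("priority must be a named vector covering all genomes")
  }
  genomes <- names(priority)
  unknown <- setdiff(unique(c(ani$query_id, ani$target_id)), genomes)
  if (length(unknown)) {
    stop("genome(s) in ani table without a priority: ", paste(unknown, collapse = ", "))
  }
  if (any(ani$ani < 0 | ani$ani > 100)) stop("ani must be within [0, 100]")

  # undirected ANI lookup, max over reported directions
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  edge <- tapply(ani$ani, key(ani$query_id, ani$target_id), max)

  ord <- genomes[order(-priority[genomes], genomes)]
  cluster_of <- stats::setNames(rep(NA_character_, length(genomes)), genomes)
  reps <- character(0)
  for (g in ord) {
    if (!is.na(cluster_of[g])) next
    cluster_of[g] <- g
    reps <- c(reps, g)
    free <- names(cluster_of)[is.na(cluster_of)]
    if (length(free)) {
      a <- edge[key(g, free)]
      hit <- free[!is.na(a) & a >= threshold]
      cluster_of[hit] <- g
    }
  }
  cluster_id <- stats::setNames(sprintf("C%03d", seq_along(reps)), reps)
  data.frame(
    genome_id = genomes,
    cluster_id = unname(cluster_id[cluster_of[genomes]]),
    is_representative = genomes == cluster_of[genomes],
    stringsAsFactors = FALSE
  )
}

#' Pick the best qualifying reference hit for a query genome
#'
#' The best hit is the reference comparison with maximal ANI among those with
#' aligned fraction at or above `min_af` (65% by default).
#'
#' @param hits data.frame of reference comparisons for one query
#'   (`target_id`, `ani`, `aligned_fraction`).
#' @param min_af Minimum aligned fraction (percent) for a hit to qualify.
#' @return One-row data.frame, or `NULL` when no hit qualifies.
#' @export
best_reference_hit <- function(hits, min_af = 65) {
  stopifnot(all(c("ani", "aligned_fraction") %in% names(hits)))
  ok <- hits[hits$aligned_fraction >= min_af, , drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  ok[which.max(ok$ani), , drop = FALSE]
}

#' Classify a genome's novelty against a reference catalog
#'
#' Given the best qualifying reference hit (see [best_reference_hit()]):
#' no hit or ANI < 95 is a novel species; 95 <= ANI < 99 a novel strain;
#' ANI >= 99 a known genome. Novelty bounds are strict `<` as printed; the
#' aligned-fraction gate is applied when selecting the best hit.
#'
#' @param best_ani Best qualifying hit ANI (percent), or `NA`/`NULL` when no
#'   reference hit qualifies. Vectorized (with `NA` for "no hit").
#' @return Character vector in
#'   `c("known", "novel_strain", "novel_species")`.
#' @export
novelty_classify <- function(best_ani) {
  if (is.null(best_ani) || length(best_ani) == 0) return("novel_species")
  stopifnot(is.numeric(best_ani) || all(is.na(best_ani)))
  if (any(!is.na(best_ani) & (best_ani < 0 | best_ani > 100))) {
    stop("ani must be within [0, 100]")
  }
  ifelse(is.na(best_ani) | best_ani < 95, "novel_species",
    ifelse(best_ani < 99, "novel_strain", "known")
  )
}
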