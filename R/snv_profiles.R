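#' Call alleles for one strain in one sample
#'
#' Builds a strain profile from pileup rows. An allele (position, base) is
#' called when it is supported by at least `min_reads` reads with base call
#' quality Phred >= 15 (the pileup's `min_phred_passing_count` column); a
#' position is evaluable ("covered") when its total qualifying depth reaches
#' the same bound.
#'
#' @param pileup_rows data.frame of pileup rows for a single strain and
#'   sample: `position`, `allele`, `read_count`, `min_phred_passing_count`
#'   (plus optional `strain_id`, `sample_id`).
#' @param min_reads Minimum qualifying reads to call an allele (default 2).
#' @return A list of class `strain_profile`: `strain_id`, `sample_id`,
#'   `alleles` (data.frame of called `position`, `allele`),
#'   `covered_positions` (integer vector).
#' @export
call_alleles <- function(pileup_rows, min_reads = 2) {
  stopifnot(all(c("position", "allele", "read_count", "min_phred_passing_count") %in%
    names(pileup_rows)))
  if (any(pileup_rows$read_count < 0) || any(pileup_rows$min_phred_passing_count < 0)) {
    stop("read counts must be non-negative")
  }
  called <- pileup_rows$min_phred_passing_count >= min_reads
  qual_depth <- tapply(pileup_rows$min_phred_passing_count, pileup_rows$position, sum)
  covered <- sort(as.integer(names(qual_depth)[qual_depth >= min_reads]))
  alleles <- pileup_rows[called, c("position", "allele"), drop = FALSE]
  alleles <- alleles[order(alleles$position, alleles$allele), , drop = FALSE]
  rownames(alleles) <- NULL
  structure(
    list(
      strain_id = pileup_rows$strain_id[1] %||% NA_character_,
      sample_id = pileup_rows$sample_id[1] %||% NA_character_,
      alleles = alleles,
      covered_positions = covered
    ),
    class = "strain_profile"
  )
}

#' Call alleles across a whole pileup table
#'
#' Vectorized counterpart of [call_alleles()] over every (strain, sample)
#' combination in a pileup table.
#'
#' @param pileup data.frame with `strain_id`, `sample_id`, `position`,
#'   `allele`, `read_count`, `min_phred_passing_count`.
#' @param min_reads Minimum qualifying reads (default 2).
#' @return A list with `calls` (data.frame `strain_id`, `sample_id`,
#'   `position`, `allele` of called alleles) and `covered` (data.frame
#'   `strain_id`, `sample_id`, `position` of evaluable positions).
#' @export
call_alleles_table <- function(pileup, min_reads = 2) {
  stopifnot(all(c(
    "strain_id", "sample_id", "position", "allele",
    "read_count", "min_phred_passing_count"
  ) %in% names(pileup)))
  if (any(pileup$read_count < 0) || any(pileup$min_phred_passing_count < 0)) {
    stop("read counts must be non-negative")
  }
  calls <- pileup[
    pileup$min_phred_passing_count >= min_reads,
    c("strain_id", "sample_id", "position", "allele"),
    drop = FALSE
  ]
  rownames(calls) <- NULL
  key <- paste(pileup$strain_id, pileup$sample_id, pileup$position, sep = "\r")
  qual_depth <- rowsum(pileup$min_phred_passing_count, key)
  ok <- rownames(qual_depth)[qual_depth[, 1] >= min_reads]
  parts <- strsplit(ok, "\r", fixed = TRUE)
  covered <- data.frame(
    strain_id = vapply(parts, `[`, "", 1),
    sample_id = vapply(parts, `[`, "", 2),
    position = as.integer(vapply(parts, `[`, "", 3)),
    stringsAsFactors = FALSE
  )
  list(calls = calls, covered = covered)
}

#' Strain presence filter
#'
#' Keeps (strain, sample) profiles with horizontal coverage (breadth) >= 10%
#' and average vertical coverage (depth) >= 0.15x; both bounds inclusive.
#'
#' @param coverage data.frame with `strain_id`, `sample_id`, `breadth`,
#'   `depth`.
#' @param min_breadth,min_depth Inclusive presence bounds.
#' @return The kept rows, with attributes `n_kept` and `n_dropped`.
#' @export
presence_filter <- function(coverage, min_breadth = 0.10, min_depth = 0.15) {
  stopifnot(all(c("strain_id", "sample_id", "breadth", "depth") %in% names(coverage)))
  keep <- coverage$breadth >= min_breadth & coverage$depth >= min_depth
  out <- coverage[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Allele incidence across screening samples
#'
#' For every strain, computes the incidence f of each observed allele across
#' that strain's screening samples (the samples that pass the presence
#' filter). With `coverage_aware = TRUE` (default) the denominator of f for
#' an allele is the number of screening samples whose evaluable positions
#' include the allele's position, so absence through non-coverage does not
#' deflate f; `coverage_aware = FALSE` restores a naive global denominator
#' (the number of screening samples). Alleles never observed in any
#' screening sample are excluded.
#'
#' @param calls Called alleles (`strain_id`, `sample_id`, `position`,
#'   `allele`), as from [call_alleles_table()], already restricted to
#'   screening samples.
#' @param covered Evaluable positions (`strain_id`, `sample_id`,
#'   `position`), likewise restricted.
#' @param screened data.frame with `strain_id`, `sample_id` listing the
#'   screening samples per strain (e.g. the output of [presence_filter()]).
#' @param coverage_aware Use per-allele coverage-aware denominators.
#' @return data.frame `strain_id`, `position`, `allele`, `f`, `n_carrying`,
#'   `n_covered`, `n_screen`.
#' @export
allele_incidence <- function(calls, covered, screened, coverage_aware = TRUE) {
  stopifnot(all(c("strain_id", "sample_id") %in% names(screened)))
  n_screen <- table(unique(screened[, c("strain_id", "sample_id")])$strain_id)
  if (length(n_screen) == 0 || all(n_screen == 0)) stop("no screening samples")

  pair_key <- function(df) paste(df$strain_id, df$sample_id, sep = "\r")
  keep_pairs <- pair_key(screened)
  calls <- calls[pair_key(calls) %in% keep_pairs, , drop = FALSE]
  covered <- covered[pair_key(covered) %in% keep_pairs, , drop = FALSE]
  if (nrow(calls) == 0) {
    return(data.frame(
      strain_id = character(0), position = integer(0), allele = character(0),
      f = numeric(0), n_carrying = integer(0), n_covered = integer(0),
      n_screen = integer(0), stringsAsFactors = FALSE
    ))
  }

  akey <- paste(calls$strain_id, calls$position, calls$allele, sep = "\r")
  n_carrying <- rowsum(rep(1L, nrow(calls)), akey)
  alleles <- do.call(rbind, strsplit(rownames(n_carrying), "\r", fixed = TRUE))
  out <- data.frame(
    strain_id = alleles[, 1],
    position = as.integer(alleles[, 2]),
    allele = alleles[, 3],
    n_carrying = as.integer(n_carrying[, 1]),
    stringsAsFactors = FALSE
  )

  pkey <- paste(covered$strain_id, covered$position, sep = "\r")
  n_covered <- rowsum(rep(1L, nrow(covered)), pkey)
  out$n_covered <- as.integer(n_covered[paste(out$strain_id, out$position, sep = "\r"), 1])
  out$n_screen <- as.integer(n_screen[out$strain_id])
  denom <- if (coverage_aware) out$n_covered else out$n_screen
  out$f <- out$n_carrying / denom
  out <- out[order(out$strain_id, out$position, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}
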