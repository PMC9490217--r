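#' MAG quality score
#'
#' Scores a metagenome-assembled genome (MAG) from its CheckM-style
#' completeness and contamination estimates and assembly N50:
#' `quality = completeness - 5 * contamination + log(n50)`.
#'
#' The log base defaults to the natural log; base 10 is also supported since
#' the choice only rescales the (small) N50 term.
#'
#' @param completeness Percent completeness in `[0, 100]`.
#' @param contamination Percent contamination, `>= 0`.
#' @param n50 Assembly N50 in base pairs, `>= 1`.
#' @param log_base Base of the logarithm applied to `n50`; `exp(1)` (default)
#'   or `10`.
#' @return Numeric quality score (vectorized over the inputs).
#' @export
#' @examples
#' quality_score(90, 10, 1e6)
quality_score <- function(completeness, contamination, n50, log_base = exp(1)) {
  stopifnot(is.numeric(completeness), is.numeric(contamination), is.numeric(n50))
  if (any(completeness < 0 | completeness > 100)) {
    stop("completeness must be within [0, 100]")
  }
  if (any(contamination < 0)) stop("contamination must be >= 0")
  if (any(n50 < 1)) stop("n50 must be >= 1 (log undefined below 1)")
  completeness - 5 * contamination + log(n50, base = log_base)
}

#' MAG retention rule
#'
#' A MAG is retained when quality >= 50, contamination <= 10 and
#' completeness >= 50 (all boundaries inclusive).
#'
#' @inheritParams quality_score
#' @return Logical vector, `TRUE` for retained records.
#' @export
passes_retention <- function(completeness, contamination, n50, log_base = exp(1)) {
  q <- quality_score(completeness, contamination, n50, log_base)
  q >= 50 & contamination <= 10 & completeness >= 50
}

#' MAG quality tier
#'
#' Tiers retained MAGs with high -> medium -> low precedence: high needs
#' completeness >= 90 and contamination <= 5; medium needs completeness >= 70
#' and contamination <= 10; every other retained MAG is low. The precedence
#' makes the three tiers a partition of the retained set.
#'
#' @inheritParams quality_score
#' @return Character vector in `c("high", "medium", "low")`.
#' @export
mag_tier <- function(completeness, contamination, n50, log_base = exp(1)) {
  retained <- passes_retention(completeness, contamination, n50, log_base)
  if (any(!retained)) {
    stop("mag_tier() is defined only for retained records; filter with passes_retention() first")
  }
  ifelse(completeness >= 90 & contamination <= 5, "high",
    ifelse(completeness >= 70 & contamination <= 10, "medium", "low")
  )
}

#' Count MAGs per quality tier
#'
#' @param tiers Character vector of tiers as returned by [mag_tier()], or a
#'   named numeric vector/list of per-tier counts.
#' @return A list with components `high`, `medium`, `low` and `total`
#'   (JSON-serializable).
#' @export
#' @examples
#' summarize_tiers(c(high = 1152, medium = 1497, low = 613))
summarize_tiers <- function(tiers) {
  if (is.numeric(tiers) || is.list(tiers)) {
    counts <- unlist(tiers)
    bad <- setdiff(names(counts), c("high", "medium", "low"))
    if (length(bad)) stop("unknown tier name(s): ", paste(bad, collapse = ", "))
    out <- list(
      high = unname(counts["high"] %||% 0),
      medium = unname(counts["medium"] %||% 0),
      low = unname(counts["low"] %||% 0)
    )
    out <- lapply(out, function(x) if (is.na(x)) 0 else x)
  } else {
    stopifnot(is.character(tiers))
    out <- list(
      high = sum(tiers == "high"),
      medium = sum(tiers == "medium"),
      low = sum(tiers == "low")
    )
  }
  out$total <- out$high + out$medium + out$low
  out
}

#' QC a table of MAG records
#'
#' Adds `quality`, `retained` and `tier` columns to a MAG record table
#' (columns `mag_id`, `completeness`, `contamination`, `n50`, plus optional
#' taxonomy columns). `tier` is `NA` for non-retained records.
#'
#' @param mags A data.frame of MAG records.
#' @param log_base Log base for the N50 term, see [quality_score()].
#' @return The input data.frame with `quality`, `retained`, `tier` appended.
#' @export
qc_mags <- function(mags, log_base = exp(1)) {
  need <- c("mag_id", "completeness", "contamination", "n50")
  missing_cols <- setdiff(need, names(mags))
  if (length(missing_cols)) {
    stop("mags is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  mags$quality <- quality_score(mags$completeness, mags$contamination, mags$n50, log_base)
  mags$retained <- passes_retention(mags$completeness, mags$contamination, mags$n50, log_base)
  mags$tier <- NA_character_
  if (any(mags$retained)) {
    mags$tier[mags$retained] <- mag_tier(
      mags$completeness[mags$retained],
      mags$contamination[mags$retained],
      mags$n50[mags$retained],
      log_base
    )
  }
  mags
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
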