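#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over strain abundances
#' (computed via `vegan::vegdist`). Samples are the columns of the input.
#'
#' @param abundance Strain x sample matrix of non-negative abundances.
#' @return Symmetric sample x sample matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(abundance) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundance must be non-negative")
  totals <- colSums(abundance)
  if (any(totals == 0)) {
    who <- colnames(abundance)[totals == 0] %||% which(totals == 0)
    stop("sample(s) with zero total abundance: ", paste(who, collapse = ", "))
  }
  as.matrix(vegan::vegdist(t(abundance), method = "bray"))
}

#' PERMANOVA on a distance matrix
#'
#' Sequential (Type I) permutational multivariate ANOVA via
#' `vegan::adonis2(by = "terms")` with unrestricted sample-label
#' permutations and the Monte Carlo p-value
#' `(1 + #\{permuted F >= observed F\}) / (1 + n_perm)`. Samples are
#' canonicalized to sorted sample-id order before permuting, so the result
#' does not depend on input row order.
#'
#' @param distances Symmetric sample x sample distance matrix with sample
#'   ids as dimnames.
#' @param metadata data.frame with `sample_id` and the term columns.
#' @param terms Character vector of metadata columns, in model order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed making the permutation set reproducible.
#' @return data.frame with `term`, `df`, `sum_of_squares`, `pseudo_F`, `R2`,
#'   `p_value`, `n_permutations` (terms, then Residual and Total rows).
#' @export
permanova <- function(distances, metadata, terms, n_perm = 999, seed = 1L) {
  distances <- as.matrix(distances)
  ids <- sort(colnames(distances))
  if (is.null(ids)) stop("distance matrix must carry sample ids as dimnames")
  meta <- metadata[!duplicated(metadata$sample_id), , drop = FALSE]
  rownames(meta) <- meta$sample_id
  if (!all(ids %in% rownames(meta))) stop("metadata is missing samples present in the distances")
  meta <- meta[ids, , drop = FALSE]
  missing_terms <- setdiff(terms, names(meta))
  if (length(missing_terms)) stop("unknown term(s): ", paste(missing_terms, collapse = ", "))
  for (tm in terms) {
    if (length(unique(meta[[tm]])) < 2) {
      stop("term '", tm, "' has a single level among these samples")
    }
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  d <- stats::as.dist(distances[ids, ids])
  set.seed(as.integer(seed))
  fit <- vegan::adonis2(
    stats::reformulate(terms, response = "d"),
    data = meta[, terms, drop = FALSE],
    permutations = n_perm, by = "terms"
  )
  data.frame(
    term = rownames(fit),
    df = fit$Df,
    sum_of_squares = fit$SumOfSqs,
    pseudo_F = fit$F,
    R2 = fit$R2,
    p_value = fit$`Pr(>F)`,
    n_permutations = n_perm,
    stringsAsFactors = FALSE
  )
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value when both groups have at most 8 observations and there are
#' no ties; otherwise the normal approximation with tie and continuity
#' corrections (via `stats::wilcox.test`).
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @return List with `U` (the rank-sum U statistic of the first group) and
#'   `p`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) stop("both groups must be non-empty")
  ties <- any(duplicated(c(values_a, values_b)))
  exact <- length(values_a) <= 8 && length(values_b) <= 8 && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    values_a, values_b,
    exact = exact, correct = TRUE, alternative = "two.sided"
  ))
  p <- ht$p.value
  # fully tied data (zero rank variance) carries no evidence either way
  if (is.nan(p)) p <- 1
  list(U = unname(ht$statistic), p = min(p, 1))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midrank-transformed vectors. A constant input has
#' no defined rank correlation and yields `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Spearman's rho, or `NA` for degenerate input.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' First principal-coordinate axis of a distance matrix
#'
#' Classical metric scaling (PCoA) on the Gower-centered matrix via
#' `stats::cmdscale`; returns the first axis with its sign fixed so the
#' first sample's coordinate is non-negative. Used as the one-dimensional
#' "community composition" summary correlated against transmitted-strain
#' abundance.
#'
#' @param distances Symmetric sample x sample distance matrix (>= 3
#'   samples).
#' @return Named numeric vector, one coordinate per sample.
#' @export
composition_axis <- function(distances) {
  distances <- as.matrix(distances)
  if (nrow(distances) < 3) stop("need at least 3 samples")
  axis <- stats::cmdscale(stats::as.dist(distances), k = 1)[, 1]
  if (axis[1] < 0) axis <- -axis
  axis
}
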