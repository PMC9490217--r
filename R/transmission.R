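#' Agreement-class probabilities for one allele
#'
#' For an allele with incidence f across screening samples, the four
#' agreement classes of a sample pair and their probabilities under
#' independence are: present in both `p11 = f^2`, absent in both
#' `p00 = (1 - f)^2`, present in exactly one `p10 = p01 = f (1 - f)`. The
#' four sum to 1. `method = "literal"` instead evaluates the difference
#' forms `f1 - f2`, `(1 - f1) - (1 - f2)`, `f1 - (1 - f2)`, `(1 - f1) - f2`;
#' these are not probabilities (they can be negative and do not sum to 1)
#' and are provided for comparison only.
#'
#' @param f Allele incidence in `[0, 1]` (vectorized). Clamp with
#'   [clamp_incidence()] before taking logs downstream.
#' @param f2 Second-sample incidence, defaults to `f` (the incidence table
#'   is strain-level, not per-sample).
#' @param method `"product"` (default) or `"literal"`.
#' @return List with numeric components `p11`, `p00`, `p10`, `p01`.
#' @export
pair_probabilities <- function(f, f2 = f, method = c("product", "literal")) {
  method <- match.arg(method)
  if (any(f < 0 | f > 1) || any(f2 < 0 | f2 > 1)) {
    stop("incidence f must be within [0, 1]")
  }
  if (method == "product") {
    list(p11 = f * f2, p00 = (1 - f) * (1 - f2), p10 = f * (1 - f2), p01 = (1 - f) * f2)
  } else {
    list(
      p11 = f - f2, p00 = (1 - f) - (1 - f2),
      p10 = f - (1 - f2), p01 = (1 - f) - f2
    )
  }
}

#' Clamp allele incidences away from 0 and 1
#'
#' Replaces f by `min(max(f, 1/(2 n)), 1 - 1/(2 n))` with n the number of
#' screening samples — the add-half pseudocount convention — so that fixed
#' alleles do not produce `log(0)` in the likelihood.
#'
#' @param f Incidence values.
#' @param n_screen Number of screening samples.
#' @return Clamped incidences in the open interval (0, 1).
#' @export
clamp_incidence <- function(f, n_screen) {
  if (any(n_screen < 1)) stop("n_screen must be >= 1")
  eps <- 1 / (2 * n_screen)
  pmin(pmax(f, eps), 1 - eps)
}

#' Log-likelihood of an observed SNV-profile overlap
#'
#' Over the evaluated alleles of one sample pair,
#' `L_obs = [sum over (1,1) log p11 + sum over (0,0) log p00]
#'        - [sum over (1,0) log p10 + sum over (0,1) log p01]`
#' and `L_min = sum over all alleles min(log p11, log p00)`, the
#' log-likelihood of the least likely agreement case (natural logs).
#'
#' @param classes Character vector of per-allele agreement classes among
#'   `"11"`, `"00"`, `"10"`, `"01"`.
#' @param f Clamped incidence per allele (same length as `classes`).
#' @param min_alleles Minimum evaluated alleles; below it the comparison is
#'   skipped and `NULL` is returned.
#' @return List `L_obs`, `L_min`, `n_alleles`, or `NULL` when skipped.
#' @export
overlap_likelihood <- function(classes, f, min_alleles = 20) {
  stopifnot(length(classes) == length(f))
  if (!all(classes %in% c("11", "00", "10", "01"))) {
    stop("classes must be among '11', '00', '10', '01'")
  }
  if (length(classes) < min_alleles) return(NULL)
  p <- pair_probabilities(f)
  lp <- cbind(`11` = log(p$p11), `00` = log(p$p00), `10` = log(p$p10), `01` = log(p$p01))
  term <- lp[cbind(seq_along(classes), match(classes, colnames(lp)))]
  sign <- ifelse(classes %in% c("11", "00"), 1, -1)
  list(
    L_obs = sum(sign * term),
    L_min = sum(pmin(lp[, "11"], lp[, "00"])),
    n_alleles = length(classes)
  )
}

#' Raw transmission probability score
#'
#' `P_raw = L_obs / L_min`. Equals 1 when every allele agrees in its least
#' likely class and approaches 0 when agreement terms cancel against
#' disagreement terms.
#'
#' @param L_obs,L_min Log-likelihoods from [overlap_likelihood()];
#'   `L_min` must be negative.
#' @return Numeric ratio.
#' @export
raw_score <- function(L_obs, L_min) {
  if (any(L_min >= 0)) stop("L_min must be negative")
  L_obs / L_min
}

#' Standardize raw scores to transmission scores
#'
#' Z-standardizes a strain's P_raw values over all of its evaluated sample
#' pairs: `S_T = (P_raw - mean) / sd` with the sample (n - 1) standard
#' deviation. With fewer than `min_pairs` pairs, or zero spread, every S_T
#' for the strain is undefined (`NA`).
#'
#' @param p_raw Numeric vector of a strain's P_raw values.
#' @param min_pairs Minimum number of evaluated pairs (default 3).
#' @return Numeric vector of S_T values (possibly all `NA`).
#' @export
standardize_scores <- function(p_raw, min_pairs = 3) {
  if (length(p_raw) < min_pairs) return(rep(NA_real_, length(p_raw)))
  mu <- mean(p_raw)
  sigma <- stats::sd(p_raw)
  if (!is.finite(sigma) || sigma == 0) return(rep(NA_real_, length(p_raw)))
  (p_raw - mu) / sigma
}

#' Classify a sample pair into a transmission event type
#'
#' Same host with rumen and cecum sites is a foregut-hindgut pair; different
#' hosts of the same species an intra-species pair; different species an
#' inter-species pair. The same gut site of the same host is not an eligible
#' pair.
#'
#' @param meta_a,meta_b One-row data.frames (or lists) with `host_id`,
#'   `host_species`, `gut_site`.
#' @return One of `"foregut_hindgut"`, `"intra_species"`, `"inter_species"`.
#' @export
classify_event <- function(meta_a, meta_b) {
  if (meta_a$host_id == meta_b$host_id) {
    if (setequal(c(meta_a$gut_site, meta_b$gut_site), c("rumen", "cecum"))) {
      return("foregut_hindgut")
    }
    stop("same host and same gut site is not an eligible pair")
  }
  if (meta_a$host_species == meta_b$host_species) "intra_species" else "inter_species"
}

#' Score all sample pairs per strain
#'
#' Runs the full pairwise comparison for every strain: evaluated alleles of
#' a pair are the variant (alt) alleles from the incidence table whose
#' positions are evaluable (qualifying depth >= 2) in both samples; each
#' allele contributes its agreement class; L_obs, L_min and P_raw follow
#' [overlap_likelihood()] and [raw_score()]; S_T standardizes P_raw per
#' strain over all evaluated pairs ([standardize_scores()]). All unordered
#' pairs of screening samples are evaluated except pairs of the same host
#' and gut site, so control-group pairs provide the null background of the
#' standardization.
#'
#' @param calls,covered Called alleles and evaluable positions, as from
#'   [call_alleles_table()].
#' @param screened Screening samples per strain ([presence_filter()] output).
#' @param metadata Sample metadata with `sample_id`, `host_id`,
#'   `host_species`, `gut_site`, `group`.
#' @param min_alleles Minimum evaluated alleles per pair (default 20).
#' @param min_pairs Minimum evaluated pairs per strain for standardization.
#' @param coverage_aware Passed to [allele_incidence()].
#' @return data.frame `strain_id`, `sample_a`, `sample_b`, `n_alleles`,
#'   `L_obs`, `L_min`, `P_raw`, `S_T`.
#' @export
score_transmission <- function(calls, covered, screened, metadata,
                               min_alleles = 20, min_pairs = 3,
                               coverage_aware = TRUE) {
  stopifnot(all(c("sample_id", "host_id", "host_species", "gut_site") %in% names(metadata)))
  inc <- allele_incidence(calls, covered, screened, coverage_aware = coverage_aware)
  inc <- inc[inc$allele == "alt", , drop = FALSE]
  meta <- metadata[!duplicated(metadata$sample_id), , drop = FALSE]
  rownames(meta) <- meta$sample_id

  out <- list()
  for (s in unique(screened$strain_id)) {
    samples <- sort(unique(screened$sample_id[screened$strain_id == s]))
    if (length(samples) < 2) next
    inc_s <- inc[inc$strain_id == s, , drop = FALSE]
    if (nrow(inc_s) == 0) next
    positions <- inc_s$position
    f <- clamp_incidence(inc_s$f, inc_s$n_screen)
    p <- pair_probabilities(f)
    l11 <- log(p$p11); l00 <- log(p$p00); l10 <- log(p$p10); l01 <- log(p$p01)
    lmin <- pmin(l11, l00)

    cov_s <- covered[covered$strain_id == s & covered$sample_id %in% samples, , drop = FALSE]
    cal_s <- calls[
      calls$strain_id == s & calls$sample_id %in% samples & calls$allele == "alt", ,
      drop = FALSE
    ]
    M <- matrix(0, length(positions), length(samples), dimnames = list(NULL, samples))
    X <- M
    pos_row <- stats::setNames(seq_along(positions), positions)
    ci <- pos_row[as.character(cov_s$position)]
    ok <- !is.na(ci)
    M[cbind(ci[ok], match(cov_s$sample_id[ok], samples))] <- 1
    xi <- pos_row[as.character(cal_s$position)]
    ok <- !is.na(xi)
    X[cbind(xi[ok], match(cal_s$sample_id[ok], samples))] <- 1
    P <- X * M
    Q <- (1 - X) * M

    L_obs_m <- crossprod(P * l11, P) + crossprod(Q * l00, Q) -
      crossprod(P * l10, Q) - crossprod(Q * l01, P)
    L_min_m <- crossprod(M * lmin, M)
    n_m <- crossprod(M, M)

    idx <- which(upper.tri(n_m), arr.ind = TRUE)
    a <- samples[idx[, 1]]; b <- samples[idx[, 2]]
    same_site <- meta[a, "host_id"] == meta[b, "host_id"] &
      meta[a, "gut_site"] == meta[b, "gut_site"]
    enough <- n_m[idx] >= min_alleles
    keep <- !same_site & enough
    if (!any(keep)) next
    df <- data.frame(
      strain_id = s,
      sample_a = a[keep], sample_b = b[keep],
      n_alleles = as.integer(n_m[idx][keep]),
      L_obs = L_obs_m[idx][keep],
      L_min = L_min_m[idx][keep],
      stringsAsFactors = FALSE
    )
    df$P_raw <- raw_score(df$L_obs, df$L_min)
    df$S_T <- standardize_scores(df$P_raw, min_pairs = min_pairs)
    out[[length(out) + 1L]] <- df
  }
  if (length(out) == 0) {
    return(data.frame(
      strain_id = character(0), sample_a = character(0), sample_b = character(0),
      n_alleles = integer(0), L_obs = numeric(0), L_min = numeric(0),
      P_raw = numeric(0), S_T = numeric(0), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call transmission events from transmission scores
#'
#' Emits an event for every eligible scored pair with `S_T >= threshold`.
#' Eligible pairs are (a) same-gut-site pairs between two different hosts of
#' the cohoused group and (b) rumen-cecum pairs within one host. Cross-host
#' pairs of different gut sites are scored (they contribute to the
#' standardization background) but are not callable: sharing there cannot be
#' attributed to exactly one of the three event types.
#'
#' @param scores Output of [score_transmission()].
#' @param metadata Sample metadata (see [score_transmission()]); must also
#'   carry `group`.
#' @param threshold Minimum S_T to call an event (default 2.0).
#' @return data.frame `strain_id`, `sample_a`, `sample_b`, `S_T`,
#'   `event_type`, with attribute `n_eligible` (number of scored eligible
#'   pairs, called or not).
#' @export
detect_events <- function(scores, metadata, threshold = 2.0) {
  meta <- metadata[!duplicated(metadata$sample_id), , drop = FALSE]
  rownames(meta) <- meta$sample_id
  a <- meta[scores$sample_a, ]; b <- meta[scores$sample_b, ]
  within_host_fh <- a$host_id == b$host_id & a$gut_site != b$gut_site
  cohoused_pair <- a$host_id != b$host_id & a$gut_site == b$gut_site &
    a$group == "cohoused" & b$group == "cohoused"
  eligible <- within_host_fh | cohoused_pair
  called <- eligible & !is.na(scores$S_T) & scores$S_T >= threshold
  out <- scores[called, c("strain_id", "sample_a", "sample_b", "S_T"), drop = FALSE]
  out$event_type <- vapply(
    seq_len(nrow(out)),
    function(i) classify_event(meta[out$sample_a[i], ], meta[out$sample_b[i], ]),
    character(1)
  )
  rownames(out) <- NULL
  attr(out, "n_eligible") <- sum(eligible)
  out
}

#' Summarize transmission events
#'
#' Counts the distinct transmitted strains, their percentage of the catalog
#' (two decimals), the partition of transmitted strains into "only
#' intra-species", "only inter-species", "only foregut-hindgut" and
#' "multiple types" (a strain with events of several types counts once under
#' multiple), and optionally the phylum breakdown of transmitted strains.
#'
#' @param events data.frame with `strain_id` and `event_type` (or per-type
#'   strain counts as a named list for arithmetic-only use, e.g.
#'   `list(only_intra = 190, only_inter = 12, only_foregut_hindgut = 10,
#'   multiple = 19)`).
#' @param total_strains Size of the strain catalog.
#' @param phyla Optional named vector mapping strain_id to phylum.
#' @return A JSON-serializable list with counts and percentages.
#' @export
summarize_events <- function(events, total_strains, phyla = NULL) {
  pct <- function(k, n) if (n > 0) round(100 * k / n, 2) else 0
  if (is.data.frame(events)) {
    types_by_strain <- tapply(events$event_type, events$strain_id, function(x) sort(unique(x)))
    n_types <- lengths(types_by_strain)
    single <- unlist(lapply(types_by_strain[n_types == 1], `[`, 1))
    counts <- list(
      only_intra = sum(single == "intra_species"),
      only_inter = sum(single == "inter_species"),
      only_foregut_hindgut = sum(single == "foregut_hindgut"),
      multiple = sum(n_types > 1)
    )
    strains <- names(types_by_strain)
  } else {
    counts <- lapply(
      c(only_intra = "only_intra", only_inter = "only_inter",
        only_foregut_hindgut = "only_foregut_hindgut", multiple = "multiple"),
      function(k) events[[k]] %||% 0
    )
    strains <- NULL
  }
  n_transmitted <- counts$only_intra + counts$only_inter +
    counts$only_foregut_hindgut + counts$multiple
  if (total_strains < n_transmitted) {
    stop("total_strains is smaller than the number of transmitted strains")
  }
  out <- list(
    n_transmitted = n_transmitted,
    total_strains = total_strains,
    pct_transmitted = pct(n_transmitted, total_strains),
    only_intra = counts$only_intra,
    pct_only_intra = pct(counts$only_intra, n_transmitted),
    only_inter = counts$only_inter,
    pct_only_inter = pct(counts$only_inter, n_transmitted),
    only_foregut_hindgut = counts$only_foregut_hindgut,
    pct_only_foregut_hindgut = pct(counts$only_foregut_hindgut, n_transmitted),
    multiple = counts$multiple,
    pct_multiple = pct(counts$multiple, n_transmitted)
  )
  if (!is.null(phyla) && !is.null(strains) && n_transmitted > 0) {
    tab <- sort(table(phyla[strains]), decreasing = TRUE)
    out$phylum_breakdown_pct <- as.list(round(100 * as.numeric(tab) / n_transmitted, 2))
    names(out$phylum_breakdown_pct) <- names(tab)
  }
  out
}

#' Fraction of total abundance held by transmitted strains
#'
#' @param events Event table with a `strain_id` column.
#' @param abundance Strain x sample abundance matrix.
#' @return Named numeric vector: per sample, the abundance of strains with
#'   at least one event divided by total abundance.
#' @export
transmitted_abundance_fraction <- function(events, abundance) {
  transmitted <- intersect(unique(events$strain_id), rownames(abundance))
  totals <- colSums(abundance)
  if (any(totals == 0)) stop("sample(s) with zero total abundance")
  if (length(transmitted) == 0) {
    return(stats::setNames(rep(0, ncol(abundance)), colnames(abundance)))
  }
  colSums(abundance[transmitted, , drop = FALSE]) / totals
}
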