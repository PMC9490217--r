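#' Validate pipeline input tables
#'
#' Checks the sample metadata, abundance and coverage tables for the column,
#' type and consistency problems that would break downstream stages.
#' Findings are returned, not raised.
#'
#' @param metadata Sample metadata data.frame.
#' @param abundance Optional strain x sample abundance matrix.
#' @param coverage Optional coverage data.frame.
#' @return data.frame with `level` (`"error"`/`"warning"`) and `message`.
#' @export
validate_inputs <- function(metadata, abundance = NULL, coverage = NULL) {
  findings <- list()
  add <- function(level, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = message, stringsAsFactors = FALSE
    )
  }
  need <- c("sample_id", "host_id", "host_species", "gut_site", "group", "timepoint")
  for (col in setdiff(need, names(metadata))) {
    add("error", paste0("metadata is missing column '", col, "'"))
  }
  if ("sample_id" %in% names(metadata) && anyDuplicated(metadata$sample_id)) {
    add("error", "metadata has duplicated sample_id values")
  }
  if ("group" %in% names(metadata) && length(unique(metadata$group)) < 2) {
    add("warning", "metadata 'group' has a single level; group comparisons are impossible")
  }
  if (!is.null(abundance)) {
    if (any(abundance < 0)) add("error", "abundance has negative entries")
    if ("sample_id" %in% names(metadata)) {
      orphans <- setdiff(colnames(abundance), metadata$sample_id)
      for (s in orphans) {
        add("error", paste0("abundance sample '", s, "' is absent from metadata"))
      }
    }
  }
  if (!is.null(coverage)) {
    for (col in setdiff(c("strain_id", "sample_id", "breadth", "depth"), names(coverage))) {
      add("error", paste0("coverage is missing column '", col, "'"))
    }
  }
  if (length(findings) == 0) {
    return(data.frame(level = character(0), message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

matrix_to_tsv <- function(mat, id_col, path) {
  df <- data.frame(rownames(mat), mat, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> allele calling -> presence filter -> incidence ->
#' transmission scoring -> event calling -> summaries -> community
#' statistics, all from one [sim_config()]. When `out_dir` is given, writes
#' `metadata.tsv`, `abundance.tsv`, `coverage.tsv`, `scores.tsv`,
#' `events.tsv`, `truth_events.tsv` and `report.json` there (existing files
#' are reused-in-place only in the sense that they are overwritten when
#' `force = TRUE` or absent; with `force = FALSE` an existing `report.json`
#' short-circuits the write).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param score_threshold Minimum S_T to call an event.
#' @param min_alleles,min_pairs Scoring gates, see [score_transmission()].
#' @param min_breadth,min_depth Presence-filter bounds.
#' @param n_perm PERMANOVA permutations.
#' @param force Overwrite existing outputs.
#' @return A list with every stage's tables and the `report` summary list.
#' @export
run_study_pipeline <- function(config = sim_config(), out_dir = NULL,
                               score_threshold = 2.0,
                               min_alleles = 20, min_pairs = 3,
                               min_breadth = 0.10, min_depth = 0.15,
                               n_perm = 999, force = FALSE) {
  study <- generate_study(config)
  called <- call_alleles_table(study$pileup)
  screened <- presence_filter(study$coverage, min_breadth, min_depth)
  scores <- score_transmission(
    called$calls, called$covered, screened, study$metadata,
    min_alleles = min_alleles, min_pairs = min_pairs
  )
  events <- detect_events(scores, study$metadata, threshold = score_threshold)
  event_summary <- summarize_events(
    events, total_strains = config$n_strains, phyla = study$truth$strain_phyla
  )

  taxonomy <- data.frame(
    mag_id = names(study$truth$strain_phyla),
    phylum = unname(study$truth$strain_phyla),
    stringsAsFactors = FALSE
  )
  phylum_fractions <- phylum_relative_abundance(study$abundance, taxonomy)
  alpha <- alpha_diversity(study$abundance)
  transmitted_fraction <- transmitted_abundance_fraction(events, study$abundance)

  # per-habitat cohoused-vs-control PERMANOVA on Bray-Curtis, as in the
  # study design (goat rumen, goat cecum, pig cecum analyzed separately)
  habitats <- unique(paste(study$metadata$host_species, study$metadata$gut_site))
  permanova_tables <- list()
  for (h in habitats) {
    keep <- paste(study$metadata$host_species, study$metadata$gut_site) == h
    ids <- study$metadata$sample_id[keep]
    sub_meta <- study$metadata[keep, , drop = FALSE]
    if (length(unique(sub_meta$group)) < 2 || length(ids) < 4) next
    d <- bray_curtis(study$abundance[, ids, drop = FALSE])
    permanova_tables[[h]] <- permanova(
      d, sub_meta, terms = "group", n_perm = n_perm, seed = config$seed
    )
  }

  report <- list(
    seed = config$seed,
    n_strains = config$n_strains,
    n_samples = nrow(study$metadata),
    profiles_kept = attr(screened, "n_kept"),
    profiles_dropped = attr(screened, "n_dropped"),
    n_scored_pairs = nrow(scores),
    n_eligible_pairs = attr(events, "n_eligible"),
    n_events = nrow(events),
    event_summary = event_summary,
    n_planted_events = nrow(study$truth$planted_events),
    permanova = lapply(permanova_tables, function(x) {
      list(term = x$term[1], pseudo_F = x$pseudo_F[1], R2 = x$R2[1], p_value = x$p_value[1])
    })
  )

  result <- list(
    config = config, study = study, screened = screened, scores = scores,
    events = events, event_summary = event_summary,
    phylum_fractions = phylum_fractions, alpha = alpha,
    transmitted_fraction = transmitted_fraction,
    permanova = permanova_tables, report = report
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    report_path <- file.path(out_dir, "report.json")
    if (force || !file.exists(report_path)) {
      write_tsv(study$metadata, file.path(out_dir, "metadata.tsv"))
      matrix_to_tsv(study$abundance, "strain_id", file.path(out_dir, "abundance.tsv"))
      write_tsv(study$coverage, file.path(out_dir, "coverage.tsv"))
      write_tsv(scores, file.path(out_dir, "scores.tsv"))
      write_tsv(events, file.path(out_dir, "events.tsv"))
      write_tsv(study$truth$planted_events, file.path(out_dir, "truth_events.tsv"))
      jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  result
}

#' Compare called events against the planted truth
#'
#' Matches called events to planted events by strain and unordered sample
#' pair, optionally restricted to event types, and reports sensitivity
#' (recall of planted events) and precision (fraction of calls that were
#' planted).
#'
#' @param events Called events ([detect_events()] output).
#' @param truth_events Planted events (`truth$planted_events`).
#' @param types Optional event types to restrict both sides to, e.g.
#'   `c("intra_species", "inter_species")` for the cohoused events.
#' @return List `sensitivity`, `precision`, `n_planted`, `n_called`,
#'   `n_matched`.
#' @export
event_recovery <- function(events, truth_events, types = NULL) {
  pair_key <- function(df, a, b) {
    paste(df$strain_id, pmin(df[[a]], df[[b]]), pmax(df[[a]], df[[b]]), sep = "\r")
  }
  if (!is.null(types)) {
    events <- events[events$event_type %in% types, , drop = FALSE]
    truth_events <- truth_events[truth_events$event_type %in% types, , drop = FALSE]
  }
  called <- unique(pair_key(events, "sample_a", "sample_b"))
  planted <- unique(pair_key(truth_events, "donor_sample", "recipient_sample"))
  n_matched <- length(intersect(called, planted))
  list(
    sensitivity = if (length(planted)) n_matched / length(planted) else NA_real_,
    precision = if (length(called)) n_matched / length(called) else NA_real_,
    n_planted = length(planted),
    n_called = length(called),
    n_matched = n_matched
  )
}
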