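#' Configuration for a synthetic cohousing study
#'
#' Bundles and validates every knob of the synthetic-study generator. The
#' defaults mirror the cohousing design the pipeline targets: 15 goats and
#' 15 pigs with six of each species cohoused in one pen, goats sampled at
#' rumen (foregut) and cecum (hindgut), pigs at cecum only.
#'
#' @param n_strains Number of strains in the catalog.
#' @param n_goats,n_pigs Total hosts per species.
#' @param n_cohoused_goats,n_cohoused_pigs Hosts of each species in the
#'   cohoused (social contact) group; the rest are controls in separate pens.
#' @param timepoints Character vector of sampling timepoint labels.
#' @param n_positions_per_strain Polymorphic positions tracked per strain.
#' @param mean_depth Mean per-position read depth (x) for a strain of average
#'   abundance.
#' @param breadth_range Length-2 fraction interval from which each profile's
#'   horizontal coverage (breadth) is drawn.
#' @param seq_error_rate Per-read probability that a base call reports the
#'   wrong allele.
#' @param base_quality_mean Mean Phred quality; per-read qualities are
#'   Normal(`base_quality_mean`, 3) truncated to `[2, 41]` and rounded.
#' @param transmission_rate Probability of planting a strain-sharing event on
#'   an eligible cohoused sample pair (see [generate_study()]).
#' @param foregut_hindgut_rate Probability of planting a rumen-to-cecum
#'   sharing event per goat and strain.
#' @param haplotype_mutation_rate Per-position flip probability applied when a
#'   haplotype is copied during planting.
#' @param mixing_coefficient Fraction in `[0, 1]` pulling cohoused sample
#'   compositions toward the cross-species cohoused mean composition.
#' @param habitat_occupancy Probability that a strain occupies each of the
#'   three habitats (goat rumen, goat cecum, pig cecum).
#' @param seed Integer seed; fixes all generator output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 50,
                       n_goats = 15, n_pigs = 15,
                       n_cohoused_goats = 6, n_cohoused_pigs = 6,
                       timepoints = "m3",
                       n_positions_per_strain = 200,
                       mean_depth = 10,
                       breadth_range = c(0.7, 0.95),
                       seq_error_rate = 0.002,
                       base_quality_mean = 30,
                       transmission_rate = 0.3,
                       foregut_hindgut_rate = 0.3,
                       haplotype_mutation_rate = 0.005,
                       mixing_coefficient = 0.3,
                       habitat_occupancy = 0.6,
                       seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains),
    n_goats = as.integer(n_goats), n_pigs = as.integer(n_pigs),
    n_cohoused_goats = as.integer(n_cohoused_goats),
    n_cohoused_pigs = as.integer(n_cohoused_pigs),
    timepoints = as.character(timepoints),
    n_positions_per_strain = as.integer(n_positions_per_strain),
    mean_depth = mean_depth,
    breadth_range = breadth_range,
    seq_error_rate = seq_error_rate,
    base_quality_mean = base_quality_mean,
    transmission_rate = transmission_rate,
    foregut_hindgut_rate = foregut_hindgut_rate,
    haplotype_mutation_rate = haplotype_mutation_rate,
    mixing_coefficient = mixing_coefficient,
    habitat_occupancy = habitat_occupancy,
    seed = as.integer(seed)
  )
  counts <- c(
    cfg$n_strains, cfg$n_goats, cfg$n_pigs,
    cfg$n_positions_per_strain, length(cfg$timepoints)
  )
  if (any(counts < 1)) stop("counts must be >= 1")
  if (cfg$n_cohoused_goats > cfg$n_goats || cfg$n_cohoused_pigs > cfg$n_pigs) {
    stop("cohoused counts must not exceed total host counts")
  }
  if (cfg$n_cohoused_goats < 0 || cfg$n_cohoused_pigs < 0) stop("cohoused counts must be >= 0")
  probs <- c(
    cfg$seq_error_rate, cfg$transmission_rate, cfg$foregut_hindgut_rate,
    cfg$haplotype_mutation_rate, cfg$mixing_coefficient, cfg$habitat_occupancy
  )
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be within [0, 1]")
  if (length(cfg$breadth_range) != 2 || any(cfg$breadth_range < 0 | cfg$breadth_range > 1) ||
    cfg$breadth_range[1] > cfg$breadth_range[2]) {
    stop("breadth_range must be an increasing fraction interval within [0, 1]")
  }
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  structure(cfg, class = "sim_config")
}

# probability that a rounded truncated-Normal(base_quality, 3) Phred score
# on [2, 41] reaches the >= 15 call-quality gate
phred_pass_prob <- function(base_quality_mean, threshold = 15, sd = 3, lo = 2, hi = 41) {
  denom <- stats::pnorm(hi, base_quality_mean, sd) - stats::pnorm(lo, base_quality_mean, sd)
  num <- stats::pnorm(hi, base_quality_mean, sd) - stats::pnorm(threshold - 0.5, base_quality_mean, sd)
  max(0, min(1, num / denom))
}

flip_bits <- function(x, rate) {
  if (rate <= 0) return(x)
  as.integer(xor(x == 1L, stats::rbinom(length(x), 1L, rate) == 1L))
}

#' Generate a full synthetic cohousing study
#'
#' Builds a complete study from a [sim_config()]: a strain catalog with
#' phylum labels, sample metadata (host, species, gut site, cohoused/control
#' group, timepoint), habitat-specific log-normal strain abundances (cohoused
#' compositions linearly mixed toward the cohoused mean), binary strain
#' haplotypes over polymorphic positions, Poisson-depth pileups with
#' sequencing error and truncated-normal base qualities, and a truth table of
#' planted transmission events.
#'
#' Planting proceeds in two passes over dedicated RNG streams derived from
#' the seed. Foregut-hindgut events: per goat and strain present in both of
#' the goat's gut sites, with probability `foregut_hindgut_rate` the cecum
#' haplotype becomes a mutated copy of the rumen haplotype. Cohoused events:
#' eligible pairs are same-gut-site sample pairs between two different
#' cohoused hosts that both carry the strain and whose hosts are not yet part
#' of a planted pair for that strain (a per-strain host matching, so planted
#' links never chain into unplanted sharing); each eligible pair succeeds
#' with probability `transmission_rate`, upon which the recipient's haplotype
#' becomes a mutated copy of the donor's. A copy landing on a goat site that
#' has a planted foregut-hindgut link for the strain is propagated to the
#' goat's other site so both planted events stay true.
#'
#' @param config A [sim_config()].
#' @return A list of class `strain_study` with components `metadata`
#'   (data.frame), `abundance` (strain x sample CPM matrix), `coverage`
#'   (data.frame: strain_id, sample_id, breadth, depth), `pileup`
#'   (data.frame: strain_id, sample_id, position, allele, read_count,
#'   min_phred_passing_count) and `truth` (planted_events, strain_phyla,
#'   haplotypes array, habitat occupancy matrix, config).
#' @export
generate_study <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be created by sim_config()")
  n_pos <- config$n_positions_per_strain

  ## -- catalog, hosts, samples -------------------------------------------
  set.seed(config$seed)
  strain_ids <- sprintf("S%03d", seq_len(config$n_strains))
  phyla_pool <- c(
    "Firmicutes_A", "Bacteroidota", "Proteobacteria", "Firmicutes",
    "Verrucomicrobiota", "Spirochaetota", "Actinobacteriota", "Thermoplasmatota"
  )
  phyla_w <- c(0.38, 0.37, 0.05, 0.05, 0.05, 0.04, 0.04, 0.02)
  strain_phyla <- stats::setNames(
    sample(phyla_pool, config$n_strains, replace = TRUE, prob = phyla_w), strain_ids
  )

  goats <- sprintf("G%02d", seq_len(config$n_goats))
  pigs <- sprintf("P%02d", seq_len(config$n_pigs))
  units <- rbind(
    data.frame(
      host_id = rep(goats, each = 2), host_species = "goat",
      gut_site = rep(c("rumen", "cecum"), config$n_goats),
      stringsAsFactors = FALSE
    ),
    data.frame(
      host_id = pigs, host_species = "pig", gut_site = "cecum",
      stringsAsFactors = FALSE
    )
  )
  units$group <- ifelse(
    (units$host_species == "goat" & units$host_id %in% goats[seq_len(config$n_cohoused_goats)]) |
      (units$host_species == "pig" & units$host_id %in% pigs[seq_len(config$n_cohoused_pigs)]),
    "cohoused", "control"
  )
  units$unit_id <- paste(units$host_id, units$gut_site, sep = "_")
  units$habitat <- paste(units$host_species, units$gut_site, sep = "_")

  metadata <- do.call(rbind, lapply(config$timepoints, function(tp) {
    m <- units
    m$timepoint <- tp
    m$sample_id <- paste(m$unit_id, tp, sep = "_")
    m
  }))
  metadata <- metadata[, c(
    "sample_id", "host_id", "host_species", "gut_site", "group", "timepoint", "unit_id", "habitat"
  )]
  rownames(metadata) <- NULL

  ## -- habitat occupancy and abundances ----------------------------------
  habitats <- c("goat_rumen", "goat_cecum", "pig_cecum")
  occ <- matrix(
    stats::rbinom(config$n_strains * 3, 1L, config$habitat_occupancy),
    config$n_strains, 3,
    dimnames = list(strain_ids, habitats)
  )
  empty <- which(rowSums(occ) == 0)
  if (length(empty)) occ[cbind(empty, sample.int(3, length(empty), replace = TRUE))] <- 1L
  meanlog <- matrix(
    stats::rnorm(config$n_strains * 3, 0, 1), config$n_strains, 3,
    dimnames = list(strain_ids, habitats)
  )

  comp <- matrix(0, config$n_strains, nrow(metadata),
    dimnames = list(strain_ids, metadata$sample_id)
  )
  for (j in seq_len(nrow(metadata))) {
    hab <- metadata$habitat[j]
    present <- occ[, hab] == 1L
    raw <- numeric(config$n_strains)
    raw[present] <- stats::rlnorm(sum(present), meanlog[present, hab], 0.5)
    if (sum(raw) == 0) stop("internal: sample with no occupying strain")
    comp[, j] <- raw / sum(raw)
  }
  cohoused_samples <- metadata$sample_id[metadata$group == "cohoused"]
  if (length(cohoused_samples) > 0 && config$mixing_coefficient > 0) {
    m <- config$mixing_coefficient
    pen_mean <- rowMeans(comp[, cohoused_samples, drop = FALSE])
    comp[, cohoused_samples] <- (1 - m) * comp[, cohoused_samples, drop = FALSE] + m * pen_mean
  }
  abundance <- comp * 1e6

  # planting eligibility: a unit is a genuine carrier of a strain iff the
  # strain occupies the unit's habitat. Trace abundance received only through
  # pen-level composition mixing does not qualify -- a planted transmission
  # event must be observable from both samples' reads to be a meaningful
  # truth entry.
  unit_presence <- occ[, units$habitat, drop = FALSE] == 1L
  colnames(unit_presence) <- units$unit_id

  ## -- haplotypes ---------------------------------------------------------
  q <- matrix(stats::runif(n_pos * config$n_strains, 0.2, 0.8), n_pos, config$n_strains,
    dimnames = list(NULL, strain_ids)
  )
  hap <- array(0L, c(n_pos, nrow(units), config$n_strains),
    dimnames = list(NULL, units$unit_id, strain_ids)
  )
  for (s in seq_len(config$n_strains)) {
    hap[, , s] <- matrix(
      stats::rbinom(n_pos * nrow(units), 1L, q[, s]), n_pos, nrow(units)
    )
  }

  ## -- planted foregut-hindgut events (goats only) ------------------------
  set.seed(config$seed + 10007L)
  mu <- config$haplotype_mutation_rate
  events <- list()
  fh_link <- matrix(FALSE, config$n_strains, config$n_goats,
    dimnames = list(strain_ids, goats)
  )
  for (g in goats) {
    rum <- paste(g, "rumen", sep = "_")
    cec <- paste(g, "cecum", sep = "_")
    for (s in strain_ids) {
      if (!(unit_presence[s, rum] && unit_presence[s, cec])) next
      if (stats::runif(1) < config$foregut_hindgut_rate) {
        hap[, cec, s] <- flip_bits(hap[, rum, s], mu)
        fh_link[s, g] <- TRUE
        events[[length(events) + 1L]] <- data.frame(
          strain_id = s,
          donor_sample = paste(rum, config$timepoints, sep = "_"),
          recipient_sample = paste(cec, config$timepoints, sep = "_"),
          event_type = "foregut_hindgut", stringsAsFactors = FALSE
        )
      }
    }
  }

  ## -- planted cohoused events (per-strain host matching) -----------------
  # decision pass: a pure Bernoulli stream over the eligible pairs, kept free
  # of any other draws so it can be replayed independently for validation
  set.seed(config$seed + 20007L)
  co_units <- units[units$group == "cohoused", , drop = FALSE]
  co_units <- co_units[order(co_units$unit_id), , drop = FALSE]
  pair_idx <- if (nrow(co_units) >= 2) utils::combn(nrow(co_units), 2) else matrix(0L, 2, 0)
  planted <- list()
  for (s in strain_ids) {
    used_hosts <- character(0)
    for (k in seq_len(ncol(pair_idx))) {
      a <- co_units[pair_idx[1, k], ]
      b <- co_units[pair_idx[2, k], ]
      if (a$gut_site != b$gut_site || a$host_id == b$host_id) next
      if (a$host_id %in% used_hosts || b$host_id %in% used_hosts) next
      if (!(unit_presence[s, a$unit_id] && unit_presence[s, b$unit_id])) next
      if (stats::runif(1) < config$transmission_rate) {
        used_hosts <- c(used_hosts, a$host_id, b$host_id)
        planted[[length(planted) + 1L]] <- list(strain = s, a = a, b = b)
      }
    }
  }
  # copy pass: apply the recorded plantings on a separate stream
  set.seed(config$seed + 25013L)
  for (pl in planted) {
    s <- pl$strain; a <- pl$a; b <- pl$b
    hap[, b$unit_id, s] <- flip_bits(hap[, a$unit_id, s], mu)
    if (b$host_species == "goat" && fh_link[s, b$host_id]) {
      other <- paste(b$host_id, setdiff(c("rumen", "cecum"), b$gut_site), sep = "_")
      hap[, other, s] <- flip_bits(hap[, b$unit_id, s], mu)
    }
    events[[length(events) + 1L]] <- data.frame(
      strain_id = s,
      donor_sample = paste(a$unit_id, config$timepoints, sep = "_"),
      recipient_sample = paste(b$unit_id, config$timepoints, sep = "_"),
      event_type = if (a$host_species == b$host_species) "intra_species" else "inter_species",
      stringsAsFactors = FALSE
    )
  }
  planted_events <- if (length(events)) {
    do.call(rbind, events)
  } else {
    data.frame(
      strain_id = character(0), donor_sample = character(0),
      recipient_sample = character(0), event_type = character(0),
      stringsAsFactors = FALSE
    )
  }
  rownames(planted_events) <- NULL

  ## -- pileups and coverage ------------------------------------------------
  set.seed(config$seed + 30007L)
  p15 <- phred_pass_prob(config$base_quality_mean)
  acc <- list()
  cov_rows <- list()
  unit_of <- stats::setNames(metadata$unit_id, metadata$sample_id)
  for (j in seq_len(nrow(metadata))) {
    smp <- metadata$sample_id[j]
    present <- comp[, j] > 0
    if (!any(present)) next
    w_all <- comp[, j] / mean(comp[present, j])
    for (s in strain_ids[present]) {
      w <- min(w_all[s], 10)
      breadth <- stats::runif(1, config$breadth_range[1], config$breadth_range[2])
      n_cov <- max(1L, round(breadth * n_pos))
      covered <- sort(sample.int(n_pos, n_cov))
      d <- stats::rpois(n_cov, config$mean_depth * w)
      keep <- d > 0
      covered <- covered[keep]
      d <- d[keep]
      depth <- sum(d) / n_pos
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        strain_id = s, sample_id = smp, breadth = breadth, depth = depth,
        stringsAsFactors = FALSE
      )
      if (length(d) == 0) next
      h <- hap[covered, unit_of[[smp]], s]
      n_err <- stats::rbinom(length(d), d, config$seq_error_rate)
      alt_n <- ifelse(h == 1L, d - n_err, n_err)
      ref_n <- d - alt_n
      pass_alt <- stats::rbinom(length(d), alt_n, p15)
      pass_ref <- stats::rbinom(length(d), ref_n, p15)
      ka <- alt_n > 0
      kr <- ref_n > 0
      acc[[length(acc) + 1L]] <- data.frame(
        strain_id = s, sample_id = smp,
        position = c(covered[kr], covered[ka]),
        allele = c(rep("ref", sum(kr)), rep("alt", sum(ka))),
        read_count = c(ref_n[kr], alt_n[ka]),
        min_phred_passing_count = c(pass_ref[kr], pass_alt[ka]),
        stringsAsFactors = FALSE
      )
    }
  }
  pileup <- do.call(rbind, acc)
  rownames(pileup) <- NULL
  coverage <- do.call(rbind, cov_rows)
  rownames(coverage) <- NULL

  meta_out <- metadata[, c(
    "sample_id", "host_id", "host_species", "gut_site", "group", "timepoint"
  )]
  structure(
    list(
      metadata = meta_out,
      abundance = abundance,
      coverage = coverage,
      pileup = pileup,
      truth = list(
        planted_events = planted_events,
        strain_phyla = strain_phyla,
        haplotypes = hap,
        allele_frequencies = q,
        occupancy = occ,
        config = config
      )
    ),
    class = "strain_study"
  )
}

#' Randomly drop observed alleles from a strain profile
#'
#' Robustness helper: removes each called allele independently with
#' probability `dropout_rate`, leaving coverage and depth untouched.
#'
#' @param profile A `strain_profile` (see [call_alleles()]) or a data.frame
#'   of called alleles.
#' @param dropout_rate Probability in `[0, 1]` of dropping each allele.
#' @param seed Integer seed.
#' @return Object of the same type with the surviving alleles.
#' @export
corrupt_profile <- function(profile, dropout_rate, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate must be within [0, 1]")
  set.seed(as.integer(seed))
  drop_rows <- function(df) {
    if (nrow(df) == 0 || dropout_rate == 0) return(df)
    keep <- stats::rbinom(nrow(df), 1L, 1 - dropout_rate) == 1L
    df[keep, , drop = FALSE]
  }
  if (inherits(profile, "strain_profile")) {
    profile$alleles <- drop_rows(profile$alleles)
    profile
  } else if (is.data.frame(profile)) {
    drop_rows(profile)
  } else {
    stop("profile must be a strain_profile or a data.frame of alleles")
  }
}

#' Simulate a table of MAG quality records
#'
#' Draws completeness, contamination and N50 spanning the retention and tier
#' boundaries, for exercising the MAG QC stage.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @return data.frame with `mag_id`, `completeness`, `contamination`, `n50`,
#'   `phylum`.
#' @export
simulate_mag_records <- function(n = 100, seed = 1L) {
  set.seed(as.integer(seed))
  data.frame(
    mag_id = sprintf("MAG%04d", seq_len(n)),
    completeness = round(stats::runif(n, 40, 100), 2),
    contamination = round(pmin(stats::rexp(n, 1 / 3), 25), 2),
    n50 = pmax(1, round(stats::rlnorm(n, log(5e4), 1))),
    phylum = sample(c("Firmicutes_A", "Bacteroidota", "Proteobacteria"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a hierarchical pairwise ANI table
#'
#' Builds genomes nested as species clusters containing strain clusters:
#' within-strain ANI in `[99.2, 99.9]`, between strains of one species in
#' `[95.5, 98.5]`, between species in `[80, 92]`. Useful for checking that
#' 99% clusters nest inside 95% clusters.
#'
#' @param n_species Number of species-level clusters.
#' @param strains_per_species Strain clusters per species.
#' @param genomes_per_strain Genomes per strain cluster.
#' @param seed Integer seed.
#' @return data.frame (`query_id`, `target_id`, `ani`, `aligned_fraction`)
#'   with attributes `species_of` and `strain_of` (named truth vectors).
#' @export
simulate_ani_table <- function(n_species = 3, strains_per_species = 2,
                               genomes_per_strain = 3, seed = 1L) {
  set.seed(as.integer(seed))
  ids <- character(0)
  species_of <- character(0)
  strain_of <- character(0)
  for (sp in seq_len(n_species)) {
    for (st in seq_len(strains_per_species)) {
      for (g in seq_len(genomes_per_strain)) {
        id <- sprintf("g%d_%d_%d", sp, st, g)
        ids <- c(ids, id)
        species_of <- c(species_of, sprintf("sp%d", sp))
        strain_of <- c(strain_of, sprintf("sp%d_st%d", sp, st))
      }
    }
  }
  names(species_of) <- ids
  names(strain_of) <- ids
  pairs <- utils::combn(length(ids), 2)
  ani <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ani[k] <- if (strain_of[i] == strain_of[j]) {
      stats::runif(1, 99.2, 99.9)
    } else if (species_of[i] == species_of[j]) {
      stats::runif(1, 95.5, 98.5)
    } else {
      stats::runif(1, 80, 92)
    }
  }
  out <- data.frame(
    query_id = ids[pairs[1, ]], target_id = ids[pairs[2, ]],
    ani = ani, aligned_fraction = stats::runif(ncol(pairs), 66, 95),
    stringsAsFactors = FALSE
  )
  attr(out, "species_of") <- species_of
  attr(out, "strain_of") <- strain_of
  out
}
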