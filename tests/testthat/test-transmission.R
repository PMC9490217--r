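test_that("agreement-class probabilities are independence products summing to one", {
  p <- pair_probabilities(0.5)
  expect_equal(unlist(p), c(p11 = 0.25, p00 = 0.25, p10 = 0.25, p01 = 0.25))
  p2 <- pair_probabilities(0.2)
  expect_equal(unlist(p2), c(p11 = 0.04, p00 = 0.64, p10 = 0.16, p01 = 0.16))
  f_hi <- clamp_incidence(1, n_screen = 1000)
  p3 <- pair_probabilities(f_hi)
  expect_gt(p3$p11, 0.998)
  expect_lt(p3$p00 + p3$p10 + p3$p01, 0.002)
  for (f in seq(0.05, 0.95, by = 0.1)) {
    pf <- pair_probabilities(f)
    expect_equal(pf$p11 + pf$p00 + pf$p10 + pf$p01, 1)
    expect_true(all(unlist(pf) > 0 & unlist(pf) < 1))
  }
  expect_error(pair_probabilities(1.2), "within")
  # the literal printed difference forms degenerate to zero at equal f
  lit <- pair_probabilities(0.3, method = "literal")
  expect_equal(lit$p11, 0)
  expect_equal(lit$p10, 0.3 - 0.7)
})

test_that("clamping keeps incidences in the open unit interval", {
  expect_equal(clamp_incidence(1, 4), 1 - 1 / 8)
  expect_equal(clamp_incidence(0, 4), 1 / 8)
  expect_equal(clamp_incidence(0.5, 4), 0.5)
  expect_error(clamp_incidence(0.5, 0), "n_screen")
})

test_that("overlap likelihood matches closed forms and the two-allele example", {
  # all alleles agree as (0,0) at f = 0.5: L_obs = n log 0.25 = L_min
  n <- 30
  ol <- overlap_likelihood(rep("00", n), rep(0.5, n))
  expect_equal(ol$L_obs, n * log(0.25))
  expect_equal(ol$L_min, n * log(0.25))
  expect_equal(raw_score(ol$L_obs, ol$L_min), 1)

  ol2 <- overlap_likelihood(c("11", "01"), c(0.2, 0.8), min_alleles = 1)
  expect_equal(ol2$L_obs, log(0.04) - log(0.16))
  expect_equal(ol2$L_min, log(0.04) + log(0.04))
  expect_equal(raw_score(ol2$L_obs, ol2$L_min), (log(0.04) - log(0.16)) / (2 * log(0.04)))

  # below the allele gate the comparison is skipped
  expect_null(overlap_likelihood(rep("00", 5), rep(0.5, 5), min_alleles = 20))
  expect_error(overlap_likelihood("zz", 0.5, min_alleles = 1), "classes")
})

test_that("likelihoods match a brute-force per-allele oracle within 1e-9", {
  set.seed(17)
  f_grid <- seq(0.05, 0.95, by = 0.05)
  classes_pool <- c("11", "00", "10", "01")
  for (rep_i in 1:40) {
    n <- sample(1:10, 1)
    classes <- sample(classes_pool, n, replace = TRUE)
    f <- sample(f_grid, n, replace = TRUE)
    got <- overlap_likelihood(classes, f, min_alleles = 1)
    want <- brute_force_overlap(classes, f)
    expect_equal(got$L_obs, want$L_obs, tolerance = 1e-9)
    expect_equal(got$L_min, want$L_min, tolerance = 1e-9)
    expect_equal(raw_score(got$L_obs, got$L_min), want$P_raw, tolerance = 1e-9)
  }
})

test_that("raw score is the L_obs/L_min ratio with negative L_min", {
  expect_equal(raw_score(-3, -3), 1)
  expect_equal(raw_score(0, -3), 0)
  expect_error(raw_score(-1, 0), "negative")
})

test_that("standardization yields z-scores with sample-sd denominator", {
  expect_equal(standardize_scores(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize_scores(c(0.1, 0.2, 0.2, 0.5))
  expect_equal(z, c(-0.8660254, -0.2886751, -0.2886751, 1.4433757), tolerance = 1e-6)
  expect_true(all(is.na(standardize_scores(c(0.3, 0.3, 0.3)))))
  expect_true(all(is.na(standardize_scores(c(0.1, 0.9)))))  # below min_pairs
  set.seed(5)
  for (i in 1:10) {
    v <- rnorm(sample(3:30, 1))
    zz <- standardize_scores(v)
    expect_equal(mean(zz), 0, tolerance = 1e-9)
    expect_equal(sd(zz), 1, tolerance = 1e-9)
  }
})

test_that("swapping the two samples of a pair leaves the score unchanged", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    classes <- sample(c("11", "00", "10", "01"), n, replace = TRUE)
    f <- runif(n, 0.1, 0.9)
    swapped <- unname(c(`11` = "11", `00` = "00", `10` = "01", `01` = "10")[classes])
    a <- overlap_likelihood(classes, f, min_alleles = 1)
    b <- overlap_likelihood(swapped, f, min_alleles = 1)
    expect_equal(a$L_obs, b$L_obs)
    expect_equal(a$L_min, b$L_min)
  }
})

test_that("event classification follows host identity, species, and gut site", {
  goatA_r <- meta_row("G1", "goat", "rumen")
  goatA_c <- meta_row("G1", "goat", "cecum")
  goatB_c <- meta_row("G2", "goat", "cecum")
  pigC_c <- meta_row("P1", "pig", "cecum")
  expect_equal(classify_event(goatA_r, goatA_c), "foregut_hindgut")
  expect_equal(classify_event(goatA_c, goatB_c), "intra_species")
  expect_equal(classify_event(goatA_c, pigC_c), "inter_species")
  expect_error(classify_event(goatA_c, goatA_c), "not an eligible pair")
})

test_that("event detection respects the threshold and eligibility rules", {
  study <- generate_study(small_config(seed = 4))
  scores <- score_study(study)
  none <- detect_events(scores, study$metadata, threshold = Inf)
  expect_equal(nrow(none), 0)
  all_called <- detect_events(scores, study$metadata, threshold = -Inf)
  expect_gt(nrow(all_called), 0)
  meta <- study$metadata
  rownames(meta) <- meta$sample_id
  # at threshold -Inf every eligible scored pair with a defined S_T is called
  sa <- meta[scores$sample_a, ]; sb <- meta[scores$sample_b, ]
  eligible <- (sa$host_id == sb$host_id & sa$gut_site != sb$gut_site) |
    (sa$host_id != sb$host_id & sa$gut_site == sb$gut_site &
      sa$group == "cohoused" & sb$group == "cohoused")
  expect_equal(nrow(all_called), sum(eligible & !is.na(scores$S_T)))
  expect_equal(attr(all_called, "n_eligible"), sum(eligible))
  a <- meta[all_called$sample_a, ]; b <- meta[all_called$sample_b, ]
  within <- a$host_id == b$host_id
  expect_true(all(a$gut_site[within] != b$gut_site[within]))
  expect_true(all(a$group[!within] == "cohoused" & b$group[!within] == "cohoused"))
  expect_true(all(a$gut_site[!within] == b$gut_site[!within]))
})

test_that("event summaries reproduce proportion arithmetic", {
  s <- summarize_events(
    list(only_intra = 190, only_inter = 12, only_foregut_hindgut = 10, multiple = 19),
    total_strains = 3262
  )
  expect_equal(s$n_transmitted, 231)
  expect_equal(s$pct_transmitted, 7.08)
  expect_equal(s$pct_only_intra, 82.25)
  expect_equal(s$pct_only_inter, 5.19)
  expect_equal(s$pct_only_foregut_hindgut, 4.33)

  empty <- summarize_events(
    data.frame(strain_id = character(0), event_type = character(0)),
    total_strains = 10
  )
  expect_equal(empty$n_transmitted, 0)
  expect_equal(empty$pct_transmitted, 0)

  ev <- data.frame(
    strain_id = c("S1", "S1", "S2", "S3", "S3"),
    event_type = c("intra_species", "intra_species", "inter_species",
      "intra_species", "foregut_hindgut")
  )
  s2 <- summarize_events(ev, total_strains = 4,
    phyla = c(S1 = "PhyA", S2 = "PhyA", S3 = "PhyB"))
  expect_equal(s2$only_intra, 1)
  expect_equal(s2$only_inter, 1)
  expect_equal(s2$multiple, 1)
  expect_equal(s2$pct_transmitted, 75)
  expect_equal(s2$phylum_breakdown_pct$PhyA, round(100 * 2 / 3, 2))
  expect_error(summarize_events(ev, total_strains = 2), "smaller")
})

test_that("transmitted abundance fraction sums transmitted strains per sample", {
  ab <- matrix(c(250000, 750000, 500000, 500000), 2, 2,
    dimnames = list(c("S1", "S2"), c("a", "b"))
  )
  ev <- data.frame(strain_id = "S1")
  expect_equal(unname(transmitted_abundance_fraction(ev, ab)), c(0.25, 0.5))
  expect_equal(
    unname(transmitted_abundance_fraction(data.frame(strain_id = character(0)), ab)),
    c(0, 0)
  )
  both <- data.frame(strain_id = c("S1", "S2"))
  expect_equal(unname(transmitted_abundance_fraction(both, ab)), c(1, 1))
})
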