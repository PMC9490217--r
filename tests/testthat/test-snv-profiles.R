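pileup_row <- function(position, allele, n, n_pass, strain = "S1", sample = "a") {
  data.frame(
    strain_id = strain, sample_id = sample, position = position,
    allele = allele, read_count = n, min_phred_passing_count = n_pass,
    stringsAsFactors = FALSE
  )
}

test_that("allele calls need two reads passing the Phred >= 15 gate", {
  # one high-quality read is not enough
  p1 <- pileup_row(1, "alt", 1, 1)
  expect_equal(nrow(call_alleles(p1)$alleles), 0)
  # exactly two qualifying reads: called (boundary inclusive)
  p2 <- pileup_row(1, "alt", 2, 2)
  prof <- call_alleles(p2)
  expect_equal(prof$alleles$allele, "alt")
  expect_equal(prof$covered_positions, 1L)
  # 3 reads below Phred 15 plus one above: only 1 qualifying read
  p3 <- pileup_row(1, "alt", 4, 1)
  expect_equal(nrow(call_alleles(p3)$alleles), 0)
  expect_equal(length(call_alleles(p3)$covered_positions), 0)
  # qualifying depth pools alleles at a position
  p4 <- rbind(pileup_row(5, "ref", 1, 1), pileup_row(5, "alt", 1, 1))
  expect_equal(call_alleles(p4)$covered_positions, 5L)
  expect_equal(nrow(call_alleles(p4)$alleles), 0)
  expect_error(call_alleles(pileup_row(1, "alt", -1, 0)), "non-negative")
})

test_that("table-level calling agrees with the single-profile caller", {
  study <- generate_study(small_config(seed = 3))
  pile <- study$pileup
  called <- call_alleles_table(pile)
  one <- pile[pile$strain_id == pile$strain_id[1] & pile$sample_id == pile$sample_id[1], ]
  prof <- call_alleles(one)
  sub <- called$calls[
    called$calls$strain_id == one$strain_id[1] & called$calls$sample_id == one$sample_id[1],
  ]
  expect_setequal(
    paste(sub$position, sub$allele),
    paste(prof$alleles$position, prof$alleles$allele)
  )
  cov_sub <- called$covered[
    called$covered$strain_id == one$strain_id[1] & called$covered$sample_id == one$sample_id[1],
  ]
  expect_setequal(cov_sub$position, prof$covered_positions)
})

test_that("presence filter keeps breadth >= 0.10 and depth >= 0.15 inclusively", {
  cov <- data.frame(
    strain_id = "S1", sample_id = letters[1:4],
    breadth = c(0.10, 0.09, 0.50, 0.50),
    depth = c(0.15, 5.0, 0.1499, 0.15)
  )
  kept <- presence_filter(cov)
  expect_setequal(kept$sample_id, c("a", "d"))
  expect_equal(attr(kept, "n_kept"), 2)
  expect_equal(attr(kept, "n_dropped"), 2)

  # 10 profiles: 3 fail breadth, 2 others fail depth -> 5 kept
  cov10 <- data.frame(
    strain_id = "S1", sample_id = paste0("s", 1:10),
    breadth = c(0.05, 0.08, 0.09, rep(0.5, 7)),
    depth = c(rep(1, 3), 0.01, 0.1, rep(1, 5))
  )
  expect_equal(nrow(presence_filter(cov10)), 5)
  # idempotence
  once <- presence_filter(cov10)
  expect_equal(presence_filter(once)$sample_id, once$sample_id)
})

test_that("allele incidence uses coverage-aware denominators", {
  screened <- data.frame(strain_id = "S1", sample_id = c("a", "b", "c", "d"))
  covered <- data.frame(
    strain_id = "S1",
    sample_id = c("a", "b", "d", "a", "b", "c", "d"),
    position = c(1L, 1L, 1L, 2L, 2L, 2L, 2L)
  )
  calls <- data.frame(
    strain_id = "S1",
    sample_id = c("a", "b", "a"),
    position = c(1L, 1L, 2L),
    allele = "alt"
  )
  inc <- allele_incidence(calls, covered, screened)
  # position 1: carried by a, b; c does not cover it; absent in d -> 2/3
  expect_equal(inc$f[inc$position == 1], 2 / 3)
  # position 2: carried by a of 4 covering samples
  expect_equal(inc$f[inc$position == 2], 1 / 4)
  expect_true(all(inc$n_screen == 4))

  naive <- allele_incidence(calls, covered, screened, coverage_aware = FALSE)
  expect_equal(naive$f[naive$position == 1], 2 / 4)

  # carried in all covering samples
  all4 <- data.frame(
    strain_id = "S1", sample_id = c("a", "b", "c", "d"), position = 2L, allele = "alt"
  )
  inc4 <- allele_incidence(all4, covered, screened)
  expect_equal(inc4$f[inc4$position == 2], 1)
  # sample order invariance; numerator never decreases when a carrier is added
  inc_rev <- allele_incidence(calls[3:1, ], covered[seq(nrow(covered), 1), ], screened)
  expect_equal(inc_rev$f, inc$f)
  expect_error(allele_incidence(calls, covered, screened[0, ]), "no screening samples")
})

test_that("with zero sequencing error, called alt alleles match planted haplotypes", {
  cfg <- small_config(seed = 9, seq_error_rate = 0, mean_depth = 20)
  study <- generate_study(cfg)
  called <- call_alleles_table(study$pileup)
  alt <- called$calls[called$calls$allele == "alt", ]
  hap <- study$truth$haplotypes
  unit_of <- sub("_t1$", "", alt$sample_id)
  planted <- hap[cbind(alt$position, match(unit_of, colnames(hap[, , 1])),
    match(alt$strain_id, dimnames(hap)[[3]]))]
  expect_true(all(planted == 1L))
})

test_that("corrupt_profile drops alleles at the requested rate", {
  study <- generate_study(small_config(seed = 2))
  one <- study$pileup[
    study$pileup$strain_id == study$pileup$strain_id[1] &
      study$pileup$sample_id == study$pileup$sample_id[1],
  ]
  prof <- call_alleles(one)
  expect_equal(corrupt_profile(prof, 0, seed = 1)$alleles, prof$alleles)
  expect_equal(nrow(corrupt_profile(prof, 1, seed = 1)$alleles), 0)

  big <- data.frame(position = 1:1000, allele = "alt")
  surv <- nrow(corrupt_profile(big, 0.5, seed = 11))
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(surv, bounds[1])
  expect_lte(surv, bounds[2])
  expect_error(corrupt_profile(big, 1.5), "dropout_rate")
})
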