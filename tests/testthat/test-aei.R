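test_that("amplicon reads are classified by exact allele match only", {
  major <- "ACGTACGTGACGTACG"
  minor <- "ACGTACGTAACGTACG"   # differs at position 9
  reads <- c(major, minor, minor,
             sub("^AC", "AA", major),          # non-SNP mismatch
             substr(major, 1, 14))             # 2-nt deletion
  res <- classify_amplicon_reads(reads, major, minor)
  expect_equal(res$major, 1L)
  expect_equal(res$minor, 2L)
  expect_equal(res$discarded, 2L)
  expect_error(classify_amplicon_reads(reads, major, paste0(minor, "A")),
               class = "starr_bad_input")
  expect_error(classify_amplicon_reads(reads, major, major),
               class = "starr_bad_input")
})

test_that("replicate AEI fold and Fisher test behave on canonical tables", {
  tab <- data.frame(sample = "sw1353", replicate = c("r1", "r2", "r3"),
                    dna_major = c(50L, 5L, 11L), dna_minor = c(50L, 5L, 3L),
                    rna_major = c(40L, 5L, 2L), rna_minor = c(60L, 5L, 12L))
  res <- replicate_aei(tab)
  expect_equal(res$fold[1], 1.5)
  expect_equal(res$fold[2], 1.0)
  expect_equal(res$fisher_p[2], 1.0)
  # third row: (12,2,3,11) against the hypergeometric enumeration oracle
  expect_equal(res$fisher_p[3], fisher_enumeration_p(12, 2, 3, 11))
})

test_that("Fisher p matches the enumeration oracle across random tables", {
  set.seed(17)
  for (i in 1:25) {
    counts <- sample(0:50, 4, replace = TRUE)
    if (sum(counts[1:2]) == 0 || sum(counts[3:4]) == 0) next
    tab <- data.frame(dna_major = counts[4], dna_minor = counts[3],
                      rna_major = counts[2], rna_minor = counts[1])
    res <- replicate_aei(tab)
    expect_equal(res$fisher_p,
                 fisher_enumeration_p(counts[1], counts[2],
                                      counts[3], counts[4]),
                 tolerance = 1e-12)
  }
})

test_that("fold is invariant to independent DNA and RNA depth scaling", {
  tab <- data.frame(dna_major = 40L, dna_minor = 30L,
                    rna_major = 20L, rna_minor = 25L)
  scaled <- data.frame(dna_major = 400L, dna_minor = 300L,
                       rna_major = 60L, rna_minor = 75L)
  expect_equal(replicate_aei(tab)$fold, replicate_aei(scaled)$fold)
})

test_that("zero denominators leave the fold undefined but flagged", {
  tab <- data.frame(dna_major = 10L, dna_minor = 0L,
                    rna_major = 10L, rna_minor = 5L)
  res <- replicate_aei(tab)
  expect_true(is.na(res$fold))
  expect_false(is.na(res$fisher_p))
})

test_that("cohort AEI separates shifted fractions at the enumerated exact p", {
  n <- 9L
  tab <- expand.grid(replicate = c("r1", "r2", "r3"),
                     sample = sprintf("p%02d", seq_len(n)),
                     stringsAsFactors = FALSE)
  tab$dna_minor <- 500L; tab$dna_major <- 500L       # fractions all 0.50
  tab$rna_minor <- 550L; tab$rna_major <- 450L       # fractions all 0.55
  res <- cohort_aei(tab)
  expect_equal(res$n_patients, 9L)
  expect_equal(res$mw_p, 2 / choose(18, 9))
  expect_equal(res$median_aei, (0.55 / 0.45) / 1.0)
})

test_that("cohort AEI is null when RNA mirrors DNA", {
  tab <- expand.grid(replicate = c("r1", "r2", "r3"),
                     sample = sprintf("p%02d", 1:4),
                     stringsAsFactors = FALSE)
  set.seed(23)
  minor <- rbinom(nrow(tab), 1000, 0.5)
  tab$dna_minor <- minor; tab$dna_major <- 1000L - minor
  tab$rna_minor <- minor; tab$rna_major <- 1000L - minor
  res <- cohort_aei(tab)
  expect_equal(res$median_aei, 1.0)
  expect_equal(res$mw_p, 1.0)
})

test_that("patients with a missing pool are excluded with a warning", {
  tab <- expand.grid(replicate = c("r1", "r2", "r3"),
                     sample = sprintf("p%02d", 1:3),
                     stringsAsFactors = FALSE)
  tab$dna_minor <- 500L; tab$dna_major <- 500L
  tab$rna_minor <- 520L; tab$rna_major <- 480L
  tab$rna_minor[tab$sample == "p01"] <- 0L
  tab$rna_major[tab$sample == "p01"] <- 0L
  expect_warning(res <- cohort_aei(tab), "p01")
  expect_equal(res$n_patients, 2L)
})

test_that("a reversed patient attenuates the test but not the median much", {
  tab <- expand.grid(replicate = c("r1", "r2", "r3"),
                     sample = sprintf("p%02d", 1:9),
                     stringsAsFactors = FALSE)
  tab$dna_minor <- 500L; tab$dna_major <- 500L
  tab$rna_minor <- 550L; tab$rna_major <- 450L
  rev_sel <- tab$sample == "p09"
  tab$rna_minor[rev_sel] <- 400L; tab$rna_major[rev_sel] <- 600L
  res <- cohort_aei(tab)
  full <- 2 / choose(18, 9)
  expect_gt(res$mw_p, full)
  expect_equal(res$median_aei, (0.55 / 0.45))
})

test_that("simulated AEI cohorts detect a true fold and stay null without one", {
  sim <- simulate_aei(n_patients = 9L, true_fold = 1.5, dna_depth = 10000L,
                      rna_depth = 10000L, seed = 31L)
  per_rep <- replicate_aei(sim)
  expect_true(all(per_rep$fisher_p < 1e-5))
  res <- cohort_aei(sim)
  expect_lt(res$mw_p, 0.01)
  expect_gt(res$median_aei, 1.2)
  null_sim <- simulate_aei(n_patients = 9L, true_fold = 1, dna_depth = 5000L,
                           rna_depth = 5000L, seed = 32L)
  expect_gt(cohort_aei(null_sim)$mw_p, 0.05)
})
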