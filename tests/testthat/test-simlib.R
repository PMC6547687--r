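test_that("identical seeds reproduce the simulation, different seeds differ", {
  a <- simulate_counts(sim_config(n_snps = 20L, seed = 11L))
  b <- simulate_counts(sim_config(n_snps = 20L, seed = 11L))
  c <- simulate_counts(sim_config(n_snps = 20L, seed = 12L))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$counts$barcode, c$counts$barcode))
})

test_that("truth table encodes the configured allelic effect", {
  cfg <- sim_config(n_snps = 50L, frac_differential = 0.2,
                    effect_log2 = 1.32, seed = 5L)
  truth <- simulate_counts(cfg)$truth
  expect_equal(sum(truth$is_differential), 10L)
  shift <- truth$a_minor - truth$a_major
  expect_equal(shift[truth$is_differential], rep(1.32, 10L))
  expect_equal(shift[!truth$is_differential], rep(0, 40L))
})

test_that("complete dropout yields an empty count table, not an error", {
  sim <- simulate_counts(sim_config(n_snps = 5L, dropout_prob = 1, seed = 2L))
  expect_equal(nrow(sim$counts), 0L)
  expect_equal(sim$totals$dna_total, rep(0L, 3L))
})

test_that("null config gives no systematic allele difference", {
  cfg <- sim_config(n_snps = 60L, frac_differential = 0, rna_noise_sd = 0,
                    dna_depth = 5e6, rna_depth = 5e6, dropout_prob = 0,
                    seed = 9L)
  sim <- simulate_counts(cfg)
  meas <- score_measurements(sim$counts, sim$totals)
  act <- aggregate_alleles(meas)
  d <- merge(act[act$allele_tag == "minor", c("snp_id", "mean_score")],
             act[act$allele_tag == "major", c("snp_id", "mean_score")],
             by = "snp_id")
  expect_lt(abs(mean(d$mean_score.x - d$mean_score.y)), 0.05)
})

test_that("error-free reads round-trip through the counting module", {
  scr <- make_toy_screen()
  files <- simulate_reads(scr$sim$counts, scr$lib$designs, scr$config,
                          dir = tempfile())
  tab <- tabulate_replicates(files, scr$lib$inserts)
  ord <- function(x) {
    x <- x[order(x$snp_id, x$allele_tag, x$barcode, x$replicate), ]
    rownames(x) <- NULL
    x
  }
  got <- ord(tab$counts)
  want <- ord(scr$sim$counts)
  want$dna_reads <- as.integer(want$dna_reads)
  want$rna_reads <- as.integer(want$rna_reads)
  expect_equal(got, want)
  expect_equal(tab$totals$dna_total, scr$sim$totals$dna_total)
  expect_equal(tab$totals$rna_total, scr$sim$totals$rna_total)
})

test_that("a single substitution inside the insert voids assignment", {
  scr <- make_toy_screen(n_snps = 2L)
  insert <- scr$lib$designs$insert[1]
  read <- paste0(insert, ADAPTOR_3P, "ACGTA")
  s <- strsplit(read, "")[[1]]
  s[50] <- setdiff(c("A", "C", "G", "T"), s[50])[1]
  mutated <- paste(s, collapse = "")
  asn <- assign_reads(c(read, mutated), scr$lib$inserts)
  expect_equal(asn$reason, c("ok", "no_match"))
  expect_true(is.na(asn$snp_id[2]))
})

test_that("counts consumed by simulate_reads must exist in the designs", {
  scr <- make_toy_screen(n_snps = 2L)
  counts <- scr$sim$counts
  counts$snp_id[1] <- "snp9999"
  expect_error(simulate_reads(counts, scr$lib$designs, scr$config),
               class = "starr_unknown_variant")
})

test_that("peak overlap probability follows the logistic model", {
  n <- 400L
  gr <- GenomicRanges::GRanges("sim",
    IRanges::IRanges(start = (seq_len(n) - 1L) * 1000L + 1L, width = 196L))
  names(gr) <- sprintf("snp%04d", seq_len(n))
  act <- stats::setNames(stats::rnorm(n), names(gr))
  # slope 0, intercept 0: every region overlapped with probability 0.5
  flat <- simulate_peaks(gr, act, slope = 0, intercept = 0, seed = 3L)
  frac <- mean(GenomicRanges::countOverlaps(gr, flat) > 0)
  expect_gt(frac, 0.40)
  expect_lt(frac, 0.60)
  # strongly positive slope: top activity quantile beats bottom
  steep <- simulate_peaks(gr, act, slope = 6, intercept = 0, seed = 3L)
  hit <- GenomicRanges::countOverlaps(gr, steep) > 0
  top <- act >= quantile(act, 0.8)
  bottom <- act <= quantile(act, 0.2)
  expect_gt(mean(hit[top]), mean(hit[bottom]))
  # every emitted peak intersects its source region by >= 1 bp
  expect_true(all(GenomicRanges::countOverlaps(steep, gr) >= 1))
})

test_that("feature simulator validates config and marks skewed columns", {
  expect_error(simulate_features(n_regions = 10, n_features = 5, n_causal = 6),
               class = "starr_bad_config")
  fs <- simulate_features(n_regions = 50, n_features = 20, n_causal = 3,
                          skew_frac = 0.5, seed = 4L)
  expect_equal(dim(fs$X), c(50L, 20L))
  expect_equal(sum(fs$beta != 0), 3L)
  expect_true(all(fs$X[, fs$skewed] > 0))
})

test_that("AEI simulator produces paired replicate counts at depth", {
  tab <- simulate_aei(n_patients = 4L, true_fold = 1.5, dna_depth = 1000L,
                      rna_depth = 1000L, n_replicates = 3L, seed = 8L)
  expect_equal(nrow(tab), 12L)
  expect_equal(unique(tab$dna_major + tab$dna_minor), 1000L)
  expect_equal(unique(tab$rna_major + tab$rna_minor), 1000L)
  # zero depth is representable and flagged downstream, not an error
  empty <- simulate_aei(n_patients = 2L, dna_depth = 0L, seed = 8L)
  expect_true(all(empty$dna_major + empty$dna_minor == 0L))
})
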