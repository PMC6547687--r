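#' Configuration for the synthetic MPRA generator
#'
#' Bundles the parameters of the generative model used to emulate a
#' replicated, barcoded STARR-seq screen. Defaults emulate the regime of a
#' triplicate screen where each allele is represented by a handful of
#' degenerate barcodes and ends up with roughly a dozen usable
#' barcode-replicate measurements.
#'
#' The generative model: each allele receives
#' \eqn{B \sim \mathrm{Pois}(\lambda_{bc})} barcodes (truncated at
#' \eqn{\ge 1}), each surviving a cloning bottleneck with probability
#' \code{1 - dropout_prob}. A surviving barcode has a log-normal DNA
#' abundance \eqn{\lambda_b}. Per replicate, DNA reads are Poisson with
#' mean proportional to \eqn{\lambda_b}; RNA reads are Poisson with mean
#' proportional to \eqn{\lambda_b 2^{a + \epsilon}}, where \eqn{a} is the
#' allele's true log2 activity and \eqn{\epsilon} is barcode-by-replicate
#' Gaussian noise. The log-normal/Poisson mixture yields the overdispersed
#' counts characteristic of MPRA libraries.
#'
#' @param n_snps Number of simulated SNPs.
#' @param frac_differential Fraction of SNPs whose minor allele activity is
#'   shifted by \code{effect_log2}.
#' @param effect_log2 Minor-vs-major activity shift for differential SNPs,
#'   in log2 units (1.32 corresponds to a 2.5-fold expression change).
#' @param activity_sd Spread of baseline (major-allele) activities, log2 units.
#' @param barcodes_per_allele Mean of the truncated Poisson barcode count.
#' @param dna_abundance_logsd sdlog of the log-normal per-barcode DNA
#'   abundance.
#' @param rna_noise_sd sd of the barcode-by-replicate log2 expression noise.
#' @param n_replicates Number of transfection replicates.
#' @param dna_depth,rna_depth Expected total reads per replicate per pool.
#' @param dropout_prob Per-barcode bottleneck loss probability.
#' @param read_error_rate Per-base substitution probability used by
#'   \code{\link{simulate_reads}}.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_snps = 200L,
                       frac_differential = 0.1,
                       effect_log2 = 1.32,
                       activity_sd = 1.0,
                       barcodes_per_allele = 6,
                       dna_abundance_logsd = 1.0,
                       rna_noise_sd = 0.5,
                       n_replicates = 3L,
                       dna_depth = 1e6,
                       rna_depth = 1e6,
                       dropout_prob = 0.3,
                       read_error_rate = 0,
                       seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps),
              frac_differential = frac_differential,
              effect_log2 = effect_log2,
              activity_sd = activity_sd,
              barcodes_per_allele = barcodes_per_allele,
              dna_abundance_logsd = dna_abundance_logsd,
              rna_noise_sd = rna_noise_sd,
              n_replicates = as.integer(n_replicates),
              dna_depth = dna_depth,
              rna_depth = rna_depth,
              dropout_prob = dropout_prob,
              read_error_rate = read_error_rate,
              seed = as.integer(seed))
  probs <- c(frac_differential = frac_differential,
             dropout_prob = dropout_prob,
             read_error_rate = read_error_rate)
  if (any(probs < 0 | probs > 1))
    stop_starr("starr_bad_config", "probabilities must lie in [0, 1]")
  if (cfg$dna_depth < 0 || cfg$rna_depth < 0)
    stop_starr("starr_bad_config", "depths must be >= 0")
  if (cfg$n_replicates < 1)
    stop_starr("starr_bad_config", "n_replicates must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# Poisson truncated at >= 1, via inverse CDF
rpois_pos <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
}

rand_barcodes <- function(n, width = 5L) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = width)
  apply(m, 2, paste, collapse = "")
}

#' Simulate a barcode-level MPRA count table
#'
#' Draws barcode-level DNA and RNA read counts for every allele of every
#' simulated SNP across replicates, under the model described in
#' \code{\link{sim_config}}, together with the ground-truth activities.
#'
#' Differential SNPs are the first \code{round(frac_differential * n_snps)}
#' in the table; their minor allele activity is
#' \code{a_major + effect_log2}. Barcode collisions within an allele (the
#' degenerate 5-mer space is finite) merge into a single molecule class.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with
#'   \describe{
#'     \item{counts}{data.frame snp_id, allele_tag, barcode, replicate,
#'       dna_reads, rna_reads - rows with at least one read in either pool.}
#'     \item{truth}{data.frame snp_id, a_major, a_minor, is_differential.}
#'     \item{totals}{data.frame replicate, dna_total, rna_total (sums of
#'       emitted reads; the normalizers downstream).}
#'   }
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_snps
  snp_id <- sprintf("snp%04d", seq_len(n))
  n_diff <- round(config$frac_differential * n)
  is_diff <- seq_len(n) <= n_diff
  a_major <- stats::rnorm(n, 0, config$activity_sd)
  a_minor <- a_major + ifelse(is_diff, config$effect_log2, 0)
  truth <- data.frame(snp_id = snp_id, a_major = a_major, a_minor = a_minor,
                      is_differential = is_diff, stringsAsFactors = FALSE)

  # per-allele barcode draws
  alleles <- data.frame(
    snp_id = rep(snp_id, each = 2L),
    allele_tag = rep(c("major", "minor"), n),
    activity = as.vector(rbind(a_major, a_minor)),
    stringsAsFactors = FALSE)
  n_bc <- rpois_pos(nrow(alleles), config$barcodes_per_allele)
  keep <- stats::rbinom(sum(n_bc), 1L, 1 - config$dropout_prob) == 1L
  idx <- rep(seq_len(nrow(alleles)), n_bc)[keep]
  if (length(idx) == 0) {
    empty <- data.frame(snp_id = character(0), allele_tag = character(0),
                        barcode = character(0), replicate = character(0),
                        dna_reads = integer(0), rna_reads = integer(0),
                        stringsAsFactors = FALSE)
    totals <- data.frame(replicate = sprintf("rep%d", seq_len(config$n_replicates)),
                         dna_total = 0L, rna_total = 0L)
    return(list(counts = empty, truth = truth, totals = totals))
  }
  bc <- data.frame(
    snp_id = alleles$snp_id[idx],
    allele_tag = alleles$allele_tag[idx],
    activity = alleles$activity[idx],
    barcode = rand_barcodes(length(idx)),
    lambda = stats::rlnorm(length(idx), 0, config$dna_abundance_logsd),
    stringsAsFactors = FALSE)
  # merge barcode collisions within an allele into one molecule class
  key <- paste(bc$snp_id, bc$allele_tag, bc$barcode, sep = "\r")
  if (anyDuplicated(key)) {
    lam <- tapply(bc$lambda, key, sum)
    bc <- bc[!duplicated(key), ]
    bc$lambda <- as.numeric(lam[paste(bc$snp_id, bc$allele_tag, bc$barcode,
                                      sep = "\r")])
  }

  reps <- sprintf("rep%d", seq_len(config$n_replicates))
  out <- vector("list", length(reps))
  totals <- data.frame(replicate = reps, dna_total = 0, rna_total = 0)
  for (r in seq_along(reps)) {
    dna_mu <- bc$lambda / sum(bc$lambda) * config$dna_depth
    eps <- stats::rnorm(nrow(bc), 0, config$rna_noise_sd)
    w <- bc$lambda * 2^(bc$activity + eps)
    rna_mu <- w / sum(w) * config$rna_depth
    dna <- stats::rpois(nrow(bc), dna_mu)
    rna <- stats::rpois(nrow(bc), rna_mu)
    sel <- dna + rna >= 1L
    out[[r]] <- data.frame(
      snp_id = bc$snp_id[sel], allele_tag = bc$allele_tag[sel],
      barcode = bc$barcode[sel], replicate = reps[r],
      dna_reads = dna[sel], rna_reads = rna[sel],
      stringsAsFactors = FALSE)
    totals$dna_total[r] <- sum(dna)
    totals$rna_total[r] <- sum(rna)
  }
  counts <- do.call(rbind, out)
  rownames(counts) <- NULL
  list(counts = counts, truth = truth, totals = totals)
}

mutate_reads <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  width <- nchar(reads[1])
  n_err <- stats::rbinom(length(reads), width, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(width, n_err[i])
    s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Simulate raw amplicon reads from a count table
#'
#' Emits one read per counted molecule with the library's amplicon layout:
#' 196-nt insert, then the 17-nt 3' adaptor, then the 5-nt barcode
#' (218 nt total). Per-base substitution errors are applied at
#' \code{config$read_error_rate}; base qualities are constant.
#'
#' @param counts A count table as from \code{\link{simulate_counts}}.
#' @param designs The design table from \code{\link{build_library}}.
#' @param config A \code{\link{sim_config}} (supplies error rate and seed).
#' @param dir Output directory for the FASTQ files.
#' @return data.frame with one row per replicate: replicate, dna_fastq,
#'   rna_fastq (paths to the written files).
#' @export
simulate_reads <- function(counts, designs, config, dir = tempdir()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  key <- paste(designs$snp_id, designs$allele_tag, sep = "_")
  ins <- stats::setNames(designs$insert, key)
  ck <- paste(counts$snp_id, counts$allele_tag, sep = "_")
  unknown <- setdiff(unique(ck), key)
  if (length(unknown) > 0)
    stop_starr("starr_unknown_variant",
               paste("counted variants absent from designs:",
                     paste(utils::head(unknown, 5), collapse = ", ")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reps <- unique(counts$replicate)
  files <- data.frame(replicate = reps, dna_fastq = NA_character_,
                      rna_fastq = NA_character_, stringsAsFactors = FALSE)
  for (r in seq_along(reps)) {
    sub <- counts[counts$replicate == reps[r], ]
    template <- paste0(ins[paste(sub$snp_id, sub$allele_tag, sep = "_")],
                       ADAPTOR_3P, sub$barcode)
    for (pool in c("dna", "rna")) {
      nrd <- sub[[paste0(pool, "_reads")]]
      reads <- mutate_reads(rep(template, nrd), config$read_error_rate)
      path <- file.path(dir, sprintf("%s_%s.fastq", reps[r], pool))
      write_fastq(reads, path, prefix = sprintf("%s_%s", reps[r], pool))
      files[[paste0(pool, "_fastq")]][r] <- path
    }
  }
  files
}

write_fastq <- function(reads, path, prefix = "read") {
  reads <- unname(as.character(reads))
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- sprintf("%s_%06d", prefix, seq_along(reads))
  qual <- Biostrings::BStringSet(vapply(
    nchar(reads), function(w) strrep("I", w), character(1)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Simulate an activity-linked peak set
#'
#' Generates a BED-style peak set where the probability that a region is
#' overlapped by a peak follows a logistic function of its true activity:
#' \code{plogis(intercept + slope * activity)}. Selected regions get a peak
#' guaranteed to intersect them by at least 1 bp.
#'
#' @param regions A \link[GenomicRanges]{GRanges} of tested regions, named
#'   by snp_id (see \code{\link{design_ranges}}).
#' @param activities Named numeric vector of activities (names = snp_id).
#' @param slope,intercept Logistic overlap model parameters.
#' @param seed Integer seed.
#' @param peak_width Width of emitted peaks.
#' @return A \link[GenomicRanges]{GRanges} of peaks.
#' @export
simulate_peaks <- function(regions, activities, slope = 1, intercept = 0,
                           seed = 1L, peak_width = 400L) {
  if (!all(names(regions) %in% names(activities)))
    stop_starr("starr_bad_input", "activities missing for some regions")
  set.seed(seed)
  act <- activities[names(regions)]
  p <- stats::plogis(intercept + slope * act)
  hit <- stats::runif(length(p)) < p
  if (!any(hit)) {
    return(GenomicRanges::GRanges())
  }
  sel <- regions[hit]
  mid <- (GenomicRanges::start(sel) + GenomicRanges::end(sel)) %/% 2L
  # random offset keeps >= 1 bp intersection with the source region
  off <- sample(-(peak_width %/% 2):(peak_width %/% 2), length(sel),
                replace = TRUE)
  start <- pmax(1L, mid + off - peak_width %/% 2L)
  GenomicRanges::GRanges(GenomicRanges::seqnames(sel),
                         IRanges::IRanges(start, width = peak_width))
}

#' Simulate a sparse-signal feature matrix
#'
#' Generates latent standard-normal features, a sparse coefficient vector,
#' and activities \code{y = L beta + noise}. A configurable fraction of the
#' feature columns is emitted exponentiated (right-skewed, as ChIP-seq or
#' CAGE signal would be) to exercise the log-transform path of
#' \code{\link{preprocess_features}}; the response is generated on the
#' latent (log) scale.
#'
#' @param n_regions,n_features Matrix dimensions.
#' @param n_causal Number of nonzero coefficients.
#' @param noise_sd sd of additive Gaussian noise on y.
#' @param skew_frac Fraction of feature columns emitted as exp(latent).
#' @param beta_range Magnitude range of nonzero coefficients (signs random).
#' @param seed Integer seed.
#' @return list(X, y, beta, skewed): feature matrix (regions x features,
#'   named), activities, true coefficients, logical skew flags per feature.
#' @export
simulate_features <- function(n_regions = 500L, n_features = 100L,
                              n_causal = 5L, noise_sd = 1,
                              skew_frac = 0.3, beta_range = c(0.5, 1.5),
                              seed = 1L) {
  if (n_causal > n_features)
    stop_starr("starr_bad_config", "n_causal must not exceed n_features")
  set.seed(seed)
  L <- matrix(stats::rnorm(n_regions * n_features), n_regions, n_features,
              dimnames = list(sprintf("region%04d", seq_len(n_regions)),
                              sprintf("feature%03d", seq_len(n_features))))
  beta <- numeric(n_features)
  causal <- sample.int(n_features, n_causal)
  beta[causal] <- sample(c(-1, 1), n_causal, replace = TRUE) *
    stats::runif(n_causal, beta_range[1], beta_range[2])
  y <- as.numeric(L %*% beta + stats::rnorm(n_regions, 0, noise_sd))
  skewed <- stats::runif(n_features) < skew_frac
  X <- L
  X[, skewed] <- exp(L[, skewed])
  names(beta) <- colnames(X)
  names(skewed) <- colnames(X)
  list(X = X, y = y, beta = beta, skewed = skewed)
}

#' Simulate paired DNA/cDNA allele counts for an AEI cohort
#'
#' Per heterozygous patient, the genomic DNA minor-allele fraction is drawn
#' from a Beta distribution centered at 0.5 (spread controlled by
#' \code{overdispersion}); the RNA minor-allele odds equal the DNA odds
#' times \code{true_fold}. Each technical replicate draws binomial counts
#' at the stated depths.
#'
#' @param n_patients Number of heterozygous patients.
#' @param true_fold True allelic expression imbalance (RNA/DNA odds ratio).
#' @param dna_depth,rna_depth Reads per replicate per pool.
#' @param overdispersion Beta concentration (both shape parameters); larger
#'   means DNA fractions closer to exactly 0.5.
#' @param n_replicates Technical replicates per patient.
#' @param seed Integer seed.
#' @return data.frame sample, replicate, dna_major, dna_minor, rna_major,
#'   rna_minor.
#' @export
simulate_aei <- function(n_patients = 9L, true_fold = 1.5,
                         dna_depth = 5000L, rna_depth = 5000L,
                         overdispersion = 200, n_replicates = 3L,
                         seed = 1L) {
  set.seed(seed)
  f_dna <- stats::rbeta(n_patients, overdispersion, overdispersion)
  odds_rna <- f_dna / (1 - f_dna) * true_fold
  f_rna <- odds_rna / (1 + odds_rna)
  grid <- expand.grid(replicate = sprintf("rep%d", seq_len(n_replicates)),
                      sample = sprintf("patient%02d", seq_len(n_patients)),
                      stringsAsFactors = FALSE)[, c("sample", "replicate")]
  i <- match(grid$sample, sprintf("patient%02d", seq_len(n_patients)))
  dna_minor <- stats::rbinom(nrow(grid), dna_depth, f_dna[i])
  rna_minor <- stats::rbinom(nrow(grid), rna_depth, f_rna[i])
  data.frame(grid,
             dna_major = dna_depth - dna_minor, dna_minor = dna_minor,
             rna_major = rna_depth - rna_minor, rna_minor = rna_minor,
             stringsAsFactors = FALSE)
}
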