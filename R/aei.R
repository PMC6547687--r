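#' Classify amplicon reads by allele
#'
#' Counts reads that exactly equal the expected major-allele or
#' minor-allele amplicon over the evaluated window. Reads of a different
#' length (implying an indel) or with any mismatch to both amplicons are
#' discarded - the indel-free / error-free rule for allele-specific
#' quantification.
#'
#' @param reads Character vector of read sequences (or DNAStringSet).
#' @param major_amplicon,minor_amplicon Expected amplicon sequences; must
#'   be the same length and differ only at the variant base.
#' @return list(major, minor, discarded): read counts per class.
#' @export
classify_amplicon_reads <- function(reads, major_amplicon, minor_amplicon) {
  if (nchar(major_amplicon) != nchar(minor_amplicon))
    stop_starr("starr_bad_input", "expected amplicons differ in length")
  diff_at <- which(strsplit(major_amplicon, "")[[1]] !=
                   strsplit(minor_amplicon, "")[[1]])
  if (length(diff_at) != 1)
    stop_starr("starr_bad_input",
               "expected amplicons must differ at exactly one base")
  reads <- as.character(reads)
  w <- nchar(major_amplicon)
  window <- substr(reads, 1L, w)
  is_major <- nchar(reads) == w & window == major_amplicon
  is_minor <- nchar(reads) == w & window == minor_amplicon
  list(major = sum(is_major), minor = sum(is_minor),
       discarded = sum(!is_major & !is_minor))
}

#' Per-replicate allelic expression imbalance
#'
#' For each row of paired DNA/cDNA allele counts, computes the AEI fold
#' \deqn{(rna_{minor}/rna_{major}) / (dna_{minor}/dna_{major})}
#' (the RNA allele ratio normalized by the DNA allele ratio) and a
#' two-sided Fisher's exact test of allele vs pool.
#'
#' @param counts data.frame with columns dna_major, dna_minor, rna_major,
#'   rna_minor (and any identifier columns, carried through).
#' @return The input with added columns fold (NA when a denominator count
#'   is zero) and fisher_p.
#' @export
replicate_aei <- function(counts) {
  need <- c("dna_major", "dna_minor", "rna_major", "rna_minor")
  if (!all(need %in% names(counts)))
    stop_starr("starr_bad_input",
               paste("counts need columns:", paste(need, collapse = ", ")))
  out <- counts
  out$fold <- NA_real_
  out$fisher_p <- NA_real_
  for (i in seq_len(nrow(out))) {
    dM <- out$dna_major[i]; dm <- out$dna_minor[i]
    rM <- out$rna_major[i]; rm_ <- out$rna_minor[i]
    if (dM + dm < 1 || rM + rm_ < 1) next
    if (dM > 0 && dm >= 0 && rM > 0)
      out$fold[i] <- (rm_ / rM) / (dm / dM)
    if (dm == 0 || dM == 0) out$fold[i] <- NA_real_
    tab <- matrix(c(rm_, rM, dm, dM), nrow = 2)
    out$fisher_p[i] <- stats::fisher.test(tab)$p.value
  }
  out
}

#' Cohort-level allelic expression imbalance
#'
#' Per patient, averages the minor-allele fraction over technical
#' replicates separately in DNA and RNA, then compares the per-patient DNA
#' fractions against the per-patient RNA fractions with a two-sided
#' Mann-Whitney U test (exact for cohorts of up to \code{exact_max} per
#' group). The cohort median AEI is the median over patients of the
#' odds-ratio fold computed from the averaged fractions.
#'
#' @param counts data.frame with columns sample, replicate, dna_major,
#'   dna_minor, rna_major, rna_minor.
#' @param exact_max Largest per-group size using the exact U distribution
#'   (default 9, covering a nine-patient cohort).
#' @return list(per_patient, median_aei, mw_p, n_patients) where
#'   per_patient has sample, dna_fraction, rna_fraction, fold.
#' @export
cohort_aei <- function(counts, exact_max = 9L) {
  frac <- function(minor, major) minor / (minor + major)
  counts$dna_frac <- frac(counts$dna_minor, counts$dna_major)
  counts$rna_frac <- frac(counts$rna_minor, counts$rna_major)
  complete <- stats::complete.cases(counts$dna_frac, counts$rna_frac)
  dropped <- unique(counts$sample[!complete])
  keep_samples <- setdiff(unique(counts$sample), dropped)
  if (length(dropped) > 0)
    warning("excluding samples with missing pools: ",
            paste(dropped, collapse = ", "))
  if (length(keep_samples) < 2)
    stop_starr("starr_bad_input", "need >= 2 patients with complete counts")
  sub <- counts[counts$sample %in% keep_samples, ]
  dna <- tapply(sub$dna_frac, sub$sample, mean)
  rna <- tapply(sub$rna_frac, sub$sample, mean)
  odds <- function(f) f / (1 - f)
  fold <- odds(rna) / odds(dna)
  per_patient <- data.frame(sample = names(dna),
                            dna_fraction = as.numeric(dna),
                            rna_fraction = as.numeric(rna),
                            fold = as.numeric(fold),
                            stringsAsFactors = FALSE)
  mw <- mann_whitney_u(per_patient$rna_fraction, per_patient$dna_fraction,
                       exact_max = exact_max)
  list(per_patient = per_patient,
       median_aei = stats::median(per_patient$fold),
       mw_p = mw$p,
       n_patients = nrow(per_patient))
}
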