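#' Mann-Whitney U test between two score sets
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. When both groups are at
#' most \code{exact_max}, the exact null distribution is used: the standard
#' exact distribution when the pooled values are free of ties, or a full
#' enumeration of group labelings on mid-ranks when ties are present (the
#' permutation distribution of U, symmetric-tail two-sided p). For larger
#' groups the normal approximation with tie and continuity corrections is
#' applied. Small-sample exactness keeps fixture p-values deterministic.
#'
#' @param x,y Numeric score vectors (e.g. the two alleles' measurements).
#' @param exact_max Largest group size for which the exact distribution is
#'   used (default 8).
#' @return list(u, p): the U statistic of \code{x} relative to \code{y} and
#'   the two-sided p-value.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (length(x) == 0 || length(y) == 0)
    stop_starr("starr_bad_input", "both groups must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  small <- n1 <= exact_max && n2 <= exact_max
  if (small && !ties) {
    p <- stats::wilcox.test(x, y, alternative = "two.sided",
                            exact = TRUE)$p.value
  } else if (small && ties) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = FALSE, correct = TRUE))$p.value
  }
  list(u = u, p = p)
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up BH false-discovery-rate correction; flags hypotheses with
#' adjusted p at or below \code{fdr}.
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @param fdr FDR threshold (default 0.10).
#' @return list(q, significant).
#' @export
adjust_bh <- function(p, fdr = 0.10) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop_starr("starr_bad_input", "p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q <= fdr)
}

#' Differential allelic activity table
#'
#' For every SNP with both alleles passing the activity filters, tests the
#' pooled major-allele measurements against the pooled minor-allele
#' measurements (two-sided Mann-Whitney), applies BH correction across all
#' tested SNPs, and reports the minor/major fold change
#' \code{2^(mean_minor - mean_major)}.
#'
#' @param activities Per-allele table from \code{\link{aggregate_alleles}}.
#' @param measurements Measurement table from
#'   \code{\link{score_measurements}}.
#' @param fdr FDR threshold for the significance flag (default 0.10).
#' @param exact_max Passed to \code{\link{mann_whitney_u}}.
#' @return data.frame sorted by adjusted p: snp_id, mean_major, mean_minor,
#'   fold_change, n_major, n_minor, u_statistic, p_raw, q_bh, significant.
#'   Attribute \code{summary}: list(n_tested, n_significant,
#'   allele_spearman) where allele_spearman is the Spearman correlation of
#'   mean major vs minor activity across tested SNPs.
#' @export
differential_table <- function(activities, measurements, fdr = 0.10,
                               exact_max = 8L) {
  has_major <- activities$snp_id[activities$allele_tag == "major"]
  has_minor <- activities$snp_id[activities$allele_tag == "minor"]
  tested <- sort(intersect(has_major, has_minor))
  act_key <- paste(activities$snp_id, activities$allele_tag, sep = "_")
  mean_of <- function(ids, tag)
    activities$mean_score[match(paste(ids, tag, sep = "_"), act_key)]
  n_of <- function(ids, tag)
    activities$n_measurements[match(paste(ids, tag, sep = "_"), act_key)]

  sub <- measurements[measurements$snp_id %in% tested, ]
  split_scores <- split(sub$score, paste(sub$snp_id, sub$allele_tag, sep = "_"))
  res <- data.frame(snp_id = tested,
                    mean_major = mean_of(tested, "major"),
                    mean_minor = mean_of(tested, "minor"),
                    n_major = n_of(tested, "major"),
                    n_minor = n_of(tested, "minor"),
                    stringsAsFactors = FALSE)
  res$fold_change <- 2^(res$mean_minor - res$mean_major)
  tests <- lapply(tested, function(id) {
    mann_whitney_u(split_scores[[paste0(id, "_minor")]],
                   split_scores[[paste0(id, "_major")]],
                   exact_max = exact_max)
  })
  res$u_statistic <- vapply(tests, `[[`, 0, "u")
  res$p_raw <- vapply(tests, `[[`, 0, "p")
  adj <- adjust_bh(res$p_raw, fdr = fdr)
  res$q_bh <- adj$q
  res$significant <- adj$significant
  res <- res[order(res$q_bh, res$p_raw, res$snp_id),
             c("snp_id", "mean_major", "mean_minor", "fold_change",
               "n_major", "n_minor", "u_statistic", "p_raw", "q_bh",
               "significant")]
  rownames(res) <- NULL
  attr(res, "summary") <- list(
    n_tested = length(tested),
    n_significant = sum(res$significant),
    allele_spearman = if (length(tested) >= 3)
      stats::cor(res$mean_major, res$mean_minor, method = "spearman")
    else NA_real_)
  res
}
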