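#' Per-barcode activity scores
#'
#' For every (variant, allele, barcode, replicate) molecule class with at
#' least \code{min_dna} DNA reads and at least \code{min_rna} RNA reads,
#' computes the activity score
#' \deqn{\log_2\frac{rna / rna_{total}}{dna / dna_{total}}}
#' where the totals are the per-replicate, per-pool totals of counted
#' (error-free) reads. Classes failing either depth filter emit no
#' measurement.
#'
#' @param counts Barcode count table (snp_id, allele_tag, barcode,
#'   replicate, dna_reads, rna_reads).
#' @param totals data.frame replicate, dna_total, rna_total. If \code{NULL},
#'   totals are computed by summing \code{counts} per replicate - identical
#'   to the assigned-read totals when the table is unfiltered.
#' @param min_dna,min_rna Depth filters (defaults 10 DNA reads, 1 RNA read).
#' @return data.frame snp_id, allele_tag, barcode, replicate, dna_reads,
#'   rna_reads, score.
#' @export
score_measurements <- function(counts, totals = NULL,
                               min_dna = 10L, min_rna = 1L) {
  if (is.null(totals)) {
    agg <- stats::aggregate(cbind(dna_total = dna_reads,
                                  rna_total = rna_reads) ~ replicate,
                            data = counts, FUN = sum)
    totals <- agg
  }
  i <- match(counts$replicate, totals$replicate)
  if (anyNA(i))
    stop_starr("starr_missing_totals",
               paste("no totals for replicate(s):",
                     paste(unique(counts$replicate[is.na(i)]), collapse = ", ")))
  dt <- totals$dna_total[i]
  rt <- totals$rna_total[i]
  if (any(dt <= 0 | rt <= 0))
    stop_starr("starr_missing_totals", "pool totals must be positive")
  keep <- counts$dna_reads >= min_dna & counts$rna_reads >= min_rna
  out <- counts[keep, , drop = FALSE]
  out$score <- log2((out$rna_reads / rt[keep]) / (out$dna_reads / dt[keep]))
  rownames(out) <- NULL
  out
}

#' Aggregate measurements into per-allele activities
#'
#' Pools all barcode-replicate measurements of each allele and, for alleles
#' with at least \code{min_measurements} of them, reports the arithmetic
#' mean score. The same barcode seen in two replicates counts as two
#' measurements. Alleles failing the filter are recorded in the
#' \code{"dropped"} attribute of the result.
#'
#' @param measurements Output of \code{\link{score_measurements}}.
#' @param min_measurements Minimum pooled measurements per allele (default 3).
#' @return data.frame snp_id, allele_tag, n_measurements, mean_score, with
#'   attribute \code{dropped}: the same summary for excluded alleles.
#' @export
aggregate_alleles <- function(measurements, min_measurements = 3L) {
  if (nrow(measurements) == 0) {
    out <- data.frame(snp_id = character(0), allele_tag = character(0),
                      n_measurements = integer(0), mean_score = numeric(0))
    attr(out, "dropped") <- out
    return(out)
  }
  key <- interaction(measurements$snp_id, measurements$allele_tag, drop = TRUE)
  n <- as.integer(table(key))
  mean_score <- as.numeric(tapply(measurements$score, key, mean))
  first <- !duplicated(key)
  res <- data.frame(snp_id = measurements$snp_id[first],
                    allele_tag = measurements$allele_tag[first],
                    stringsAsFactors = FALSE)
  ord <- match(levels(key), key[first])
  res <- res[ord, ]
  res$n_measurements <- n
  res$mean_score <- mean_score
  res <- res[order(res$snp_id, res$allele_tag), ]
  rownames(res) <- NULL
  pass <- res$n_measurements >= min_measurements
  out <- res[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- res[!pass, , drop = FALSE]
  out
}

#' Between-replicate concordance of allele activities
#'
#' Computes per-replicate mean allele scores and, for every replicate pair,
#' the Pearson and Spearman correlations over alleles scored in both.
#'
#' @param measurements Output of \code{\link{score_measurements}}.
#' @param min_shared Minimum shared alleles for a defined correlation.
#' @return data.frame rep_a, rep_b, n_shared, pearson, spearman (NA for
#'   pairs with fewer than \code{min_shared} shared alleles).
#' @export
replicate_concordance <- function(measurements, min_shared = 3L) {
  reps <- sort(unique(measurements$replicate))
  if (length(reps) < 2)
    stop_starr("starr_bad_input", "need at least two replicates")
  allele <- paste(measurements$snp_id, measurements$allele_tag, sep = "_")
  per_rep <- tapply(measurements$score,
                    list(allele, measurements$replicate), mean)
  pairs <- utils::combn(reps, 2)
  out <- data.frame(rep_a = pairs[1, ], rep_b = pairs[2, ],
                    n_shared = NA_integer_, pearson = NA_real_,
                    spearman = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- per_rep[, pairs[1, k]]
    b <- per_rep[, pairs[2, k]]
    ok <- stats::complete.cases(a, b)
    out$n_shared[k] <- sum(ok)
    if (sum(ok) >= min_shared) {
      out$pearson[k] <- stats::cor(a[ok], b[ok])
      out$spearman[k] <- stats::cor(a[ok], b[ok], method = "spearman")
    }
  }
  out
}
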