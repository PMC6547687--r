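#' Rank regions into activity quintiles
#'
#' Sorts regions by descending mean score (ties broken by snp_id,
#' lexicographic) and partitions them into five near-equal quintiles.
#' Quintile 5 is the highest-scoring. When n is not divisible by 5, the
#' remainder goes to the highest quintiles, so with n = 1254 the split is
#' 251/251/251/251/250 from top to bottom.
#'
#' @param regions data.frame with at least snp_id and mean_score; any
#'   interval columns (chrom, start0, end0) are carried through.
#' @return The input rows reordered by rank with an added integer
#'   \code{quintile} column (1 = lowest scoring, 5 = highest).
#' @export
assign_quintiles <- function(regions) {
  n <- nrow(regions)
  if (n < 5)
    stop_starr("starr_bad_input", "need at least 5 regions for quintiles")
  ord <- order(-regions$mean_score, regions$snp_id)
  out <- regions[ord, , drop = FALSE]
  base <- n %/% 5L
  rem <- n %% 5L
  sizes <- rep(base, 5L) + c(rep(1L, rem), rep(0L, 5L - rem))  # Q5 first
  out$quintile <- rep(5L:1L, times = sizes)
  rownames(out) <- NULL
  out
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$start0 + 1L,
                                          end = regions$end0))
}

load_peaks <- function(peaks) {
  if (is.character(peaks)) {
    peaks <- tryCatch(rtracklayer::import(peaks, format = "BED"),
                      error = function(e)
                        stop_starr("starr_bed_parse",
                                   paste("failed to parse BED:",
                                         conditionMessage(e))))
  }
  if (!methods::is(peaks, "GRanges"))
    stop_starr("starr_bad_input", "peaks must be a GRanges or BED path")
  peaks
}

#' Flag regions overlapping peak sets
#'
#' A region is flagged for a dataset when it intersects any peak by at
#' least 1 bp (half-open interval arithmetic on the 0-based coordinates).
#' An \code{any_dataset} union flag is added.
#'
#' @param regions data.frame with chrom, start0, end0 (0-based half-open).
#' @param peak_sets Named list of peak sets, each a
#'   \link[GenomicRanges]{GRanges} or a BED file path.
#' @return data.frame of logical flags, one column per dataset plus
#'   \code{any_dataset}, rows aligned with \code{regions}.
#' @export
overlap_flags <- function(regions, peak_sets) {
  if (is.null(names(peak_sets)) || any(names(peak_sets) == ""))
    stop_starr("starr_bad_input", "peak_sets must be a named list")
  if (any(regions$end0 <= regions$start0))
    stop_starr("starr_bad_input", "regions must satisfy start < end")
  gr <- regions_to_granges(regions)
  flags <- as.data.frame(lapply(peak_sets, function(p) {
    pk <- load_peaks(p)  # force here: S4 dispatch would mask the error class
    GenomicRanges::countOverlaps(gr, pk, minoverlap = 1L) > 0
  }))
  flags$any_dataset <- Reduce(`|`, flags)
  flags
}

chisq_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(tab == tab[1, 1]) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    # degenerate margins; chisq.test errors, define the null result
    return(list(chi2 = 0, p = 1, unreliable = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value,
       unreliable = any(expected < 1))
}

enrichment_row <- function(dataset, a, b, c, d, n_datasets = 1L) {
  ch <- chisq_2x2(a, b, c, d)
  rate1 <- a / (a + b)
  rate2 <- c / (c + d)
  data.frame(dataset = dataset, a = a, b = b, c = c, d = d,
             fold = rate1 / rate2, chi2 = ch$chi2, p_raw = ch$p,
             p_bonferroni = min(1, ch$p * n_datasets),
             unreliable = ch$unreliable, stringsAsFactors = FALSE)
}

#' Top-quintile vs rest enrichment per peak dataset
#'
#' For each dataset, builds the 2x2 contingency (top quintile
#' overlap/no-overlap vs all other ranked regions overlap/no-overlap),
#' computes the overlap-rate fold, the Pearson chi-square without
#' continuity correction, and a Bonferroni correction across the datasets
#' in this invocation.
#'
#' @param flags Flag table from \code{\link{overlap_flags}}.
#' @param quintiles Integer quintile vector aligned with \code{flags} rows
#'   (or the data.frame from \code{\link{assign_quintiles}}).
#' @param datasets Which flag columns to test (default: all but the union).
#' @return data.frame with one row per dataset: dataset, a, b, c, d, fold,
#'   chi2, p_raw, p_bonferroni, unreliable (TRUE when any expected
#'   cell < 1).
#' @export
quintile_vs_rest <- function(flags, quintiles,
                             datasets = setdiff(names(flags), "any_dataset")) {
  if (is.data.frame(quintiles)) quintiles <- quintiles$quintile
  top <- quintiles == 5L
  rows <- lapply(datasets, function(ds) {
    f <- flags[[ds]]
    enrichment_row(ds,
                   a = sum(f[top]), b = sum(!f[top]),
                   c = sum(f[!top]), d = sum(!f[!top]),
                   n_datasets = length(datasets))
  })
  do.call(rbind, rows)
}

#' Top-vs-bottom quintile enrichment
#'
#' Headline comparison: overlap with any dataset in the highest-scoring
#' quintile vs the lowest-scoring quintile (single comparison, no
#' Bonferroni).
#'
#' @inheritParams quintile_vs_rest
#' @param dataset Flag column to use (default the union flag).
#' @return One-row data.frame as in \code{\link{quintile_vs_rest}}.
#' @export
top_vs_bottom <- function(flags, quintiles, dataset = "any_dataset") {
  if (is.data.frame(quintiles)) quintiles <- quintiles$quintile
  f <- flags[[dataset]]
  top <- quintiles == 5L
  bot <- quintiles == 1L
  enrichment_row(dataset,
                 a = sum(f[top]), b = sum(!f[top]),
                 c = sum(f[bot]), d = sum(!f[bot]),
                 n_datasets = 1L)
}

#' Enrichment from a printed contingency table
#'
#' Convenience wrapper computing fold and uncorrected Pearson chi-square
#' directly from four contingency counts (group 1 overlap / no-overlap,
#' group 2 overlap / no-overlap).
#'
#' @param a,b,c,d Non-negative contingency counts.
#' @param dataset Label for the output row.
#' @return One-row data.frame as in \code{\link{quintile_vs_rest}}.
#' @export
contingency_enrichment <- function(a, b, c, d, dataset = "contingency") {
  if (any(c(a, b, c, d) < 0))
    stop_starr("starr_bad_input", "contingency counts must be non-negative")
  enrichment_row(dataset, a, b, c, d, n_datasets = 1L)
}
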