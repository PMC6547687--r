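#' Run the simulate-score-test-enrich demo pipeline
#'
#' End-to-end orchestration over simulated data: generate a barcode count
#' table, score measurements, aggregate alleles, call differential SNPs,
#' and (optionally) simulate an activity-linked peak set and compute
#' quintile enrichment. Each stage writes its TSV/JSON artifacts into
#' \code{out_dir}; a manifest records seeds, row counts and md5 checksums,
#' so a re-run with the same config reproduces identical non-log outputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A \code{\link{sim_config}}.
#' @param stages Ordered subset of
#'   \code{c("simulate", "score", "test", "enrich")}. Later stages require
#'   the earlier ones in the same call.
#' @param fdr FDR threshold for differential calls.
#' @param peak_slope,peak_intercept Logistic overlap model for the
#'   simulated peak set used by the enrich stage.
#' @return Invisibly, the manifest list (also written as manifest.json).
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         stages = c("simulate", "score", "test", "enrich"),
                         fdr = 0.10, peak_slope = 2, peak_intercept = -1) {
  all_stages <- c("simulate", "score", "test", "enrich")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(stage, dep) {
    if (stage %in% stages && !dep %in% stages)
      stop_starr("starr_stage_dependency",
                 sprintf("stage '%s' requires stage '%s'", stage, dep))
  }
  need("score", "simulate"); need("test", "score"); need("enrich", "test")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  manifest <- list(seed = config$seed, config = unclass(config),
                   stages = stages, outputs = list())

  sim <- meas <- act <- diff <- NULL
  if ("simulate" %in% stages) {
    sim <- simulate_counts(config)
    files["counts"] <- file.path(out_dir, "counts.tsv")
    files["truth"] <- file.path(out_dir, "truth.tsv")
    files["totals"] <- file.path(out_dir, "totals.tsv")
    write_tsv(sim$counts, files["counts"])
    write_tsv(sim$truth, files["truth"])
    write_tsv(sim$totals, files["totals"])
  }
  if ("score" %in% stages) {
    meas <- score_measurements(sim$counts, sim$totals)
    act <- aggregate_alleles(meas)
    files["measurements"] <- file.path(out_dir, "measurements.tsv")
    files["activities"] <- file.path(out_dir, "activities.tsv")
    write_tsv(meas, files["measurements"])
    write_tsv(act, files["activities"])
    if (config$n_replicates >= 2) {
      files["concordance"] <- file.path(out_dir, "concordance.tsv")
      write_tsv(replicate_concordance(meas), files["concordance"])
    }
  }
  if ("test" %in% stages) {
    diff <- differential_table(act, meas, fdr = fdr)
    files["differential"] <- file.path(out_dir, "differential.tsv")
    write_tsv(diff, files["differential"])
    summ <- attr(diff, "summary")
    files["diff_summary"] <- file.path(out_dir, "differential_summary.json")
    jsonlite::write_json(summ, files["diff_summary"], auto_unbox = TRUE,
                         digits = NA)
  }
  if ("enrich" %in% stages) {
    # major-allele regions on a fictitious coordinate system: windows are
    # laid out end to end per SNP, activity-linked peaks dropped on top
    majors <- act[act$allele_tag == "major", ]
    n <- nrow(majors)
    if (n >= 5) {
      regions <- data.frame(snp_id = majors$snp_id, chrom = "sim",
                            start0 = (seq_len(n) - 1L) * 1000L,
                            end0 = (seq_len(n) - 1L) * 1000L + INSERT_WIDTH,
                            mean_score = majors$mean_score,
                            stringsAsFactors = FALSE)
      gr <- GenomicRanges::GRanges(
        regions$chrom, IRanges::IRanges(regions$start0 + 1L, regions$end0))
      names(gr) <- regions$snp_id
      activities <- stats::setNames(regions$mean_score, regions$snp_id)
      peaks <- simulate_peaks(gr, activities, slope = peak_slope,
                              intercept = peak_intercept,
                              seed = config$seed + 2L, peak_width = 300L)
      q <- assign_quintiles(regions)
      flags <- overlap_flags(q, list(simulated_peaks = peaks))
      enr <- rbind(quintile_vs_rest(flags, q),
                   top_vs_bottom(flags, q))
      files["quintiles"] <- file.path(out_dir, "quintiles.tsv")
      files["enrichment"] <- file.path(out_dir, "enrichment.tsv")
      write_tsv(q, files["quintiles"])
      write_tsv(enr, files["enrichment"])
    }
  }

  manifest$outputs <- lapply(stats::setNames(nm = names(files)), function(k) {
    list(path = basename(files[[k]]),
         md5 = unname(tools::md5sum(files[[k]])),
         rows = length(readLines(files[[k]])) - 1L)
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
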