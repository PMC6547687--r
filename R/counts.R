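#' Assign reads to library variants by exact insert match
#'
#' A read is assigned to a (snp_id, allele_tag) when its first 196 bases
#' exactly equal that design's insert - the string-level equivalent of
#' keeping only error-free molecules. Because allelic insert pairs differ
#' at the variant base, any single sequencing error either breaks the match
#' (non-SNP position) or produces the other allele's exact insert only if
#' it hits the SNP base and flips it precisely; exact matching therefore
#' never assigns a read ambiguously.
#'
#' @param reads Character vector of read sequences (or a
#'   \link[Biostrings]{DNAStringSet}).
#' @param inserts Reference inserts: named \link[Biostrings]{DNAStringSet}
#'   or named character vector, names \code{<snp_id>_<allele_tag>}. Must be
#'   unique sequences.
#' @return data.frame with columns snp_id, allele_tag (NA for rejected
#'   reads) and reason ("ok", "short_read" or "no_match").
#' @export
assign_reads <- function(reads, inserts) {
  reads <- as.character(reads)
  ref <- as.character(inserts)
  if (anyDuplicated(ref))
    stop_starr("starr_duplicate_insert", "reference inserts are not unique")
  if (is.null(names(ref)) || anyNA(names(ref)))
    stop_starr("starr_bad_input", "reference inserts must be named")
  reason <- rep("ok", length(reads))
  reason[nchar(reads) < INSERT_WIDTH] <- "short_read"
  prefix <- substr(reads, 1L, INSERT_WIDTH)
  hit <- match(prefix, ref)
  reason[is.na(hit) & reason == "ok"] <- "no_match"
  lab <- names(ref)[hit]
  lab[reason != "ok"] <- NA_character_
  # names are "<snp_id>_<allele_tag>"; allele tag is the final token
  allele <- sub("^.*_", "", lab)
  snp <- sub("_[^_]*$", "", lab)
  data.frame(snp_id = snp, allele_tag = allele, reason = reason,
             stringsAsFactors = FALSE)
}

#' Extract the degenerate barcode from a read
#'
#' Under the library layout (196-nt insert + 17-nt 3' adaptor + 5-nt
#' barcode) the barcode occupies read positions 214-218 (1-based). The
#' 17-nt adaptor preceding it must match \code{ADAPTOR_3P} exactly: an
#' adaptor error marks an error-prone molecule. Barcodes containing
#' anything outside A/C/G/T are rejected.
#'
#' @param reads Character vector of read sequences (or DNAStringSet).
#' @return data.frame with columns barcode (NA when rejected) and reason
#'   ("ok", "short_read", "bad_adaptor", "bad_barcode").
#' @export
extract_barcodes <- function(reads) {
  reads <- as.character(reads)
  min_len <- INSERT_WIDTH + nchar(ADAPTOR_3P) + 5L
  reason <- rep("ok", length(reads))
  reason[nchar(reads) < min_len] <- "short_read"
  adaptor <- substr(reads, INSERT_WIDTH + 1L, INSERT_WIDTH + nchar(ADAPTOR_3P))
  reason[reason == "ok" & adaptor != ADAPTOR_3P] <- "bad_adaptor"
  bc <- substr(reads, INSERT_WIDTH + nchar(ADAPTOR_3P) + 1L,
               INSERT_WIDTH + nchar(ADAPTOR_3P) + 5L)
  ok_bc <- vapply(strsplit(bc, "", fixed = TRUE),
                  function(x) all(is_nt(x)), logical(1))
  reason[reason == "ok" & !ok_bc] <- "bad_barcode"
  bc[reason != "ok"] <- NA_character_
  data.frame(barcode = bc, reason = reason, stringsAsFactors = FALSE)
}

read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

classify_pool <- function(reads, inserts) {
  asn <- assign_reads(reads, inserts)
  bcs <- extract_barcodes(reads)
  reason <- ifelse(asn$reason != "ok", asn$reason, bcs$reason)
  ok <- reason == "ok"
  list(assigned = data.frame(snp_id = asn$snp_id[ok],
                             allele_tag = asn$allele_tag[ok],
                             barcode = bcs$barcode[ok],
                             stringsAsFactors = FALSE),
       n_assigned_insert = sum(asn$reason == "ok"),
       reject = table(factor(reason[!ok],
                             levels = c("short_read", "no_match",
                                        "bad_adaptor", "bad_barcode"))),
       n_total = length(reads))
}

#' Tabulate barcode counts for one replicate
#'
#' Reads the DNA and RNA FASTQ files of one replicate, applies the exact
#' insert match and barcode extraction, and counts reads per
#' (snp_id, allele_tag, barcode) molecule class in each pool.
#'
#' @param dna_fastq,rna_fastq FASTQ paths (optionally gzipped).
#' @param replicate Replicate identifier recorded in the output.
#' @param inserts Reference inserts as in \code{\link{assign_reads}}.
#' @return list with
#'   \describe{
#'     \item{counts}{data.frame snp_id, allele_tag, barcode, replicate,
#'       dna_reads, rna_reads - one row per molecule class observed in
#'       either pool.}
#'     \item{totals}{data.frame replicate, dna_total, rna_total: counted
#'       (error-free, barcoded) reads per pool, the downstream
#'       normalizers.}
#'     \item{rejects}{data.frame pool, reason, n - per-reason reject
#'       tallies, plus an "insert_matched" bookkeeping row per pool.}
#'   }
#' @export
tabulate_reads <- function(dna_fastq, rna_fastq, replicate, inserts) {
  pools <- list(dna = read_fastq_seqs(dna_fastq),
                rna = read_fastq_seqs(rna_fastq))
  if (all(lengths(pools) == 0))
    warning("no reads in either pool for replicate ", replicate)
  cls <- lapply(pools, classify_pool, inserts = inserts)
  keys <- lapply(cls, function(x)
    paste(x$assigned$snp_id, x$assigned$allele_tag, x$assigned$barcode,
          sep = "\r"))
  all_keys <- union(keys$dna, keys$rna)
  if (length(all_keys) == 0) {
    counts <- data.frame(snp_id = character(0), allele_tag = character(0),
                         barcode = character(0), replicate = character(0),
                         dna_reads = integer(0), rna_reads = integer(0),
                         stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(all_keys, "\r", fixed = TRUE)
    counts <- data.frame(
      snp_id = vapply(parts, `[`, "", 1L),
      allele_tag = vapply(parts, `[`, "", 2L),
      barcode = vapply(parts, `[`, "", 3L),
      replicate = replicate,
      dna_reads = as.integer(table(factor(keys$dna, levels = all_keys))),
      rna_reads = as.integer(table(factor(keys$rna, levels = all_keys))),
      stringsAsFactors = FALSE)
    counts <- counts[order(counts$snp_id, counts$allele_tag, counts$barcode), ]
    rownames(counts) <- NULL
  }
  totals <- data.frame(replicate = replicate,
                       dna_total = sum(counts$dna_reads),
                       rna_total = sum(counts$rna_reads))
  rejects <- do.call(rbind, lapply(names(cls), function(p) {
    rej <- cls[[p]]$reject
    rbind(data.frame(pool = p, reason = names(rej), n = as.integer(rej),
                     stringsAsFactors = FALSE),
          data.frame(pool = p, reason = "insert_matched",
                     n = cls[[p]]$n_assigned_insert,
                     stringsAsFactors = FALSE))
  }))
  list(counts = counts, totals = totals, rejects = rejects)
}

#' Tabulate all replicates of a screen
#'
#' @param files data.frame with columns replicate, dna_fastq, rna_fastq
#'   (the layout emitted by \code{\link{simulate_reads}}).
#' @param inserts Reference inserts as in \code{\link{assign_reads}}.
#' @return list(counts, totals, rejects) row-bound across replicates.
#' @export
tabulate_replicates <- function(files, inserts) {
  res <- lapply(seq_len(nrow(files)), function(i)
    tabulate_reads(files$dna_fastq[i], files$rna_fastq[i],
                   files$replicate[i], inserts))
  list(counts = do.call(rbind, lapply(res, `[[`, "counts")),
       totals = do.call(rbind, lapply(res, `[[`, "totals")),
       rejects = do.call(rbind, lapply(res, function(x)
         cbind(replicate = x$totals$replicate[1], x$rejects))))
}
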