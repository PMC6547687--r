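#' Cloning adaptors flanking each library insert
#'
#' The 5' adaptor and 3' adaptor appended to every 196-nt genomic window to
#' produce the synthesized 230-nt oligo. Both are 17 nt, so each oligo is
#' 17 + 196 + 17 = 230 nt.
#'
#' @format Character scalars.
#' @name adaptors
NULL

#' @rdname adaptors
#' @export
ADAPTOR_5P <- "TCTAGAGCATGCACCGG"

#' @rdname adaptors
#' @export
ADAPTOR_3P <- "GCCGGTCAGAATGATGG"

#' Width of the genomic window placed around each variant
#' @export
INSERT_WIDTH <- 196L

# 1-based offset of the variant base within the insert. With an even window
# the variant cannot sit exactly in the middle; the convention here is 97 nt
# upstream and 98 nt downstream of the variant base.
SNP_OFFSET <- 98L

#' Read a variant table
#'
#' Parses a TSV of candidate SNPs with columns \code{snp_id}, \code{chrom},
#' \code{pos} (1-based), \code{major}, \code{minor} and optionally
#' \code{lead_group} (LD-block identifier of the GWAS lead SNP) and
#' \code{maf}. Alleles must be single A/C/G/T bases and distinct.
#'
#' @param path Path to a tab-separated variant table with a header line.
#' @return A data.frame of validated variant records.
#' @export
read_variant_table <- function(path) {
  tab <- read_tsv(path, colClasses = NA)
  validate_snps(tab)
  tab
}

validate_snps <- function(snps) {
  required <- c("snp_id", "chrom", "pos", "major", "minor")
  missing <- setdiff(required, names(snps))
  if (length(missing) > 0)
    stop_starr("starr_bad_input",
               paste("variant table lacks columns:",
                     paste(missing, collapse = ", ")))
  if (anyDuplicated(snps$snp_id))
    stop_starr("starr_duplicate_id",
               paste("duplicate snp_id:",
                     paste(unique(snps$snp_id[duplicated(snps$snp_id)]),
                           collapse = ", ")))
  bad <- !is_nt(snps$major) | !is_nt(snps$minor) | snps$major == snps$minor
  if (any(bad))
    stop_starr("starr_bad_allele",
               paste("invalid allele pair for:",
                     paste(snps$snp_id[bad], collapse = ", ")))
  if (any(snps$pos < 1))
    stop_starr("starr_bad_input", "pos must be >= 1")
  invisible(snps)
}

#' Extract the allelic window pair for one SNP
#'
#' Pulls the 196-nt window centered on the variant (97 nt upstream, 98 nt
#' downstream, variant at 1-based insert offset 98) from the plus strand of
#' the reference and substitutes the variant base to produce both allelic
#' inserts.
#'
#' @param genome A named \link[Biostrings]{DNAStringSet} (names are
#'   chromosome identifiers) or path to a FASTA file.
#' @param snp A one-row data.frame (or list) with fields \code{snp_id},
#'   \code{chrom}, \code{pos}, \code{major}, \code{minor}.
#' @return A list with elements \code{major} and \code{minor}: the two
#'   196-nt insert sequences (character), identical except at offset 98;
#'   plus \code{start0}/\code{end0}, the window in 0-based half-open
#'   (BED) coordinates.
#' @export
extract_window <- function(genome, snp) {
  genome <- load_genome(genome)
  chrom <- as.character(snp$chrom)
  if (!chrom %in% names(genome))
    stop_starr("starr_bad_input", paste("chromosome not in genome:", chrom))
  pos <- as.integer(snp$pos)
  start <- pos - (SNP_OFFSET - 1L)          # 1-based window start
  end <- start + INSERT_WIDTH - 1L
  if (start < 1L || end > length(genome[[chrom]]))
    stop_starr("starr_window_bounds",
               sprintf("window [%d, %d] out of bounds for %s (%s)",
                       start, end, chrom, snp$snp_id))
  insert <- as.character(Biostrings::subseq(genome[[chrom]], start, end))
  ref_base <- substr(insert, SNP_OFFSET, SNP_OFFSET)
  if (!ref_base %in% c(snp$major, snp$minor))
    stop_starr("starr_allele_mismatch",
               sprintf("reference base %s at %s:%d matches neither allele %s/%s (%s)",
                       ref_base, chrom, pos, snp$major, snp$minor, snp$snp_id))
  set_base <- function(allele) {
    out <- insert
    substr(out, SNP_OFFSET, SNP_OFFSET) <- allele
    out
  }
  list(major = set_base(as.character(snp$major)),
       minor = set_base(as.character(snp$minor)),
       start0 = start - 1L, end0 = end)
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop_starr("starr_bad_input", "genome must be a DNAStringSet or FASTA path")
  # FASTA descriptions often carry extra tokens after the identifier
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Build the synthesizable oligo library
#'
#' For every SNP, constructs both allelic 196-nt inserts and the full
#' 230-nt oligos (insert flanked by \code{ADAPTOR_5P} / \code{ADAPTOR_3P}).
#' Two designs per SNP, named \code{<snp_id>_major} / \code{<snp_id>_minor}.
#'
#' @param snps Variant table as from \code{\link{read_variant_table}}.
#' @param genome Reference as in \code{\link{extract_window}}.
#' @return A list with
#'   \describe{
#'     \item{designs}{data.frame: snp_id, allele_tag, chrom, start0, end0,
#'       insert, oligo (one row per allele).}
#'     \item{inserts}{\link[Biostrings]{DNAStringSet} of the 196-nt inserts,
#'       one record per design, named \code{<snp_id>_<allele_tag>} - the
#'       reference used for read assignment.}
#'   }
#' @export
build_library <- function(snps, genome) {
  validate_snps(snps)
  genome <- load_genome(genome)
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    snp <- snps[i, ]
    win <- extract_window(genome, snp)
    data.frame(
      snp_id = rep(snp$snp_id, 2L),
      allele_tag = c("major", "minor"),
      chrom = rep(as.character(snp$chrom), 2L),
      start0 = rep(win$start0, 2L),
      end0 = rep(win$end0, 2L),
      insert = c(win$major, win$minor),
      stringsAsFactors = FALSE
    )
  })
  designs <- do.call(rbind, rows)
  designs$oligo <- paste0(ADAPTOR_5P, designs$insert, ADAPTOR_3P)
  inserts <- Biostrings::DNAStringSet(designs$insert)
  names(inserts) <- paste(designs$snp_id, designs$allele_tag, sep = "_")
  if (anyDuplicated(as.character(inserts)))
    warning("non-unique inserts in library; read assignment will be ambiguous")
  list(designs = designs, inserts = inserts)
}

#' Export a built library to disk
#'
#' Writes the insert reference FASTA, the design table TSV, and a BED file
#' of the window coordinates (0-based half-open; one record per SNP).
#'
#' @param library A library from \code{\link{build_library}}.
#' @param fasta,tsv,bed Output paths; any may be \code{NULL} to skip.
#' @return Invisibly, the named list of written paths.
#' @export
write_library <- function(library, fasta = NULL, tsv = NULL, bed = NULL) {
  if (!is.null(fasta))
    Biostrings::writeXStringSet(library$inserts, fasta)
  if (!is.null(tsv))
    write_tsv(library$designs, tsv)
  if (!is.null(bed)) {
    d <- library$designs[library$designs$allele_tag == "major", ]
    gr <- GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(start = d$start0 + 1L, end = d$end0))
    names(gr) <- d$snp_id
    rtracklayer::export.bed(gr, bed)
  }
  invisible(list(fasta = fasta, tsv = tsv, bed = bed))
}

#' Genomic windows of a design table as a GRanges
#'
#' @param designs The \code{designs} data.frame from
#'   \code{\link{build_library}} (or its major-allele subset).
#' @return A \link[GenomicRanges]{GRanges} with one range per SNP,
#'   named by snp_id.
#' @export
design_ranges <- function(designs) {
  d <- designs[!duplicated(designs$snp_id), ]
  gr <- GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(start = d$start0 + 1L, end = d$end0))
  names(gr) <- d$snp_id
  gr
}
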