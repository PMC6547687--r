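# Programmatic fixtures: a toy reference genome and matching variant table
# whose snp_ids line up with the generator's naming, so simulated count
# tables can be traced back to designed inserts.

make_toy_genome <- function(chrom_lengths = c(chr1 = 2000L), seed = 42L) {
  set.seed(seed)
  seqs <- vapply(chrom_lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  gen <- Biostrings::DNAStringSet(seqs)
  names(gen) <- names(chrom_lengths)
  gen
}

# n SNPs spread along chr1, major allele = reference base
make_toy_snps <- function(genome, n = 4L, chrom = "chr1", seed = 43L) {
  set.seed(seed)
  len <- length(genome[[chrom]])
  pos <- seq(from = 200L, to = len - 200L, length.out = n)
  pos <- as.integer(round(pos))
  ref <- vapply(pos, function(p)
    as.character(Biostrings::subseq(genome[[chrom]], p, p)), character(1))
  minor <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  data.frame(snp_id = sprintf("snp%04d", seq_len(n)),
             chrom = chrom, pos = pos, major = ref, minor = unname(minor),
             lead_group = "lead1", stringsAsFactors = FALSE)
}

# a library + matching simulated counts, for read-level round trips
make_toy_screen <- function(n_snps = 4L, config = NULL) {
  genome <- make_toy_genome(c(chr1 = 2000L + 500L * n_snps))
  snps <- make_toy_snps(genome, n = n_snps)
  lib <- build_library(snps, genome)
  if (is.null(config))
    config <- sim_config(n_snps = n_snps, n_replicates = 2L,
                         dna_depth = 5000, rna_depth = 5000,
                         dropout_prob = 0, seed = 7L)
  sim <- simulate_counts(config)
  list(genome = genome, snps = snps, lib = lib, sim = sim, config = config)
}
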