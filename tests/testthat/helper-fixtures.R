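# Small in-code fixtures shared across tests.

# genotype matrix from a samples x sites matrix of call codes
toy_geno <- function(calls, chrom = NULL, pos = NULL, ref = NULL,
                     alt = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("C", m)
  genotype_matrix(paste0("s", seq_len(nrow(calls))),
                  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt),
                  calls)
}

# write a VCF from raw body lines (header supplied here); body lines carry
# CHROM POS ID REF ALT QUAL FILTER INFO FORMAT sample...
write_test_vcf <- function(body_lines, samples, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

# deterministic random DNA string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
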