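# Coordinate conventions: all internal positions are 1-based (VCF); BED
# export converts to 0-based half-open. Genotypes collapse phase.

#' Construct a genotype matrix
#'
#' The central container: an ordered set of samples, an ordered set of
#' biallelic SNP sites, and a samples x sites matrix of diploid calls coded
#' 0 (hom-ref), 1 (het), 2 (hom-alt), -1 (missing).
#'
#' @param samples character vector of sample identifiers.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `id`. Must be sorted by (chrom, pos) with no
#'   duplicated (chrom, pos); chromosome order is order of first appearance.
#' @param calls integer matrix, `length(samples)` rows x `nrow(sites)`
#'   columns, values in {-1, 0, 1, 2}.
#' @return an object of class `geno_matrix`.
#' @export
genotype_matrix <- function(samples, sites, calls) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (is.null(sites$id)) sites$id <- paste0(sites$chrom, "_", sites$pos)
  calls <- matrix(as.integer(calls), nrow = length(samples))
  if (ncol(calls) != nrow(sites))
    stop("calls has ", ncol(calls), " columns but there are ",
         nrow(sites), " sites")
  if (!all(calls %in% c(-1L, 0L, 1L, 2L)))
    stop("calls must be coded -1/0/1/2")
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  bad <- sites$ref == sites$alt |
    !(sites$ref %in% c("A", "C", "G", "T")) |
    !(sites$alt %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("ref/alt must be distinct single bases in ACGT")
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicate (chrom, pos) among sites")
  rownames(sites) <- NULL
  dimnames(calls) <- list(samples, sites$id)
  structure(list(samples = samples, sites = sites, calls = calls),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$samples), "samples x", nrow(x$sites),
      "sites on", length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(length(x$samples), nrow(x$sites))

#' Read a multi-sample VCF into a genotype matrix
#'
#' Only biallelic SNP records are kept; multiallelic or indel records are
#' skipped with a warning (the count is stored in attribute `n_skipped`).
#' Phased and unphased genotypes are treated identically; any half-missing
#' genotype (e.g. `./1`) is coded missing. Malformed GT strings are coded
#' missing and counted in attribute `n_malformed`.
#'
#' @param path path to a VCF (optionally bgzipped) with a GT FORMAT field.
#' @param regions optional data.frame(chrom, start, end), 1-based inclusive;
#'   only sites inside one of the intervals are returned.
#' @return a [genotype_matrix()] with attributes `n_skipped`, `n_malformed`.
#' @export
read_vcf <- function(path, regions = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0L) stop("VCF contains no variant records")
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    stop("VCF contains no sample genotype columns")

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0)
    warning(n_skipped, " multiallelic/indel record(s) skipped")

  chrom <- fix[snp, "CHROM"]
  pos <- as.integer(fix[snp, "POS"])
  id <- fix[snp, "ID"]
  id[is.na(id) | id == "."] <- paste0(chrom, "_", pos)[is.na(id) | id == "."]

  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(GENO_MISSING, nrow = nrow(gt), ncol = ncol(gt))
  code[gt %in% c("0/0", "0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1", "1")] <- 2L
  known <- is.na(gt) | grepl(".", gt, fixed = TRUE) |
    gt %in% c("0/0", "0/1", "1/0", "1/1", "0", "1")
  n_malformed <- sum(!known)
  if (n_malformed > 0)
    warning(n_malformed, " malformed GT value(s) set to missing")

  # drop duplicate (chrom, pos) records, keeping the first
  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) {
    warning(sum(dup), " duplicate-position record(s) skipped")
    n_skipped <- n_skipped + sum(dup)
  }
  keep <- !dup
  if (!is.null(regions)) {
    inside <- rep(FALSE, length(chrom))
    for (r in seq_len(nrow(regions)))
      inside <- inside | (chrom == regions$chrom[r] &
                            pos >= regions$start[r] & pos <= regions$end[r])
    keep <- keep & inside
  }

  g <- genotype_matrix(colnames(gt),
                       data.frame(chrom = chrom[keep], pos = pos[keep],
                                  ref = ref[snp][keep], alt = alt[snp][keep],
                                  id = id[keep], stringsAsFactors = FALSE),
                       t(code[keep, , drop = FALSE]))
  attr(g, "n_skipped") <- n_skipped
  attr(g, "n_malformed") <- n_malformed
  g
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits GT-only records; the inverse of [read_vcf()] on the call codes and
#' coordinates.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param contig_lengths optional named vector of contig lengths for the
#'   header.
#' @export
write_vcf <- function(g, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=panelsmith", con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(contig_lengths), as.integer(contig_lengths)),
               con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$samples), collapse = "\t"), con)
  gt_str <- c("./.", "0/0", "0/1", "1/1")[g$calls + 2L]
  dim(gt_str) <- dim(g$calls)
  body <- paste(g$sites$chrom, g$sites$pos, g$sites$id, g$sites$ref,
                g$sites$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a reference genome FASTA
#'
#' @param path FASTA path (a `.fai` index is not required; sequences are
#'   held in memory).
#' @return a [Biostrings::DNAStringSet] with unique names.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (anyDuplicated(names(ref))) stop("duplicate sequence names in FASTA")
  ref
}

#' Reference contig lengths
#' @param ref a `DNAStringSet` reference genome.
#' @return named integer vector of lengths in bp.
#' @export
ref_lengths <- function(ref) setNames(Biostrings::width(ref), names(ref))

#' Fetch the flanking sequences of a site
#'
#' Left flank covers reference positions `[pos - flank_len, pos - 1]`, right
#' flank `[pos + 1, pos + flank_len]` (1-based inclusive). Flanks truncated
#' at contig ends are returned shorter with the corresponding truncation
#' flag set.
#'
#' @param ref `DNAStringSet` reference genome.
#' @param chrom,pos site coordinate (1-based).
#' @param flank_len flank length in bp (default 110, the capture-probe
#'   flank evaluated throughout the design).
#' @return list(left, right, truncated_left, truncated_right).
#' @export
fetch_flank <- function(ref, chrom, pos, flank_len = 110L) {
  stopifnot(flank_len >= 1L)
  if (!chrom %in% names(ref)) stop("unknown chromosome: ", chrom)
  len <- ref_lengths(ref)[[chrom]]
  if (pos < 1L || pos > len)
    stop("site ", chrom, ":", pos, " beyond contig end (length ", len, ")")
  ls <- max(1L, pos - flank_len)
  rs <- min(len, pos + flank_len)
  left <- if (pos == 1L) "" else
    as.character(Biostrings::subseq(ref[[chrom]], ls, pos - 1L))
  right <- if (pos == len) "" else
    as.character(Biostrings::subseq(ref[[chrom]], pos + 1L, rs))
  list(left = left, right = right,
       truncated_left = nchar(left) < flank_len,
       truncated_right = nchar(right) < flank_len)
}

#' Write a panel as BED + TSV
#'
#' The BED file uses 0-based half-open single-base intervals (`pos - 1`,
#' `pos`); the TSV carries the site table with its per-site statistics.
#'
#' @param panel a `snp_panel` (see [select_uniform()]).
#' @param prefix output path prefix; writes `<prefix>.bed`, `<prefix>.tsv`.
#' @return invisibly, the two paths.
#' @export
write_panel <- function(panel, prefix) {
  sites <- if (inherits(panel, "snp_panel")) panel$sites else panel
  if (is.null(sites) || nrow(sites) == 0L) stop("panel is empty")
  bed <- file.path(paste0(prefix, ".bed"))
  tsv <- file.path(paste0(prefix, ".tsv"))
  write.table(data.frame(sites$chrom, sites$pos - 1L, sites$pos, sites$id),
              bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sites, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed, tsv = tsv))
}

#' Read a panel TSV written by [write_panel()]
#' @param path path to the `.tsv` file.
#' @return a `snp_panel` object (without a selection log).
#' @export
read_panel <- function(path) {
  sites <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, window = attr(sites, "window"),
                 selection_log = NULL), class = "snp_panel")
}

#' Validate a VCF/FASTA pair
#'
#' Checks that every site's chromosome exists in the reference, every
#' position lies within the contig, and the VCF REF allele matches the
#' reference base.
#'
#' @param g a [genotype_matrix()].
#' @param ref `DNAStringSet` reference genome.
#' @return data.frame of offending sites (zero rows when consistent).
#' @export
validate_inputs <- function(g, ref) {
  lens <- ref_lengths(ref)
  s <- g$sites
  problem <- character(nrow(s))
  known <- s$chrom %in% names(lens)
  problem[!known] <- "unknown chromosome"
  inside <- known & s$pos <= lens[s$chrom]
  problem[known & !inside] <- "position beyond contig end"
  idx <- which(inside)
  if (length(idx)) {
    base <- vapply(idx, function(i)
      as.character(Biostrings::subseq(ref[[s$chrom[i]]], s$pos[i], s$pos[i])),
      character(1))
    problem[idx[base != s$ref[idx]]] <- "REF allele mismatch"
  }
  bad <- problem != ""
  cbind(s[bad, c("chrom", "pos", "ref", "alt", "id")],
        problem = problem[bad])
}
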