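# Per-site statistics and the candidate-SNP inclusion filter.

#' Per-site allele and heterozygosity statistics
#'
#' For each site, computes the call rate, alternate-allele frequency (a het
#' contributes one alternate allele), minor allele frequency, observed
#' heterozygosity (fraction het among called genotypes), expected
#' heterozygosity `he = 2p(1-p)`, and two PIC variants: `pic_chip`, defined
#' as expected heterozygosity (maximum 0.5), and the classical biallelic
#' `pic_classic = 1 - p^2 - q^2 - 2 p^2 q^2` (maximum 0.375). Missing
#' genotypes are excluded from allele counts; no imputation.
#'
#' All-missing sites get NA statistics and `defined = FALSE`.
#'
#' @param g a [genotype_matrix()].
#' @return data.frame, one row per site: the site table plus `n_called`,
#'   `call_rate`, `p_alt`, `maf`, `hobs`, `he`, `pic_chip`, `pic_classic`,
#'   `defined`.
#' @export
site_stats <- function(g) {
  calls <- g$calls
  n_samples <- nrow(calls)
  called <- calls >= 0L
  n_called <- colSums(called)
  alt <- colSums(calls * called)      # -1 * FALSE = 0, so missing drop out
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  hobs <- ifelse(n_called > 0, colSums(calls == 1L) / n_called, NA_real_)
  he <- 2 * p * (1 - p)
  q <- 1 - p
  pic_classic <- 1 - p^2 - q^2 - 2 * p^2 * q^2
  cbind(g$sites,
        data.frame(n_called = n_called, call_rate = n_called / n_samples,
                   p_alt = p, maf = maf, hobs = hobs, he = he,
                   pic_chip = he, pic_classic = pic_classic,
                   defined = n_called > 0, row.names = NULL))
}

#' Candidate-SNP inclusion filter
#'
#' A site passes iff its missing rate is strictly below `max_missing`, its
#' minor allele frequency strictly above `min_maf`, and its observed
#' heterozygosity strictly below `max_hobs`. All three inequalities are
#' strict; sites with undefined statistics fail.
#'
#' With the defaults, every retained site has expected heterozygosity (and
#' hence `pic_chip`) in (0.455, 0.5], the band a high-MAF chip design
#' targets.
#'
#' @param stats data.frame from [site_stats()].
#' @param max_missing maximum missing-call fraction (default 0.1).
#' @param min_maf minimum minor allele frequency (default 0.35).
#' @param max_hobs maximum observed heterozygosity (default 0.5).
#' @return logical vector, one element per site.
#' @export
qc_filter <- function(stats, max_missing = 0.1, min_maf = 0.35,
                      max_hobs = 0.5) {
  stopifnot(max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 1, max_hobs >= 0, max_hobs <= 1)
  # strict inequalities with a guard so that values equal to a threshold
  # up to floating-point rounding (e.g. a missing rate of exactly 0.1
  # computed as 1 - 0.9) fail as the printed criteria require
  eps <- 1e-9
  ok <- stats$defined &
    (1 - stats$call_rate) < max_missing - eps &
    stats$maf > min_maf + eps &
    stats$hobs < max_hobs - eps
  ok & !is.na(ok)
}

#' Write a per-site statistics report
#' @param stats data.frame from [site_stats()] (optionally with extra
#'   columns such as the filter verdict).
#' @param path output TSV path.
#' @export
write_site_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
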