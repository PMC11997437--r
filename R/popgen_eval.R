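# Population-genetic estimators: nucleotide diversity, Weir-Cockerham Fst,
# Tajima's D, and chip-vs-resequencing concordance.
#
# All estimators are allele-count based (genotypes collapsed to allele
# counts); phase is never used. Window coordinates in outputs are 0-based
# half-open.

#' Per-site nucleotide diversity
#'
#' With reference/alternate allele counts `c_ref`, `c_alt` and
#' `n = c_ref + c_alt` called alleles, the per-site diversity is the mean
#' pairwise difference `c_ref * c_alt / choose(n, 2)`.
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector, one value per site; NA where fewer than 2
#'   alleles were called.
#' @export
site_pi <- function(g) {
  calls <- g$calls
  called <- calls >= 0L
  n <- 2L * colSums(called)
  c_alt <- colSums(calls * called)
  c_ref <- n - c_alt
  unname(ifelse(n >= 2L, c_ref * c_alt / (n * (n - 1) / 2), NA_real_))
}

sliding_windows <- function(chrom_lengths, window, step) {
  do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window, len))
  }))
}

#' Sliding-window nucleotide diversity
#'
#' Windows of `window` bp advancing by `step` bp; the per-window value is
#' the sum of per-site diversities over contained sites divided by the
#' window span in bp (so a window with no SNPs reports 0).
#'
#' @param g a [genotype_matrix()].
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window,step window and step size in bp (defaults 100 kb / 10 kb).
#' @return data.frame(chrom, start, end, n_snps, pi); `start`/`end` are
#'   0-based half-open.
#' @export
windowed_pi <- function(g, chrom_lengths, window = 100000L, step = 10000L) {
  wins <- sliding_windows(chrom_lengths, window, step)
  pi_site <- site_pi(g)
  pi_site[is.na(pi_site)] <- 0
  agg <- window_aggregate(g$sites, wins, pi_site)
  wins$n_snps <- agg$n
  wins$pi <- agg$sum / (wins$end - wins$start)
  wins
}

# sum `value` and count sites per window; windows are 0-based half-open
window_aggregate <- function(sites, wins, value) {
  n <- integer(nrow(wins))
  s <- numeric(nrow(wins))
  for (ch in unique(wins$chrom)) {
    wi <- which(wins$chrom == ch)
    si <- which(sites$chrom == ch)
    if (!length(si)) next
    pos0 <- sites$pos[si] - 1L
    for (k in wi) {
      inw <- pos0 >= wins$start[k] & pos0 < wins$end[k]
      n[k] <- sum(inw)
      s[k] <- sum(value[si][inw])
    }
  }
  list(n = n, sum = s)
}

#' Per-fragment nucleotide diversity
#'
#' The windowed estimator restricted to arbitrary fragments (e.g. the
#' captured probe regions of a chip). A fragment with no sites reports 0.
#'
#' @param g a [genotype_matrix()].
#' @param fragments data.frame(chrom, start, end), 0-based half-open.
#' @return the fragment table with `n_snps`, `pi` columns plus attribute
#'   `mean_pi` (unweighted mean over fragments).
#' @export
fragment_pi <- function(g, fragments) {
  pi_site <- site_pi(g)
  pi_site[is.na(pi_site)] <- 0
  agg <- window_aggregate(g$sites, fragments, pi_site)
  fragments$n_snps <- agg$n
  fragments$pi <- agg$sum / (fragments$end - fragments$start)
  attr(fragments, "mean_pi") <- mean(fragments$pi)
  fragments
}

# Weir & Cockerham (1984) per-site variance components for r populations.
# Returns a data.frame with components a (among populations), b, c and a
# `valid` flag; the Fst estimator is ratio-of-sums sum(a)/sum(a+b+c).
wc_components <- function(g, pops) {
  pops <- pops[g$samples]
  if (any(is.na(pops))) stop("every sample needs a population label")
  pop_levels <- unique(pops)
  r <- length(pop_levels)
  if (r < 2L) stop("need at least 2 populations")
  calls <- g$calls
  called <- calls >= 0L
  np <- t(vapply(pop_levels, function(p)
    colSums(called[pops == p, , drop = FALSE]), numeric(ncol(calls))))
  ap <- t(vapply(pop_levels, function(p) {
    rows <- pops == p
    colSums(calls[rows, , drop = FALSE] * called[rows, , drop = FALSE])
  }, numeric(ncol(calls))))
  hp <- t(vapply(pop_levels, function(p)
    colSums(calls[pops == p, , drop = FALSE] == 1L), numeric(ncol(calls))))
  pp <- ifelse(np > 0, ap / (2 * np), 0)
  hp <- ifelse(np > 0, hp / np, 0)

  C <- colSums(np)                       # total called individuals
  nbar <- C / r
  nc <- (C - colSums(np^2) / C) / (r - 1)
  pbar <- colSums(np * pp) / C
  s2 <- colSums(np * (pp - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(np * hp) / C

  inner <- pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4
  a <- nbar / nc * (s2 - inner / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  valid <- colSums(np >= 1) == r & nbar > 1 & nc > 0
  data.frame(chrom = g$sites$chrom, pos = g$sites$pos,
             a = ifelse(valid, a, NA_real_),
             b = ifelse(valid, b, NA_real_),
             c = ifelse(valid, cc, NA_real_), valid = valid)
}

#' Weir-Cockerham Fst, genome-wide and in sliding windows
#'
#' Per-site variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) follow Weir
#' & Cockerham (1984); windowed and genome-wide estimates are the
#' ratio-of-sums `sum(a) / sum(a + b + c)` over contributing sites.
#' Negative per-window estimates are reported, not clipped. Windows in
#' which some population has no called genotype at any site are flagged.
#'
#' @param g a [genotype_matrix()].
#' @param pops named character vector: sample -> population label.
#' @param chrom_lengths named vector of chromosome lengths (required for
#'   windowed output).
#' @param window,step window/step in bp; `window = NULL` (default) skips
#'   the windowed scan.
#' @return list(fst_global, per_site, windows); `windows` is NULL unless a
#'   window size was given.
#' @export
fst_wc <- function(g, pops, chrom_lengths = NULL, window = NULL,
                   step = 10000L) {
  comp <- wc_components(g, pops)
  num <- sum(comp$a[comp$valid])
  den <- sum((comp$a + comp$b + comp$c)[comp$valid])
  fst_global <- if (den > 0) num / den else NA_real_

  windows <- NULL
  if (!is.null(window)) {
    if (is.null(chrom_lengths))
      stop("chrom_lengths is required for windowed Fst")
    wins <- sliding_windows(chrom_lengths, window, step)
    a_v <- ifelse(comp$valid, comp$a, 0)
    abc_v <- ifelse(comp$valid, comp$a + comp$b + comp$c, 0)
    agg_a <- window_aggregate(g$sites, wins, a_v)
    agg_abc <- window_aggregate(g$sites, wins, abc_v)
    n_valid <- window_aggregate(g$sites, wins, as.numeric(comp$valid))$sum
    wins$n_snps <- agg_a$n
    wins$fst <- ifelse(agg_abc$sum > 0, agg_a$sum / agg_abc$sum, NA_real_)
    wins$flagged <- wins$n_snps > 0 & n_valid == 0
    windows <- wins
  }
  list(fst_global = fst_global, per_site = comp, windows = windows)
}

#' Tajima's D from region summaries
#'
#' Closed-form D for `n` sampled alleles, `S` segregating sites and
#' pairwise diversity `theta_pi`, using the standard a1, a2, b1, b2, c1,
#' c2, e1, e2 constants.
#'
#' @param n number of sampled alleles (haplotype-equivalents).
#' @param S number of segregating sites.
#' @param theta_pi sum of per-site pairwise diversities over the region.
#' @return Tajima's D (NaN when S = 0).
#' @export
tajima_d_value <- function(n, S, theta_pi) {
  stopifnot(n >= 3)
  if (S == 0) return(NaN)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D over a genomic region
#'
#' Each diploid contributes two alleles; missing genotypes reduce the
#' per-site allele count, and the region-level `n` is the minimum across
#' included sites (conservative). Regions with no segregating site return
#' NaN with attribute `flag = "no segregating sites"`.
#'
#' @param g a [genotype_matrix()].
#' @param chrom optional chromosome; NULL uses all sites.
#' @param start,end optional 0-based half-open bounds within `chrom`.
#' @return Tajima's D with attributes `n`, `S`, `theta_pi`.
#' @export
tajimas_d <- function(g, chrom = NULL, start = NULL, end = NULL) {
  keep <- rep(TRUE, nrow(g$sites))
  if (!is.null(chrom)) keep <- g$sites$chrom == chrom
  if (!is.null(start)) keep <- keep & (g$sites$pos - 1L) >= start
  if (!is.null(end)) keep <- keep & (g$sites$pos - 1L) < end
  if (!any(keep)) stop("no sites in region")
  calls <- g$calls[, keep, drop = FALSE]
  called <- calls >= 0L
  n_alleles <- 2L * colSums(called)
  ok <- n_alleles >= 2L
  c_alt <- colSums(calls * called)[ok]
  n_alleles <- n_alleles[ok]
  seg <- c_alt > 0L & c_alt < n_alleles
  S <- sum(seg)
  n <- min(n_alleles)
  if (n < 3) stop("need at least 3 sampled alleles")
  pi_sites <- (n_alleles - c_alt) * c_alt / (n_alleles * (n_alleles - 1) / 2)
  theta_pi <- sum(pi_sites)
  d <- tajima_d_value(n, S, theta_pi)
  attr(d, "n") <- n
  attr(d, "S") <- S
  attr(d, "theta_pi") <- theta_pi
  if (S == 0) attr(d, "flag") <- "no segregating sites"
  d
}

#' Concordance between two windowed statistics
#'
#' Pearson correlation over the windows present in both tables (matched on
#' chrom/start/end); windows with zero SNPs in either table are excluded.
#'
#' @param full,chip data.frames of windowed statistics (e.g. from
#'   [windowed_pi()] or [fst_wc()]).
#' @param stat column name to correlate (e.g. `"pi"` or `"fst"`).
#' @return list(r, n_windows).
#' @export
concordance <- function(full, chip, stat = "pi") {
  key_f <- paste(full$chrom, full$start, full$end)
  key_c <- paste(chip$chrom, chip$start, chip$end)
  m <- match(key_f, key_c)
  sel <- !is.na(m) & full$n_snps > 0 & chip$n_snps[m] > 0
  x <- full[[stat]][sel]
  y <- chip[[stat]][m[sel]]
  fin <- is.finite(x) & is.finite(y)
  if (sum(fin) < 3L) stop("fewer than 3 shared informative windows")
  list(r = cor(x[fin], y[fin]), n_windows = sum(fin))
}

#' Write windowed statistics as TSV
#' @param windows data.frame of windowed statistics.
#' @param path output path.
#' @export
write_windows <- function(windows, path) {
  write.table(windows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
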