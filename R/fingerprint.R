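# Fingerprint-set distillation, QR-style genotype profiles, method-of-
# moments IBD, relationship classification and haplotype grouping.

QR_VERSION <- "qr1"
QR_COLS <- 32L

#' Distill a panel to a compact fingerprint locus set
#'
#' Loci are allocated to chromosomes proportionally to chromosome length
#' (largest-remainder rounding) and picked greedily within each chromosome
#' by descending `pic_chip` subject to a minimum pairwise spacing. If a
#' chromosome cannot fill its quota the leftover is redistributed to the
#' other chromosomes; if the overall target is still infeasible a
#' best-effort set is returned with a warning.
#'
#' @param panel a `snp_panel` or site data.frame with `chrom`, `pos`,
#'   `pic_chip`.
#' @param k target number of loci (default 384).
#' @param min_gap minimum spacing between chosen loci in bp (default
#'   100000).
#' @param chrom_lengths optional named lengths; defaults to the maximum
#'   panel position per chromosome.
#' @return a `fingerprint_set`: list(loci, k, min_gap).
#' @export
select_fingerprint <- function(panel, k = 384L, min_gap = 100000L,
                               chrom_lengths = NULL) {
  sites <- if (inherits(panel, "snp_panel")) panel$sites else panel
  if (nrow(sites) < k)
    stop("panel has ", nrow(sites), " sites, fewer than k = ", k)
  chroms <- unique(sites$chrom)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(split(sites$pos, sites$chrom)[chroms], max,
                            numeric(1))
  chrom_lengths <- chrom_lengths[chroms]

  # largest-remainder allocation proportional to chromosome length
  exact <- k * chrom_lengths / sum(chrom_lengths)
  quota <- floor(exact)
  rem <- k - sum(quota)
  if (rem > 0) {
    extra <- order(exact - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }

  pick_chrom <- function(ch, q) {
    cand <- sites[sites$chrom == ch, , drop = FALSE]
    cand <- cand[order(-cand$pic_chip, cand$pos), , drop = FALSE]
    chosen <- integer(0)
    pos <- numeric(0)
    for (i in seq_len(nrow(cand))) {
      if (length(chosen) >= q) break
      if (all(abs(cand$pos[i] - pos) >= min_gap)) {
        chosen <- c(chosen, i)
        pos <- c(pos, cand$pos[i])
      }
    }
    cand[chosen, , drop = FALSE]
  }

  picked <- lapply(chroms, function(ch) pick_chrom(ch, quota[[ch]]))
  names(picked) <- chroms
  short <- k - sum(vapply(picked, nrow, integer(1)))
  if (short > 0) {
    # redistribute unfilled quota across chromosomes with spare candidates
    for (ch in chroms) {
      if (short == 0) break
      have <- nrow(picked[[ch]])
      more <- pick_chrom(ch, have + short)
      gain <- nrow(more) - have
      if (gain > 0) {
        picked[[ch]] <- more
        short <- short - gain
      }
    }
    if (short > 0)
      warning("spacing constraint infeasible; returning ", k - short,
              " of ", k, " loci")
  }
  loci <- do.call(rbind, picked)
  loci <- loci[order(match(loci$chrom, chroms), loci$pos), , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(loci = loci, k = k, min_gap = min_gap),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("fingerprint_set:", nrow(x$loci), "loci (target", x$k,
      "), min gap", x$min_gap, "bp\n")
  invisible(x)
}

#' Encode a genotype vector as a QR-style grid
#'
#' Each locus is a 2-bit code (00 hom-ref, 01 het, 10 hom-alt, 11
#' missing) laid out row-major in a fixed-width binary grid, padded with
#' zero bits, plus a final checksum row holding the column-wise XOR parity
#' of the payload rows. Any single flipped cell breaks its column's
#' parity, so corruption of one cell is always detected on decode.
#'
#' @param calls integer genotype vector ({-1, 0, 1, 2}) at the fingerprint
#'   loci, in fixed locus order.
#' @param sample optional sample identifier stored with the profile.
#' @return a `qr_profile`: list(sample, grid, k, version); `grid` is a 0/1
#'   matrix whose last row is the checksum.
#' @export
encode_qr <- function(calls, sample = NA_character_) {
  stopifnot(all(calls %in% c(-1L, 0L, 1L, 2L)))
  k <- length(calls)
  code <- ifelse(calls < 0L, 3L, calls)
  bits <- as.integer(rbind(code %/% 2L, code %% 2L))  # b1 then b0 per locus
  n_rows <- ceiling(2 * k / QR_COLS)
  bits <- c(bits, integer(n_rows * QR_COLS - 2 * k))
  payload <- matrix(bits, nrow = n_rows, ncol = QR_COLS, byrow = TRUE)
  checksum <- as.integer(colSums(payload) %% 2L)
  structure(list(sample = sample, grid = rbind(payload, checksum),
                 k = k, version = QR_VERSION), class = "qr_profile")
}

#' Decode a QR-style profile back to genotype calls
#'
#' Verifies the column-parity checksum before decoding; a corrupted grid
#' raises an error.
#'
#' @param profile a `qr_profile` from [encode_qr()].
#' @return integer genotype vector of length `profile$k`.
#' @export
decode_qr <- function(profile) {
  stopifnot(inherits(profile, "qr_profile"))
  if (!identical(profile$version, QR_VERSION))
    stop("unsupported profile version: ", profile$version)
  grid <- profile$grid
  payload <- grid[-nrow(grid), , drop = FALSE]
  checksum <- grid[nrow(grid), ]
  if (!all(colSums(payload) %% 2L == checksum))
    stop("checksum mismatch: profile is corrupted")
  bits <- as.integer(t(payload))[seq_len(2L * profile$k)]
  b1 <- bits[seq(1L, length(bits), by = 2L)]
  b0 <- bits[seq(2L, length(bits), by = 2L)]
  code <- 2L * b1 + b0
  ifelse(code == 3L, -1L, code)
}

#' Serialize QR profiles to JSON
#' @param profiles list of `qr_profile` objects.
#' @param path output path.
#' @export
write_qr_json <- function(profiles, path) {
  payload <- lapply(profiles, function(p)
    list(sample = p$sample, version = p$version, k = p$k,
         rows = apply(p$grid, 1, paste, collapse = "")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

# PLINK-style expected P(IBS = s | IBD = k) per locus, with the
# small-sample correction factors based on the cohort allele count A.
ibs_given_ibd <- function(p, A) {
  q <- 1 - p
  x <- p * A
  y <- q * A
  T1 <- A / (A - 1); T2 <- A / (A - 2); T3 <- A / (A - 3)
  c123 <- T1 * T2 * T3
  c12 <- T1 * T2
  list(
    p00 = 2 * p^2 * q^2 * ((x - 1) / x) * ((y - 1) / y) * c123,
    p10 = 4 * p^3 * q * ((x - 1) / x) * ((x - 2) / x) * c123 +
          4 * p * q^3 * ((y - 1) / y) * ((y - 2) / y) * c123,
    p20 = p^4 * ((x - 1) / x) * ((x - 2) / x) * ((x - 3) / x) * c123 +
          q^4 * ((y - 1) / y) * ((y - 2) / y) * ((y - 3) / y) * c123 +
          4 * p^2 * q^2 * ((x - 1) / x) * ((y - 1) / y) * c123,
    p11 = 2 * p^2 * q * ((x - 1) / x) * c12 +
          2 * p * q^2 * ((y - 1) / y) * c12,
    p21 = p^3 * ((x - 1) / x) * ((x - 2) / x) * c12 +
          q^3 * ((y - 1) / y) * ((y - 2) / y) * c12 +
          p^2 * q * ((x - 1) / x) * c12 +
          p * q^2 * ((y - 1) / y) * c12
  )
}

#' Method-of-moments IBD for one sample pair
#'
#' Observed identity-by-state (IBS) counts are combined with the expected
#' IBS-given-IBD probabilities (functions of cohort allele frequencies
#' with PLINK-style small-sample corrections) and solved sequentially for
#' the IBD-state probabilities Z0, Z1, Z2, which are then bounded to
#' [0, 1] and renormalized. `pihat = Z2 + Z1 / 2`.
#'
#' Loci missing in either sample or with cohort MAF < 0.01 are skipped;
#' pairs with fewer than 50 informative loci are flagged low-confidence.
#'
#' @param gA,gB integer genotype vectors ({-1, 0, 1, 2}) at the same loci.
#' @param freqs cohort alternate-allele frequency per locus.
#' @param n_alleles cohort called-allele count per locus (scalar or
#'   vector) used in the small-sample correction; default 200.
#' @return data.frame(z0, z1, z2, pihat, n_informative, low_confidence).
#' @export
ibd_mom <- function(gA, gB, freqs, n_alleles = 200) {
  stopifnot(length(gA) == length(gB), length(freqs) == length(gA))
  n_alleles <- rep_len(n_alleles, length(freqs))
  use <- gA >= 0L & gB >= 0L & pmin(freqs, 1 - freqs) >= 0.01 &
    n_alleles >= 4
  n_inf <- sum(use)
  if (n_inf == 0L)
    return(data.frame(z0 = NA_real_, z1 = NA_real_, z2 = NA_real_,
                      pihat = NA_real_, n_informative = 0L,
                      low_confidence = TRUE))
  a <- gA[use]; b <- gB[use]
  ibs <- 2L - abs(a - b)
  ibs[(a == 0L & b == 2L) | (a == 2L & b == 0L)] <- 0L
  obs <- tabulate(ibs + 1L, nbins = 3L)  # counts of IBS 0, 1, 2

  e <- ibs_given_ibd(freqs[use], n_alleles[use])
  E00 <- sum(e$p00); E10 <- sum(e$p10); E20 <- sum(e$p20)
  E11 <- sum(e$p11); E21 <- sum(e$p21)

  z0 <- obs[1] / E00
  z1 <- (obs[2] - z0 * E10) / E11
  z2 <- (obs[3] - z0 * E20 - z1 * E21) / n_inf
  # sequential bounding as in PLINK: an overshooting z0 (or z1) collapses
  # the remaining states before the triple is renormalized
  if (z0 > 1) { z0 <- 1; z1 <- 0; z2 <- 0 }
  if (z1 > 1) { z1 <- 1; z2 <- 0 }
  z <- pmin(pmax(c(z0, z1, z2), 0), 1)
  z <- z / sum(z)
  data.frame(z0 = z[1], z1 = z[2], z2 = z[3], pihat = z[3] + z[2] / 2,
             n_informative = n_inf, low_confidence = n_inf < 50L)
}

#' All-pairs IBD over a cohort
#'
#' Allele frequencies are estimated from the analyzed cohort itself.
#'
#' @param g a [genotype_matrix()] (typically restricted to the fingerprint
#'   loci).
#' @return data.frame with one row per unordered sample pair: `sample1`,
#'   `sample2`, the [ibd_mom()] fields and the relationship `class`.
#' @export
ibd_pairs <- function(g) {
  st <- site_stats(g)
  freqs <- st$p_alt
  n_alleles <- 2 * st$n_called
  n <- length(g$samples)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    est <- ibd_mom(g$calls[i, ], g$calls[j, ], freqs, n_alleles)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(sample1 = g$samples[i], sample2 = g$samples[j]), est)
  }
  out <- do.call(rbind, rows)
  out$class <- vapply(seq_len(nrow(out)), function(r)
    classify_relationship(out[r, ])$class, character(1))
  out
}

#' Classify a pairwise relationship from an IBD estimate
#'
#' Thresholds (all configurable) follow common practice for
#' method-of-moments IBD: `pihat >= 0.9` clone/bud-sport; `pihat` in
#' [0.4, 0.6] with `z0 <= 0.05` parent-offspring, with `z0 > 0.05` other
#' first-degree (e.g. full sib); `pihat` in [0.15, 0.4) related; else
#' unrelated.
#'
#' @param est one-row data.frame from [ibd_mom()].
#' @param clone_min,po_range,po_z0_max,related_min class thresholds.
#' @return list(class, pihat, z0, z1, z2, low_confidence).
#' @export
classify_relationship <- function(est, clone_min = 0.9,
                                  po_range = c(0.4, 0.6), po_z0_max = 0.05,
                                  related_min = 0.15) {
  ph <- est$pihat
  cls <- if (is.na(ph)) "unrelated"
    else if (ph >= clone_min) "clone_or_bud_sport"
    else if (ph >= po_range[1] && ph <= po_range[2])
      if (est$z0 <= po_z0_max) "parent_offspring" else "first_degree_other"
    else if (ph >= related_min) "related"
    else "unrelated"
  list(class = cls, pihat = ph, z0 = est$z0, z1 = est$z1, z2 = est$z2,
       low_confidence = isTRUE(est$low_confidence))
}

#' Clone / bud-sport groups from pairwise calls
#'
#' Connected components of the graph whose edges are clone-class pairs;
#' singleton samples are omitted.
#'
#' @param calls data.frame with `sample1`, `sample2`, `class` (e.g. from
#'   [ibd_pairs()]).
#' @return list of character vectors, one per group, ordered by
#'   decreasing size.
#' @export
clone_groups <- function(calls) {
  edges <- calls[calls$class == "clone_or_bud_sport", c("sample1", "sample2")]
  if (nrow(edges) == 0L) return(list())
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(gr)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  names(groups) <- NULL
  groups[order(-vapply(groups, length, integer(1)))]
}

#' Group samples by regional haplotype
#'
#' Samples sharing an identical ordered genotype-code string over the
#' region's sites receive one label; labels are ordered by descending
#' frequency (H001, H002, ...). Samples with any missing call in the
#' region are unassigned (NA).
#'
#' @param g a [genotype_matrix()].
#' @param chrom chromosome of the region.
#' @param start,end region bounds, 0-based half-open.
#' @param pops optional named sample -> population vector; adds a
#'   per-population frequency table.
#' @return list(labels: named character vector per sample, groups:
#'   data.frame(label, n, pattern), pop_freq: table or NULL).
#' @export
haplotype_groups <- function(g, chrom, start, end, pops = NULL) {
  sel <- g$sites$chrom == chrom & (g$sites$pos - 1L) >= start &
    (g$sites$pos - 1L) < end
  if (!any(sel)) stop("no sites in region")
  sub <- g$calls[, sel, drop = FALSE]
  complete <- rowSums(sub < 0L) == 0L
  pattern <- rep(NA_character_, nrow(sub))
  pattern[complete] <- apply(sub[complete, , drop = FALSE], 1, paste,
                             collapse = "")
  tab <- sort(table(pattern), decreasing = TRUE)
  lab <- setNames(sprintf("H%03d", seq_along(tab)), names(tab))
  labels <- setNames(unname(lab[pattern]), g$samples)
  groups <- data.frame(label = unname(lab), n = as.integer(tab),
                       pattern = names(tab), row.names = NULL)
  pop_freq <- NULL
  if (!is.null(pops))
    pop_freq <- table(population = pops[g$samples], haplotype = labels,
                      useNA = "no")
  list(labels = labels, groups = groups, pop_freq = pop_freq)
}
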