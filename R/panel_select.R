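# Uniformly spaced panel selection and panel characterization metrics.

#' Select a uniformly spaced panel from passing candidates
#'
#' Each chromosome is partitioned into consecutive non-overlapping windows
#' `[k * window, (k + 1) * window)` (0-based, anchored at position 0). In
#' each window the candidate with the highest `pic_chip` is chosen; ties
#' are broken by proximity to the window center, then by lowest position,
#' so selection is deterministic. Empty windows yield no site.
#'
#' @param candidates data.frame of candidate sites (all probe-passing),
#'   with at least `chrom`, `pos`, `pic_chip`; typically the
#'   `overall_pass` rows of a [probe_report()].
#' @param window window size in bp (default 100000).
#' @return a `snp_panel`: list(sites, window, selection_log) where
#'   `selection_log` records every candidate with its window and verdict.
#' @export
select_uniform <- function(candidates, window = 100000L) {
  stopifnot(window >= 1)
  if (is.null(candidates) || nrow(candidates) == 0L) {
    warning("no candidates; returning an empty panel")
    return(structure(list(sites = candidates, window = window,
                          selection_log = candidates),
                     class = "snp_panel"))
  }
  win_id <- (candidates$pos - 1L) %/% as.integer(window)
  center <- (win_id + 0.5) * window + 0.5   # back on 1-based coordinates
  key <- paste(candidates$chrom, win_id)
  ord <- order(key, -candidates$pic_chip, abs(candidates$pos - center),
               candidates$pos)
  chosen_idx <- ord[!duplicated(key[ord])]
  chosen <- sort(chosen_idx)
  log <- cbind(candidates[, c("chrom", "pos")],
               window_index = win_id,
               chosen = seq_len(nrow(candidates)) %in% chosen)
  sites <- candidates[chosen, , drop = FALSE]
  sites <- sites[order(match(sites$chrom, unique(candidates$chrom)),
                       sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites, window = window, selection_log = log),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel:", nrow(x$sites), "sites,",
      length(unique(x$sites$chrom)), "chromosome(s), window",
      x$window, "bp\n")
  invisible(x)
}

#' Panel characterization metrics
#'
#' Adjacent-site distances are computed within chromosomes only. The
#' count-versus-length relationship is summarized by a Pearson correlation
#' over (per-chromosome count, chromosome length) pairs with a two-sided
#' t-test p-value; with a single chromosome it is undefined and flagged.
#' Distance fractions use closed upper bounds (a threshold of 20000 means
#' distance <= 20 kb).
#'
#' @param panel a `snp_panel` or a site data.frame with `chrom`, `pos` and
#'   optionally `maf`, `pic_chip`.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param dist_thresholds distance thresholds (bp) for cumulative
#'   fractions.
#' @param maf_thresholds,pic_thresholds thresholds for `frac_maf_gt` /
#'   `frac_pic_gt` (strict >).
#' @return list of metrics (see fields in the return value).
#' @export
panel_metrics <- function(panel, chrom_lengths,
                          dist_thresholds = c(10000L, 20000L, 50000L),
                          maf_thresholds = c(0.4, 0.45),
                          pic_thresholds = c(0.45, 0.49)) {
  sites <- if (inherits(panel, "snp_panel")) panel$sites else panel
  if (is.null(sites) || nrow(sites) == 0L) stop("panel is empty")
  dists <- unlist(lapply(split(sites$pos, sites$chrom), function(p)
    if (length(p) > 1L) diff(sort(p)) else numeric(0)), use.names = FALSE)
  counts <- table(factor(sites$chrom, levels = names(chrom_lengths)))
  counts <- as.integer(counts)
  names(counts) <- names(chrom_lengths)

  if (length(chrom_lengths) >= 3L && var(counts) > 0) {
    ct <- cor.test(counts, as.numeric(chrom_lengths))
    r <- unname(ct$estimate); r_p <- ct$p.value; r_flag <- NA_character_
  } else if (length(chrom_lengths) == 2L && var(counts) > 0) {
    r <- unname(cor(counts, as.numeric(chrom_lengths)))
    r_p <- NA_real_; r_flag <- "p-value undefined with 2 chromosomes"
  } else {
    r <- NA_real_; r_p <- NA_real_
    r_flag <- "correlation undefined (single chromosome or constant counts)"
  }

  frac_le <- vapply(dist_thresholds, function(t)
    if (length(dists)) mean(dists <= t) else NA_real_, numeric(1))
  names(frac_le) <- paste0("le_", dist_thresholds)

  frac_gt <- function(x, thr) {
    if (is.null(x)) return(setNames(rep(NA_real_, length(thr)),
                                    paste0("gt_", thr)))
    setNames(vapply(thr, function(t) mean(x > t, na.rm = TRUE), numeric(1)),
             paste0("gt_", thr))
  }

  list(n_sites = nrow(sites),
       mean_adjacent_distance = if (length(dists)) mean(dists) else NA_real_,
       frac_distance_le = frac_le,
       per_chrom_counts = counts,
       count_length_r = r, count_length_p = r_p, count_length_flag = r_flag,
       frac_maf_gt = frac_gt(sites$maf, maf_thresholds),
       frac_pic_gt = frac_gt(sites$pic_chip, pic_thresholds))
}
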