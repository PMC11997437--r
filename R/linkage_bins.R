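# Parental cross-type classification, recombination bin maps from F1
# progeny, per-parent recombination maps and segregation-distortion scans.
#
# Pseudo-testcross convention: markers heterozygous in exactly one parent
# are recoded to that parent's transmitted allele; markers heterozygous in
# both parents are phase-ambiguous for origin and are used only in
# segregation tests.

#' Classify the parental cross type at each marker
#'
#' Only three configurations (up to allele relabeling) are informative:
#' hom x het (`AAxAB`, informative parent 2), het x het (`ABxAB`, both
#' informative for segregation), het x hom (`ABxBB`, informative parent
#' 1). Identical or opposite homozygotes, and any missing parental call,
#' are uninformative.
#'
#' @param gP1,gP2 integer parental call vectors ({-1, 0, 1, 2}).
#' @return data.frame(type, informative_parent); `informative_parent` is
#'   1, 2, 0 (= both) or NA.
#' @export
classify_cross <- function(gP1, gP2) {
  stopifnot(length(gP1) == length(gP2))
  type <- rep("uninformative", length(gP1))
  inf <- rep(NA_integer_, length(gP1))
  het1 <- gP1 == 1L
  het2 <- gP2 == 1L
  hom1 <- gP1 %in% c(0L, 2L)
  hom2 <- gP2 %in% c(0L, 2L)
  type[hom1 & het2] <- "AAxAB"; inf[hom1 & het2] <- 2L
  type[het1 & hom2] <- "ABxBB"; inf[het1 & hom2] <- 1L
  type[het1 & het2] <- "ABxAB"; inf[het1 & het2] <- 0L
  miss <- gP1 < 0L | gP2 < 0L
  type[miss] <- "uninformative"; inf[miss] <- NA_integer_
  data.frame(type = type, informative_parent = inf)
}

#' Recode progeny genotypes to parental origin at testcross markers
#'
#' For markers where `parent` is the (only) heterozygous parent, progeny
#' calls are recoded to the allele transmitted by that parent: 1 if it
#' transmitted the allele shared with the homozygous parent, 2 otherwise.
#' Progeny genotypes impossible under the cross (e.g. hom-alt from a
#' 0/0 x 0/1 cross) and missing calls become NA.
#'
#' Which allele the het parent transmitted is known per marker, but which
#' *haplotype* carried it is not: the linkage phase of the het parent's
#' markers is arbitrary. With `orient = TRUE` (default) each marker is
#' oriented against the preceding markers on its chromosome by progeny
#' majority vote, so origin codes are haplotype-consistent along the
#' chromosome (adjacent informative markers recombine in well under half
#' of the progeny, which makes the vote unambiguous at realistic marker
#' densities and family sizes).
#'
#' @param g a [genotype_matrix()] of the progeny.
#' @param gP1,gP2 parental call vectors aligned to `g`'s sites.
#' @param parent 1 or 2: which parent's markers to recode.
#' @param orient infer marker linkage phase by majority vote (default
#'   TRUE).
#' @return list(index: site indices used, origin: markers x progeny
#'   matrix of {1, 2, NA}, sites: the corresponding site table).
#' @export
recode_origin <- function(g, gP1, gP2, parent, orient = TRUE) {
  ct <- classify_cross(gP1, gP2)
  idx <- which(!is.na(ct$informative_parent) &
                 ct$informative_parent == parent)
  if (!length(idx)) stop("no testcross markers for parent ", parent)
  hom_code <- if (parent == 1L) gP2[idx] else gP1[idx]
  calls <- t(g$calls[, idx, drop = FALSE])      # markers x progeny
  origin <- matrix(NA_integer_, nrow(calls), ncol(calls))
  # hom_code is 0 or 2, so these assignments never collide; the opposite
  # homozygote is impossible under the cross and stays NA
  origin[calls == hom_code] <- 1L               # shared allele transmitted
  origin[calls == 1L] <- 2L                     # the het parent's other allele
  sites <- g$sites[idx, , drop = FALSE]
  if (orient) {
    for (ch in unique(sites$chrom)) {
      rows <- which(sites$chrom == ch)
      rows <- rows[order(sites$pos[rows])]
      prev <- origin[rows[1], ]
      for (r in rows[-1]) {
        v <- origin[r, ]
        both <- !is.na(prev) & !is.na(v)
        if (any(both) && mean(v[both] != prev[both]) > 0.5) {
          v <- 3L - v
          origin[r, ] <- v
        }
        prev <- ifelse(is.na(v), prev, v)
      }
    }
  }
  dimnames(origin) <- list(g$sites$id[idx], g$samples)
  list(index = idx, origin = origin, sites = sites)
}

#' Build recombination bins from origin-recoded markers
#'
#' Consecutive markers (genome order) are merged into one bin while their
#' progeny origin vectors are compatible, i.e. equal wherever both are
#' non-missing; an all-missing marker is compatible with anything and is
#' absorbed into the current bin. The bin boundary is placed between the
#' first two conflicting markers; bin start/end are the first/last member
#' marker positions. The bin pattern is the consensus origin vector
#' (missing values filled from later members).
#'
#' @param origin markers x progeny matrix of {1, 2, NA} from
#'   [recode_origin()].
#' @param sites site table aligned to `origin`'s rows (needs `chrom`,
#'   `pos`).
#' @return list(bins: data.frame(chrom, start, end, n_markers), pattern:
#'   bins x progeny matrix).
#' @export
build_bins <- function(origin, sites) {
  stopifnot(nrow(origin) == nrow(sites))
  bins <- list()
  patterns <- list()
  for (ch in unique(sites$chrom)) {
    rows <- which(sites$chrom == ch)
    rows <- rows[order(sites$pos[rows])]
    cur <- origin[rows[1], ]
    start <- sites$pos[rows[1]]
    last <- start
    n_mark <- 1L
    for (r in rows[-1]) {
      v <- origin[r, ]
      both <- !is.na(cur) & !is.na(v)
      if (any(cur[both] != v[both])) {
        bins[[length(bins) + 1L]] <-
          data.frame(chrom = ch, start = start, end = last,
                     n_markers = n_mark)
        patterns[[length(patterns) + 1L]] <- cur
        cur <- v
        start <- sites$pos[r]
        n_mark <- 0L
      } else {
        fill <- is.na(cur) & !is.na(v)
        cur[fill] <- v[fill]
      }
      last <- sites$pos[r]
      n_mark <- n_mark + 1L
    }
    bins[[length(bins) + 1L]] <-
      data.frame(chrom = ch, start = start, end = last, n_markers = n_mark)
    patterns[[length(patterns) + 1L]] <- cur
  }
  list(bins = do.call(rbind, bins), pattern = do.call(rbind, patterns))
}

#' Per-parent recombination map from a bin map
#'
#' Crossovers are transitions between adjacent bins' origin calls per
#' progeny. With `smooth = TRUE` (default) an isolated bin whose call
#' differs from two agreeing flanking bins is treated as a genotyping
#' error and flipped before counting (a double transition within a 3-bin
#' span); with `smooth = FALSE` such spans are kept and flagged.
#'
#' @param binmap list from [build_bins()].
#' @param smooth logical; smooth isolated double-recombinant bins.
#' @return list(breakpoints: data.frame(progeny, chrom, interval_start,
#'   interval_end), counts: crossovers per progeny, interval_counts:
#'   crossovers per inter-bin interval, n_flagged: smoothed/flagged
#'   double-transition bins).
#' @export
recombination_map <- function(binmap, smooth = TRUE) {
  bins <- binmap$bins
  pat <- binmap$pattern
  progeny <- colnames(pat)
  if (is.null(progeny)) progeny <- paste0("progeny", seq_len(ncol(pat)))
  bp <- list()
  n_flagged <- 0L
  counts <- setNames(integer(ncol(pat)), progeny)
  ic_key <- character(0)

  for (ch in unique(bins$chrom)) {
    rows <- which(bins$chrom == ch)
    if (length(rows) < 2L) next
    sub <- pat[rows, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      x <- sub[, j]
      obs <- which(!is.na(x))
      if (length(obs) < 2L) next
      v <- x[obs]
      if (length(v) >= 3L) {
        iso <- which(v[-c(1, length(v))] != v[-c(length(v) - 1, length(v))] &
                       v[-c(1, 2)] == v[-c(length(v) - 1, length(v))]) + 1L
        n_flagged <- n_flagged + length(iso)
        if (smooth && length(iso)) v[iso] <- v[iso - 1L]
      }
      tr <- which(diff(v) != 0L)
      counts[j] <- counts[j] + length(tr)
      for (t in tr) {
        b_lo <- rows[obs[t]]
        b_hi <- rows[obs[t + 1L]]
        bp[[length(bp) + 1L]] <-
          data.frame(progeny = progeny[j], chrom = ch,
                     interval_start = bins$end[b_lo],
                     interval_end = bins$start[b_hi])
        ic_key <- c(ic_key, paste(ch, bins$end[b_lo], bins$start[b_hi]))
      }
    }
  }
  breakpoints <- if (length(bp)) do.call(rbind, bp) else
    data.frame(progeny = character(), chrom = character(),
               interval_start = integer(), interval_end = integer())
  list(breakpoints = breakpoints, counts = counts,
       interval_counts = if (length(ic_key)) table(ic_key) else table(character(0)),
       n_flagged = n_flagged)
}

#' Segregation test at one marker
#'
#' Pearson chi-square of progeny genotype classes against the Mendelian
#' expectation: 1:1 over the two possible classes for a testcross marker
#' (`AAxAB` / `ABxBB`; df = 1), 1:2:1 over hom-ref/het/hom-alt for an
#' intercross marker (`ABxAB`; df = 2). Progeny genotypes impossible
#' under the cross are excluded.
#'
#' @param progeny_calls integer calls ({-1, 0, 1, 2}) at the marker.
#' @param type cross type string from [classify_cross()].
#' @param hom_code for testcross markers, the homozygous parent's call (0
#'   or 2); defaults to 0.
#' @param min_called minimum called progeny (default 20).
#' @return data.frame(chisq, df, p, n_used).
#' @export
segregation_test <- function(progeny_calls, type, hom_code = 0L,
                             min_called = 20L) {
  x <- progeny_calls[progeny_calls >= 0L]
  if (type == "ABxAB") {
    obs <- c(sum(x == 0L), sum(x == 1L), sum(x == 2L))
    expp <- c(0.25, 0.5, 0.25)
    df <- 2L
  } else if (type %in% c("AAxAB", "ABxBB")) {
    obs <- c(sum(x == hom_code), sum(x == 1L))
    expp <- c(0.5, 0.5)
    df <- 1L
  } else {
    return(data.frame(chisq = NA_real_, df = NA_integer_, p = NA_real_,
                      n_used = length(x)))
  }
  n <- sum(obs)
  if (n < min_called)
    return(data.frame(chisq = NA_real_, df = df, p = NA_real_, n_used = n))
  e <- n * expp
  chisq <- sum((obs - e)^2 / e)
  data.frame(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE),
             n_used = n)
}

#' Genome-wide segregation-distortion scan
#'
#' Runs [segregation_test()] at every informative marker.
#'
#' @param g progeny [genotype_matrix()].
#' @param gP1,gP2 parental call vectors aligned to `g`'s sites.
#' @param min_called minimum called progeny per marker.
#' @return data.frame per informative marker: chrom, pos, type, chisq, df,
#'   p, n_used.
#' @export
segregation_scan <- function(g, gP1, gP2, min_called = 20L) {
  ct <- classify_cross(gP1, gP2)
  idx <- which(ct$type != "uninformative")
  rows <- lapply(idx, function(i) {
    hom <- if (ct$type[i] == "AAxAB") gP1[i] else if (ct$type[i] == "ABxBB")
      gP2[i] else 0L
    cbind(g$sites[i, c("chrom", "pos", "id")],
          type = ct$type[i],
          segregation_test(g$calls[, i], ct$type[i], hom_code = hom,
                           min_called = min_called))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge significant markers into segregation-distortion regions
#'
#' The significance threshold is Bonferroni-corrected
#' (`alpha / n_markers` over markers with a defined p-value); runs of at
#' least `min_run` consecutive significant markers on a chromosome are
#' merged into regions whose bounds are the flanking marker positions.
#'
#' @param scan data.frame from [segregation_scan()].
#' @param alpha family-wise error rate (default 0.05).
#' @param min_run minimum run length (default 3).
#' @return data.frame(chrom, start, end, n_markers, min_p).
#' @export
distortion_regions <- function(scan, alpha = 0.05, min_run = 3L) {
  ok <- !is.na(scan$p)
  n_tests <- sum(ok)
  if (n_tests == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_markers = integer(),
                      min_p = numeric()))
  thr <- alpha / n_tests
  out <- list()
  for (ch in unique(scan$chrom)) {
    sub <- scan[scan$chrom == ch & ok, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    sig <- sub$p < thr
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      i <- starts[k]:ends[k]
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start = sub$pos[i[1]],
                   end = sub$pos[i[length(i)]], n_markers = length(i),
                   min_p = min(sub$p[i]))
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_markers = integer(),
                      min_p = numeric()))
  do.call(rbind, out)
}
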