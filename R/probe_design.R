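# Probe-flank GC and genome-wide specificity screening.
#
# A candidate's two capture flanks must (i) have GC inside a closed band
# and (ii) have fewer than `max_hits` homologous regions elsewhere in the
# genome under three ungapped similarity rules, all with strict ("more
# than") thresholds:
#   IDENTICAL_GT40  - an identical stretch of more than 40 bp,
#   SIM85_OVER80    - more than 85% identity over an 80 bp window,
#   SIM95_OVER70    - more than 95% identity over a 70 bp window.

RULE_NAMES <- c("IDENTICAL_GT40", "SIM85_OVER80", "SIM95_OVER70")

dna_to_int <- function(seq) {
  x <- utf8ToInt(toupper(seq))
  out <- integer(length(x))
  out[x == 65L] <- 1L  # A
  out[x == 67L] <- 2L  # C
  out[x == 71L] <- 3L  # G
  out[x == 84L] <- 4L  # T
  out
}

#' GC fraction of a DNA sequence
#'
#' `(#G + #C) / length`; ambiguous bases (N) count in the denominator only.
#'
#' @param seq character vector of DNA strings.
#' @return numeric vector of GC fractions.
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence")
  s <- toupper(seq)
  nchar(gsub("[^GC]", "", s)) / nchar(s)
}

#' The three homology rules
#'
#' Match-count thresholds are precomputed so that the printed "more than"
#' inequalities stay strict: an exact 40-bp stretch does not trigger the
#' first rule, and 68/80 = 85.0% does not trigger the second.
#'
#' @return list with `min_run` (exact-identity rule) and a data.frame of
#'   window rules (`len`, `min_match`).
#' @export
homology_rules <- function() {
  win <- data.frame(name = RULE_NAMES[2:3], len = c(80L, 70L),
                    frac = c(0.85, 0.95))
  win$min_match <- as.integer(floor(win$frac * win$len)) + 1L
  list(min_run = 40L, windows = win)
}

#' Precompute the integer-encoded genome for homology scanning
#'
#' @param ref `DNAStringSet` reference genome.
#' @return opaque index object accepted by [count_homologous_regions()].
#' @export
build_homology_index <- function(ref) {
  idx <- lapply(seq_along(ref), function(i) {
    fwd <- dna_to_int(as.character(ref[[i]]))
    rev_seq <- as.character(Biostrings::reverseComplement(ref[[i]]))
    list(fwd = fwd, rev = dna_to_int(rev_seq), len = length(fwd))
  })
  names(idx) <- names(ref)
  structure(idx, class = "homology_index")
}

merge_hit_intervals <- function(hits, gap = 10L) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  out <- list()
  cur <- hits[1, ]
  for (i in seq_len(nrow(hits))[-1]) {
    h <- hits[i, ]
    if (h$start <= cur$end + gap) {
      cur$end <- max(cur$end, h$end)
      if (h$identity > cur$identity) {
        cur$identity <- h$identity
        cur$rule <- h$rule
      }
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- h
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

#' Count homologous regions of a probe sequence across a genome
#'
#' Every ungapped alignment of the probe against both strands of every
#' chromosome is evaluated against the three rules (see
#' [homology_rules()]); qualifying alignments are reduced to maximal
#' genomic intervals, intervals closer than `merge_gap` bp are merged into
#' one region, and regions overlapping the probe's own source locus are
#' excluded.
#'
#' @param probe DNA string (a capture flank).
#' @param ref `DNAStringSet` or a [build_homology_index()] object.
#' @param self_chrom,self_start,self_end optional source locus of the probe
#'   (1-based inclusive); overlapping regions are dropped.
#' @param merge_gap regions closer than this many bp are counted as one
#'   (default 10).
#' @return data.frame(chrom, start, end, strand, rule, identity), one row
#'   per homologous region.
#' @export
count_homologous_regions <- function(probe, ref, self_chrom = NULL,
                                     self_start = NULL, self_end = NULL,
                                     merge_gap = 10L) {
  rules <- homology_rules()
  if (nchar(probe) < min(rules$windows$len))
    warning("probe shorter than ", min(rules$windows$len),
            " bp; longer-window rules skipped")
  if (nchar(probe) <= rules$min_run)
    warning("probe shorter than ", rules$min_run + 1L,
            " bp; exact-identity rule cannot trigger")
  idx <- if (inherits(ref, "homology_index")) ref else build_homology_index(ref)
  p_int <- dna_to_int(probe)

  per_chrom <- lapply(names(idx), function(ch) {
    g <- idx[[ch]]
    fwd <- homology_scan_strand(p_int, g$fwd, rules$min_run,
                                rules$windows$len, rules$windows$min_match)
    rev <- homology_scan_strand(p_int, g$rev, rules$min_run,
                                rules$windows$len, rules$windows$min_match)
    rows <- list()
    if (nrow(fwd))
      rows$f <- data.frame(chrom = ch, start = fwd[, "start"],
                           end = fwd[, "end"], strand = "+",
                           rule = c("IDENTICAL_GT40", RULE_NAMES[2:3])[fwd[, "rule"] + 1L],
                           identity = fwd[, "matches"] / fwd[, "span"])
    if (nrow(rev))
      rows$r <- data.frame(chrom = ch, start = g$len - rev[, "end"] + 1L,
                           end = g$len - rev[, "start"] + 1L, strand = "-",
                           rule = c("IDENTICAL_GT40", RULE_NAMES[2:3])[rev[, "rule"] + 1L],
                           identity = rev[, "matches"] / rev[, "span"])
    hits <- do.call(rbind, rows)
    if (is.null(hits) || nrow(hits) == 0L) return(NULL)
    merged <- merge_hit_intervals(hits, gap = merge_gap)
    if (!is.null(self_chrom) && ch == self_chrom)
      merged <- merged[!(merged$start <= self_end &
                           merged$end >= self_start), , drop = FALSE]
    merged
  })
  out <- do.call(rbind, per_chrom)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      rule = character(), identity = numeric())
  rownames(out) <- NULL
  out
}

#' Evaluate one candidate SNP's capture probes
#'
#' Both flanks (left and right, each `flank_len` bp) are evaluated
#' independently: `gc_pass` requires both flank GC fractions inside the
#' closed `gc_band`; the homology hit count is the number of merged
#' regions pooled over both flanks (each flank's search excludes the whole
#' probe span around the SNP); `specificity_pass` requires strictly fewer
#' than `max_hits` regions. Flanks truncated at a contig end fail
#' automatically. `mode = "centered"` instead evaluates a single
#' `flank_len`-bp window containing the SNP.
#'
#' @param ref `DNAStringSet` or [build_homology_index()] object.
#' @param chrom,pos site coordinate.
#' @param flank_len flank length in bp (default 110).
#' @param gc_band closed GC interval, default `c(0.3, 0.7)`.
#' @param max_hits specificity threshold: pass iff hit count `< max_hits`
#'   (default 5).
#' @param mode `"flanks"` (default) or `"centered"`.
#' @param genome optional raw `DNAStringSet` when `ref` is an index (needed
#'   to extract flank sequences); ignored otherwise.
#' @return one-row data.frame: `chrom, pos, left_gc, right_gc, gc_pass,
#'   hit_count, specificity_pass, truncated, overall_pass`.
#' @export
evaluate_probe <- function(ref, chrom, pos, flank_len = 110L,
                           gc_band = c(0.3, 0.7), max_hits = 5L,
                           mode = c("flanks", "centered"), genome = NULL) {
  mode <- match.arg(mode)
  seqs <- if (inherits(ref, "homology_index")) {
    if (is.null(genome)) stop("supply `genome` when `ref` is an index")
    genome
  } else ref
  idx <- ref  # count_homologous_regions accepts either form

  if (mode == "centered") {
    half <- flank_len %/% 2L
    len <- ref_lengths(seqs)[[chrom]]
    s <- pos - half
    e <- s + flank_len - 1L
    truncated <- s < 1L || e > len
    s <- max(1L, s); e <- min(len, e)
    win <- as.character(Biostrings::subseq(seqs[[chrom]], s, e))
    gl <- gr <- gc_content(win)
    probes <- list(win)
  } else {
    fl <- fetch_flank(seqs, chrom, pos, flank_len)
    truncated <- fl$truncated_left || fl$truncated_right
    gl <- if (nzchar(fl$left)) gc_content(fl$left) else NA_real_
    gr <- if (nzchar(fl$right)) gc_content(fl$right) else NA_real_
    probes <- Filter(nzchar, list(fl$left, fl$right))
  }

  gc_pass <- !truncated && !is.na(gl) && !is.na(gr) &&
    gl >= gc_band[1] && gl <= gc_band[2] &&
    gr >= gc_band[1] && gr <= gc_band[2]

  self_s <- max(1L, pos - flank_len)
  self_e <- pos + flank_len
  hits <- do.call(rbind, lapply(probes, count_homologous_regions,
                                ref = idx, self_chrom = chrom,
                                self_start = self_s, self_end = self_e))
  # pool the two flanks' regions, de-duplicating overlaps per chromosome
  hit_count <- if (is.null(hits) || nrow(hits) == 0L) 0L else {
    sum(vapply(split(hits, hits$chrom),
               function(h) nrow(merge_hit_intervals(h, gap = 10L)),
               integer(1)))
  }

  specificity_pass <- !truncated && hit_count < max_hits
  data.frame(chrom = chrom, pos = pos, left_gc = gl, right_gc = gr,
             gc_pass = gc_pass, hit_count = hit_count,
             specificity_pass = specificity_pass, truncated = truncated,
             overall_pass = gc_pass && specificity_pass)
}

#' Probe report for a set of candidate sites
#'
#' Vectorized wrapper around [evaluate_probe()]; the genome is
#' integer-encoded once.
#'
#' @param sites data.frame with `chrom`, `pos` (e.g. QC-passing rows of a
#'   [site_stats()] table; extra columns are carried through).
#' @param ref `DNAStringSet` reference genome.
#' @inheritParams evaluate_probe
#' @return data.frame: input columns plus the [evaluate_probe()] verdicts.
#' @export
probe_report <- function(sites, ref, flank_len = 110L,
                         gc_band = c(0.3, 0.7), max_hits = 5L,
                         mode = "flanks") {
  idx <- build_homology_index(ref)
  rows <- lapply(seq_len(nrow(sites)), function(i)
    evaluate_probe(idx, sites$chrom[i], sites$pos[i], flank_len = flank_len,
                   gc_band = gc_band, max_hits = max_hits, mode = mode,
                   genome = ref))
  verdicts <- do.call(rbind, rows)
  cbind(sites, verdicts[, setdiff(names(verdicts), c("chrom", "pos")),
                        drop = FALSE])
}
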