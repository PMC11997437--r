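# Deterministic, seeded generators for genomes, structured populations,
# F1 crosses and kinship pairs, so every analysis is testable without
# external cohorts. All generators are bit-reproducible given (seed,
# arguments).

#' Simulate a reference genome with optional planted repeats
#'
#' Bases are drawn iid at the requested GC fraction. Each planted repeat
#' copies a source interval to random positions (optionally on the minus
#' strand) with exactly the configured number of mismatched bases; every
#' planted copy is recorded in a truth table.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp),
#'   each at least 10 kb unless `min_length` is lowered.
#' @param gc genome GC fraction (default 0.5).
#' @param repeats optional data.frame(chrom, start, end, n_copies,
#'   mismatches) describing source intervals to plant; an optional
#'   `strand` column ("+"/"-"/"random") controls copy orientation.
#' @param seed integer seed.
#' @param min_length minimum chromosome length (default 10000).
#' @return list(ref: `DNAStringSet`, truth: data.frame of planted copies).
#' @export
simulate_genome <- function(chrom_lengths, gc = 0.5, repeats = NULL,
                            seed = 1L, min_length = 10000L) {
  stopifnot(all(chrom_lengths >= min_length), gc > 0, gc < 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- lapply(chrom_lengths, function(len)
    sample(bases, len, replace = TRUE, prob = prob))
  names(seqs) <- names(chrom_lengths)

  truth <- data.frame(copy_id = integer(), src_chrom = character(),
                      src_start = integer(), src_end = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer())
  if (!is.null(repeats)) {
    cid <- 0L
    for (r in seq_len(nrow(repeats))) {
      src <- seqs[[repeats$chrom[r]]][repeats$start[r]:repeats$end[r]]
      L <- length(src)
      strand_mode <- if ("strand" %in% names(repeats))
        repeats$strand[r] else "+"
      for (k in seq_len(repeats$n_copies[r])) {
        dest_ch <- sample(names(seqs), 1L)
        # avoid planting across the source interval itself
        repeat {
          s <- sample.int(length(seqs[[dest_ch]]) - L + 1L, 1L)
          if (!(dest_ch == repeats$chrom[r] &&
                s <= repeats$end[r] && s + L - 1L >= repeats$start[r]))
            break
        }
        strand <- switch(strand_mode,
                         "random" = sample(c("+", "-"), 1L),
                         strand_mode)
        copy <- src
        m <- repeats$mismatches[r]
        if (m > 0L) {
          at <- sample.int(L, m)
          for (i in at)
            copy[i] <- sample(setdiff(bases, copy[i]), 1L)
        }
        if (strand == "-")
          copy <- rev(chartr("ACGT", "TGCA", copy))
        seqs[[dest_ch]][s:(s + L - 1L)] <- copy
        cid <- cid + 1L
        truth <- rbind(truth, data.frame(
          copy_id = cid, src_chrom = repeats$chrom[r],
          src_start = repeats$start[r], src_end = repeats$end[r],
          chrom = dest_ch, start = s, end = s + L - 1L,
          strand = strand, mismatches = m))
      }
    }
  }
  ref <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                         collapse = ""))
  list(ref = ref, truth = truth)
}

#' Simulate a structured population under the Balding-Nichols model
#'
#' Per SNP, an ancestral frequency is drawn uniformly on
#' `[maf_floor, 1 - maf_floor]`; each population's frequency is drawn from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` (for `F = 0` the ancestral
#' frequency is used directly), and genotypes are Hardy-Weinberg within
#' populations. `F` is the expected genome-wide Fst between populations.
#' Positions are uniform without collision, allocated to chromosomes
#' proportionally to length.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param n_pops number of populations (default 2).
#' @param samples_per_pop diploid samples per population (default 50).
#' @param n_snps total SNP count (default 2000).
#' @param F divergence parameter in [0, 1) (default 0.1).
#' @param maf_floor lower bound on ancestral MAF (default 0.05).
#' @param missing_rate fraction of calls masked missing (default 0).
#' @param seed integer seed.
#' @param genome optional `DNAStringSet`; if given, REF alleles are taken
#'   from the genome sequence (N positions are re-drawn).
#' @return list(geno: [genotype_matrix()], pops: named sample ->
#'   population vector, truth: data.frame(chrom, pos, p_anc and per-pop
#'   frequencies), F = F).
#' @export
simulate_population <- function(chrom_lengths, n_pops = 2L,
                                samples_per_pop = 50L, n_snps = 2000L,
                                F = 0.1, maf_floor = 0.05,
                                missing_rate = 0, seed = 1L,
                                genome = NULL) {
  stopifnot(F >= 0, F < 1, maf_floor >= 0, maf_floor < 0.5,
            missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")

  chrom_lengths <- vapply(chrom_lengths, as.numeric, numeric(1))
  n_per_chrom <- round(n_snps * chrom_lengths / sum(chrom_lengths))
  n_per_chrom[1] <- n_per_chrom[1] + n_snps - sum(n_per_chrom)
  if (any(n_per_chrom > chrom_lengths)) stop("SNP density infeasible")
  sites <- do.call(rbind, lapply(seq_along(chrom_lengths), function(i)
    data.frame(chrom = names(chrom_lengths)[i],
               pos = sort(sample.int(chrom_lengths[[i]], n_per_chrom[i])))))

  ref <- sample(bases, n_snps, replace = TRUE)
  if (!is.null(genome)) {
    for (i in seq_len(n_snps)) {
      b <- as.character(Biostrings::subseq(genome[[sites$chrom[i]]],
                                           sites$pos[i], sites$pos[i]))
      if (b %in% bases) ref[i] <- b
    }
  }
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

  p_anc <- runif(n_snps, maf_floor, 1 - maf_floor)
  pop_names <- paste0("pop", seq_len(n_pops))
  p_pop <- vapply(pop_names, function(p) {
    if (F == 0) p_anc else
      rbeta(n_snps, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }, numeric(n_snps))

  samples <- unlist(lapply(pop_names, function(p)
    sprintf("%s_s%03d", p, seq_len(samples_per_pop))))
  pops <- setNames(rep(pop_names, each = samples_per_pop), samples)
  calls <- matrix(0L, nrow = length(samples), ncol = n_snps)
  for (j in seq_len(n_pops)) {
    rows <- which(pops == pop_names[j])
    calls[rows, ] <- matrix(
      rbinom(length(rows) * n_snps, 2L,
             rep(p_pop[, j], each = length(rows))),
      nrow = length(rows))
  }
  if (missing_rate > 0) {
    mask <- matrix(runif(length(calls)) < missing_rate, nrow = nrow(calls))
    calls[mask] <- -1L
  }
  sites$ref <- ref
  sites$alt <- alt
  g <- genotype_matrix(samples, sites, calls)
  truth <- cbind(sites[, c("chrom", "pos")], p_anc = p_anc, p_pop)
  list(geno = g, pops = pops, truth = truth, F = F)
}

# random phased parental haplotypes realizing a mixture of cross types at
# the given markers; returns 2 x M allele matrices (0 = ref, 1 = alt)
make_f1_parents <- function(n_markers, cross_props) {
  type <- sample(names(cross_props), n_markers, replace = TRUE,
                 prob = cross_props)
  hap1 <- matrix(0L, 2, n_markers)  # parent 1
  hap2 <- matrix(0L, 2, n_markers)  # parent 2
  for (i in seq_len(n_markers)) {
    het_phase <- sample(c(0L, 1L), 1L)
    switch(type[i],
      AAxAB = {
        hom <- sample(c(0L, 1L), 1L)            # allele relabeling
        hap1[, i] <- hom
        hap2[, i] <- c(het_phase, 1L - het_phase)
      },
      ABxBB = {
        hom <- sample(c(0L, 1L), 1L)
        hap1[, i] <- c(het_phase, 1L - het_phase)
        hap2[, i] <- hom
      },
      ABxAB = {
        hap1[, i] <- c(het_phase, 1L - het_phase)
        ph2 <- sample(c(0L, 1L), 1L)
        hap2[, i] <- c(ph2, 1L - ph2)
      })
  }
  list(hap1 = hap1, hap2 = hap2, type = type)
}

#' Simulate an F1 biparental cross
#'
#' Marker positions are uniform over each chromosome; parental phased
#' haplotypes realize the requested mixture of cross types. Per gamete
#' and chromosome, the crossover count is Poisson with mean
#' `map_length_cM / 100` and crossover positions are uniform (no
#' interference). Genotyping errors replace a call with a different
#' random code at the stated rate; missing calls are masked at the stated
#' rate. Every crossover is recorded in a truth table.
#'
#' The defaults emulate a published litchi biparental design: 264
#' progeny; 53.6% of informative markers heterozygous only in parent 2,
#' the remainder split evenly; per-chromosome map lengths of 90 cM
#' (female, parent 1) and 70 cM (male, parent 2).
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param n_markers total marker count (default 1000).
#' @param n_progeny number of F1 progeny (default 264).
#' @param cross_props named proportions over c("AAxAB", "ABxAB", "ABxBB")
#'   (AAxAB = het only in parent 2).
#' @param map_length_cM named vector c(P1 = , P2 = ): per-chromosome map
#'   length per parent.
#' @param genotyping_error per-call error rate (default 0).
#' @param missing_rate per-call missing rate (default 0).
#' @param seed integer seed.
#' @return list(geno: progeny [genotype_matrix()], gP1, gP2: parental call
#'   vectors, haplotypes: the phased parental alleles, truth: data.frame of
#'   crossovers (progeny, parent, chrom, pos), markers: site table).
#' @export
simulate_f1 <- function(chrom_lengths, n_markers = 1000L, n_progeny = 264L,
                        cross_props = c(AAxAB = 0.536, ABxAB = 0.232,
                                        ABxBB = 0.232),
                        map_length_cM = c(P1 = 90, P2 = 70),
                        genotyping_error = 0, missing_rate = 0,
                        seed = 1L) {
  stopifnot(genotyping_error >= 0, genotyping_error < 1,
            missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chrom_lengths <- vapply(chrom_lengths, as.numeric, numeric(1))
  n_per_chrom <- round(n_markers * chrom_lengths / sum(chrom_lengths))
  n_per_chrom[1] <- n_per_chrom[1] + n_markers - sum(n_per_chrom)
  markers <- do.call(rbind, lapply(seq_along(chrom_lengths), function(i)
    data.frame(chrom = names(chrom_lengths)[i],
               pos = sort(sample.int(chrom_lengths[[i]], n_per_chrom[i])))))
  markers$ref <- sample(bases, n_markers, replace = TRUE)
  markers$alt <- vapply(markers$ref, function(b)
    sample(setdiff(bases, b), 1L), character(1))

  par <- make_f1_parents(n_markers, cross_props)
  gP1 <- colSums(par$hap1)
  gP2 <- colSums(par$hap2)

  chrom_of <- markers$chrom
  gamete <- function(hap, parent_label, progeny_label, truth_acc) {
    allele <- integer(n_markers)
    for (ch in names(chrom_lengths)) {
      idx <- which(chrom_of == ch)
      n_co <- rpois(1L, map_length_cM[[parent_label]] / 100)
      co <- sort(runif(n_co, 1, chrom_lengths[[ch]]))
      cur <- sample(c(1L, 2L), 1L)
      phase <- cur + cumsum(c(0L, rep(1L, n_co)))  # hap index after each co
      seg <- findInterval(markers$pos[idx], co) + 1L
      hap_idx <- 1L + (phase[seg] - 1L) %% 2L
      allele[idx] <- hap[cbind(hap_idx, idx)]
      if (n_co > 0)
        truth_acc[[length(truth_acc) + 1L]] <-
          data.frame(progeny = progeny_label, parent = parent_label,
                     chrom = ch, pos = co)
    }
    list(allele = allele, truth = truth_acc)
  }

  samples <- sprintf("F1_%03d", seq_len(n_progeny))
  calls <- matrix(0L, n_progeny, n_markers)
  truth <- list()
  for (s in seq_len(n_progeny)) {
    gm <- gamete(par$hap1, "P1", samples[s], truth)
    truth <- gm$truth
    gp <- gamete(par$hap2, "P2", samples[s], truth)
    truth <- gp$truth
    calls[s, ] <- gm$allele + gp$allele
  }
  if (genotyping_error > 0) {
    err <- which(matrix(runif(length(calls)) < genotyping_error,
                        nrow = nrow(calls)))
    for (i in err)
      calls[i] <- sample(setdiff(0:2, calls[i]), 1L)
  }
  if (missing_rate > 0)
    calls[matrix(runif(length(calls)) < missing_rate,
                 nrow = nrow(calls))] <- -1L

  g <- genotype_matrix(samples, markers, calls)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(progeny = character(), parent = character(),
               chrom = character(), pos = numeric())
  list(geno = g, gP1 = as.integer(gP1), gP2 = as.integer(gP2),
       haplotypes = par, truth = truth, markers = markers)
}

#' Simulate genotype pairs of known kinship (gene drop)
#'
#' Locus frequencies are uniform on `maf_range`; founders are
#' Hardy-Weinberg draws. Classes: `clone` (an identical copy),
#' `parent_offspring` (one allele transmitted per locus),
#' `full_sib` (two offspring of the same two founders), `unrelated`.
#'
#' @param n_pairs pairs per class.
#' @param n_loci loci per pair (default 384).
#' @param maf_range allele-frequency range (default c(0.35, 0.5)).
#' @param classes character vector of classes to simulate.
#' @param seed integer seed.
#' @return list(pairs: list of (gA, gB, class), freqs: per-locus allele
#'   frequencies).
#' @export
simulate_kinship_pairs <- function(n_pairs = 200L, n_loci = 384L,
                                   maf_range = c(0.35, 0.5),
                                   classes = c("clone", "parent_offspring",
                                               "full_sib", "unrelated"),
                                   seed = 1L) {
  set.seed(seed)
  freqs <- runif(n_loci, maf_range[1], maf_range[2])
  draw <- function() rbinom(n_loci, 2L, freqs)
  mate <- function(gm, gf) {
    # transmit one allele from each parent per locus
    tm <- ifelse(gm == 1L, sample(0:1, n_loci, replace = TRUE), gm / 2L)
    tf <- ifelse(gf == 1L, sample(0:1, n_loci, replace = TRUE), gf / 2L)
    as.integer(tm + tf)
  }
  pairs <- list()
  for (cl in classes) for (i in seq_len(n_pairs)) {
    if (cl == "clone") {
      gA <- draw(); gB <- gA
    } else if (cl == "parent_offspring") {
      gA <- draw(); other <- draw(); gB <- mate(gA, other)
    } else if (cl == "full_sib") {
      m <- draw(); f <- draw(); gA <- mate(m, f); gB <- mate(m, f)
    } else {
      gA <- draw(); gB <- draw()
    }
    pairs[[length(pairs) + 1L]] <- list(gA = gA, gB = gB, class = cl)
  }
  list(pairs = pairs, freqs = freqs)
}
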