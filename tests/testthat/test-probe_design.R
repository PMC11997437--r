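test_that("gc_content counts G+C over full length, N in denominator only", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AAAA"), 0.0)
  expect_equal(gc_content("ATGN"), 0.25)
  expect_equal(gc_content(c("GGGG", "acgt")), c(1, 0.5))
  expect_error(gc_content(""), "empty")
  # a 110-bp flank with exactly 33 G/C sits on the inclusive 0.3 boundary
  s <- paste(c(rep("G", 33), rep("A", 77)), collapse = "")
  expect_equal(gc_content(s), 0.3)
})

# build a genome string with `insert` planted at a known offset; the
# genome bases flanking the insert are forced to differ from the probe
# bases adjacent to the copied window, so exact runs cannot extend
plant <- function(backbone, insert, at, avoid_pre, avoid_post) {
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  pre <- substr(backbone, 1, at - 2)
  post <- substr(backbone, at + nchar(insert) + 1, nchar(backbone))
  paste0(pre, other(avoid_pre), insert, other(avoid_post), post)
}

test_that("exact-identity rule is strict: 41 bp triggers, 40 bp does not", {
  set.seed(101)
  probe <- rand_dna(110)
  backbone <- rand_dna(8000)
  for (L in c(40L, 41L)) {
    gseq <- plant(backbone, substr(probe, 30, 29 + L), 4000,
                  substr(probe, 29, 29), substr(probe, 30 + L, 30 + L))
    ref <- Biostrings::DNAStringSet(c(chr1 = gseq))
    hits <- count_homologous_regions(probe, ref)
    ora <- oracle_homology_regions(probe, ref)
    expect_equal(nrow(hits), nrow(ora))
    if (L == 41L) expect_equal(nrow(hits), 1L) else expect_equal(nrow(hits), 0L)
  }
})

test_that("85%-over-80bp rule is strict at the 68/80 boundary", {
  set.seed(202)
  probe <- rand_dna(110)
  backbone <- rand_dna(8000)
  mutate <- function(seq, n_mm) {
    # evenly spaced mismatches keep exact runs short and 70-bp windows dirty
    at <- round(seq(4, nchar(seq) - 3, length.out = n_mm))
    s <- strsplit(seq, "")[[1]]
    s[at] <- chartr("ACGT", "CATC", s[at])
    paste(s, collapse = "")
  }
  copy <- substr(probe, 16, 95)                       # 80 bp
  for (n_mm in c(11L, 12L)) {                         # 69/80 vs 68/80
    gseq <- plant(backbone, mutate(copy, n_mm), 4000,
                  substr(probe, 15, 15), substr(probe, 96, 96))
    ref <- Biostrings::DNAStringSet(c(chr1 = gseq))
    hits <- count_homologous_regions(probe, ref)
    ora <- oracle_homology_regions(probe, ref)
    expect_equal(nrow(hits), nrow(ora))
    if (n_mm == 11L) expect_equal(nrow(hits), 1L) else
      expect_equal(nrow(hits), 0L)
  }
})

test_that("scanner equals the exhaustive oracle on genomes with repeats", {
  reps <- data.frame(chrom = "chr1",
                     start = c(2000L, 6000L), end = c(2070L, 6095L),
                     n_copies = c(3L, 2L), mismatches = c(2L, 6L),
                     strand = c("random", "-"))
  sim <- simulate_genome(c(chr1 = 15000L, chr2 = 12000L), gc = 0.5,
                         repeats = reps, seed = 31)
  probes <- list(
    as.character(Biostrings::subseq(sim$ref[[1]], 1990, 2099)),
    as.character(Biostrings::subseq(sim$ref[[1]], 6000, 6109)),
    as.character(Biostrings::subseq(sim$ref[[2]], 500, 609)))
  selfs <- list(c("chr1", 1990, 2099), c("chr1", 6000, 6109),
                c("chr2", 500, 609))
  for (i in seq_along(probes)) {
    hits <- count_homologous_regions(probes[[i]], sim$ref,
                                     self_chrom = selfs[[i]][1],
                                     self_start = as.integer(selfs[[i]][2]),
                                     self_end = as.integer(selfs[[i]][3]))
    ora <- oracle_homology_regions(probes[[i]], sim$ref,
                                   self_chrom = selfs[[i]][1],
                                   self_start = as.integer(selfs[[i]][2]),
                                   self_end = as.integer(selfs[[i]][3]))
    hits <- hits[order(hits$chrom, hits$start), ]
    ora <- ora[order(ora$chrom, ora$start), ]
    expect_equal(nrow(hits), nrow(ora))
    expect_equal(hits$start, ora$start)
    expect_equal(hits$end, ora$end)
    expect_equal(hits$chrom, ora$chrom)
  }
})

test_that("hit count is strand-symmetric and grows by 1 per planted copy", {
  reps <- data.frame(chrom = "chr1", start = 3000L, end = 3100L,
                     n_copies = 2L, mismatches = 0L, strand = "random")
  sim <- simulate_genome(c(chr1 = 12000L), repeats = reps, seed = 77)
  probe <- as.character(Biostrings::subseq(sim$ref[[1]], 3000, 3109))
  base_hits <- nrow(count_homologous_regions(probe, sim$ref,
                                             self_chrom = "chr1",
                                             self_start = 3000,
                                             self_end = 3109))
  expect_equal(base_hits, 2L)

  rc <- Biostrings::reverseComplement(sim$ref)
  names(rc) <- names(sim$ref)
  rc_hits <- nrow(count_homologous_regions(probe, rc))
  fwd_hits <- nrow(count_homologous_regions(probe, sim$ref))
  expect_equal(rc_hits, fwd_hits)

  # append one perfect copy on a new contig: exactly one extra region
  aug <- c(sim$ref, Biostrings::DNAStringSet(c(
    chrX = paste0(rand_dna(2000, seed = 5), probe, rand_dna(2000)))))
  aug_hits <- nrow(count_homologous_regions(probe, aug,
                                            self_chrom = "chr1",
                                            self_start = 3000,
                                            self_end = 3109))
  expect_equal(aug_hits, base_hits + 1L)
})

test_that("probe evaluation enforces the closed GC band and strict hit cap", {
  # hand-built genome: SNP at pos 2111 with controlled flanks
  left <- paste(rep(c("G", "A", "T", "A"), c(33, 30, 30, 17)), collapse = "")
  right <- paste(rep(c("C", "T", "A", "T"), c(50, 20, 20, 20)), collapse = "")
  stopifnot(nchar(left) == 110, nchar(right) == 110)
  gseq <- paste0(rand_dna(2000, seed = 13), left, "A", right, rand_dna(2000))
  ref <- Biostrings::DNAStringSet(c(chr1 = gseq))
  rep1 <- evaluate_probe(ref, "chr1", 2111L)
  expect_equal(rep1$left_gc, 0.3)    # inclusive lower edge passes
  expect_equal(rep1$right_gc, 50 / 110)
  expect_true(rep1$gc_pass)
  expect_true(rep1$overall_pass)

  # low-GC left flank fails regardless of specificity
  left_low <- paste(rep(c("G", "A"), c(22, 88)), collapse = "")
  gseq2 <- paste0(rand_dna(2000, seed = 14), left_low, "A", right,
                  rand_dna(2000))
  rep2 <- evaluate_probe(Biostrings::DNAStringSet(c(chr1 = gseq2)),
                         "chr1", 2111L)
  expect_false(rep2$gc_pass)
  expect_false(rep2$overall_pass)

  # exactly 5 homologous regions fail the strict "< 5" cap; 4 pass
  for (n_copies in c(4L, 5L)) {
    reps <- data.frame(chrom = "chr1", start = 2001L, end = 2050L,
                       n_copies = n_copies, mismatches = 0L)
    sim <- simulate_genome(c(chr1 = 30000L), repeats = reps, seed = 99)
    pr <- evaluate_probe(sim$ref, "chr1", 2111L)
    expect_equal(pr$hit_count, n_copies)
    expect_equal(pr$specificity_pass, n_copies < 5L)
  }
})

test_that("truncated flanks fail automatically", {
  ref <- Biostrings::DNAStringSet(c(chr1 = rand_dna(500, seed = 21)))
  # the 49-bp left flank is too short for the window rules, which the
  # scanner reports before the truncation verdict fails the probe
  expect_warning(pr <- evaluate_probe(ref, "chr1", 50L), "shorter than")
  expect_true(pr$truncated)
  expect_false(pr$overall_pass)
})
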