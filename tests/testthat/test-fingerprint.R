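test_that("fingerprint selection respects spacing and length allocation", {
  # a panel of exactly k loci is retained in full
  sites <- data.frame(chrom = "chr1", pos = seq(1e5, 2e6, length.out = 20),
                      pic_chip = runif(20, 0.46, 0.5))
  fp <- select_fingerprint(sites, k = 20L, min_gap = 1000L)
  expect_equal(nrow(fp$loci), 20L)

  # of two loci 1 bp apart, only the higher-pic one is eligible
  near <- data.frame(chrom = "chr1", pos = c(1000L, 1001L, 500000L),
                     pic_chip = c(0.46, 0.50, 0.48))
  fp2 <- select_fingerprint(near, k = 2L, min_gap = 1000L)
  expect_equal(sort(fp2$loci$pos), c(1001L, 500000L))

  # per-chromosome counts proportional to length (largest remainder, +-1)
  set.seed(66)
  lens <- setNames(seq(2e6, 9e6, length.out = 15), paste0("chr", 1:15))
  panel <- do.call(rbind, lapply(names(lens), function(ch)
    data.frame(chrom = ch, pos = sort(sample.int(lens[[ch]], 200)),
               pic_chip = runif(200, 0.455, 0.5))))
  fp3 <- select_fingerprint(panel, k = 384L, min_gap = 1000L,
                            chrom_lengths = lens)
  expect_equal(nrow(fp3$loci), 384L)
  counts <- table(factor(fp3$loci$chrom, levels = names(lens)))
  expected <- 384 * lens / sum(lens)
  expect_true(all(abs(as.integer(counts) - expected) <= 1))
  # spacing constraint holds on every chromosome
  gaps <- unlist(lapply(split(fp3$loci$pos, fp3$loci$chrom), function(p)
    diff(sort(p))))
  expect_true(all(gaps >= 1000))
})

test_that("QR profiles round trip losslessly, including missing calls", {
  set.seed(88)
  for (rep in 1:25) {
    calls <- sample(c(-1L, 0L, 1L, 2L), 384, replace = TRUE)
    prof <- encode_qr(calls, sample = paste0("v", rep))
    expect_identical(decode_qr(prof), calls)
  }
  # all-missing payload round trips as all 11-codes
  allm <- rep(-1L, 384)
  pm <- encode_qr(allm)
  expect_true(all(pm$grid[-nrow(pm$grid), 1:32][1, ] == 1))
  expect_identical(decode_qr(pm), allm)
  # non-multiple-of-grid-width payloads work too
  short <- sample(c(-1L, 0L, 1L, 2L), 37, replace = TRUE)
  expect_identical(decode_qr(encode_qr(short)), short)
})

test_that("any single flipped QR cell is detected by the checksum", {
  set.seed(89)
  calls <- sample(c(-1L, 0L, 1L, 2L), 384, replace = TRUE)
  prof <- encode_qr(calls)
  dims <- dim(prof$grid)
  for (i in sample(prod(dims), 60)) {
    corrupted <- prof
    corrupted$grid[i] <- 1L - corrupted$grid[i]
    expect_error(decode_qr(corrupted), "corrupted")
  }
})

test_that("IBD of a sample with itself gives pihat 1", {
  set.seed(90)
  freqs <- runif(384, 0.35, 0.5)
  gA <- rbinom(384, 2, freqs)
  est <- ibd_mom(gA, gA, freqs)
  expect_gte(est$pihat, 0.99)
  expect_equal(est$z0 + est$z1 + est$z2, 1)
})

test_that("gene-drop pairs recover their IBD class", {
  sim <- simulate_kinship_pairs(n_pairs = 40L, seed = 91)
  res <- do.call(rbind, lapply(sim$pairs, function(p) {
    est <- ibd_mom(p$gA, p$gB, sim$freqs)
    data.frame(class = p$class, pihat = est$pihat, z0 = est$z0,
               called = classify_relationship(est)$class)
  }))
  by_class <- split(res, res$class)
  # bounds sized for 40 pairs/class (the full 200-pair recovery check
  # lives with the other cohort-scale analyses)
  expect_gt(mean(by_class$clone$pihat), 0.95)
  expect_lt(abs(mean(by_class$parent_offspring$pihat) - 0.5), 0.05)
  expect_lt(mean(by_class$unrelated$pihat), 0.07)
  expect_lt(mean(by_class$parent_offspring$z0), 0.05)
  expect_gte(mean(by_class$clone$called == "clone_or_bud_sport"), 0.95)
  expect_gte(mean(by_class$unrelated$called == "unrelated"), 0.85)
})

test_that("relationship classes follow the pihat/z0 thresholds", {
  mk <- function(pihat, z0) data.frame(pihat = pihat, z0 = z0,
                                       z1 = NA, z2 = NA,
                                       low_confidence = FALSE)
  expect_equal(classify_relationship(mk(0.98, 0))$class,
               "clone_or_bud_sport")
  expect_equal(classify_relationship(mk(0.5, 0.01))$class,
               "parent_offspring")
  expect_equal(classify_relationship(mk(0.5, 0.2))$class,
               "first_degree_other")
  expect_equal(classify_relationship(mk(0.25, 0.5))$class, "related")
  expect_equal(classify_relationship(mk(0.05, 0.9))$class, "unrelated")
})

test_that("clone groups are the transitive closure of clone edges", {
  calls <- data.frame(
    sample1 = c("A", "B", "D", "E"),
    sample2 = c("B", "C", "E", "F"),
    class = c("clone_or_bud_sport", "clone_or_bud_sport",
              "parent_offspring", "clone_or_bud_sport"))
  groups <- clone_groups(calls)
  expect_equal(length(groups), 2L)
  expect_equal(groups[[1]], c("A", "B", "C"))
  expect_equal(groups[[2]], c("E", "F"))
  # groups form a partition
  expect_false(any(duplicated(unlist(groups))))
  expect_equal(length(clone_groups(calls[calls$class == "parent_offspring",
                                         ])), 0L)
})

test_that("haplotype groups label identical genotype strings by frequency", {
  # 6-SNP region, four patterns with counts 12/11/7/9
  pats <- list(c(0, 0, 1, 1, 2, 0), c(1, 1, 1, 0, 0, 0),
               c(2, 2, 0, 0, 1, 1), c(0, 1, 0, 1, 0, 1))
  counts <- c(12, 11, 7, 9)
  calls <- do.call(rbind, unlist(lapply(seq_along(pats), function(i)
    replicate(counts[i], pats[[i]], simplify = FALSE)), recursive = FALSE))
  g <- toy_geno(calls, pos = 1000L + seq_len(6))
  hg <- haplotype_groups(g, "chr1", 0L, 10000L)
  expect_equal(hg$groups$n, c(12L, 11L, 9L, 7L))
  expect_equal(hg$groups$label, c("H001", "H002", "H003", "H004"))
  expect_equal(length(unique(hg$labels)), 4L)

  # a sample with a missing call is unassigned
  calls2 <- rbind(calls, c(0L, 0L, -1L, 1L, 2L, 0L))
  g2 <- toy_geno(calls2, pos = 1000L + seq_len(6))
  hg2 <- haplotype_groups(g2, "chr1", 0L, 10000L)
  expect_true(is.na(hg2$labels[nrow(calls2)]))

  # n distinct strings -> n singleton haplotypes
  g3 <- toy_geno(diag(2L, 4, 4), pos = 1000L + 1:4)
  expect_equal(haplotype_groups(g3, "chr1", 0L, 10000L)$groups$n,
               rep(1L, 4))
})
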