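test_that("generators are bit-reproducible given the same seed", {
  a <- simulate_genome(c(chr1 = 20000L), gc = 0.45, seed = 8)
  b <- simulate_genome(c(chr1 = 20000L), gc = 0.45, seed = 8)
  expect_identical(as.character(a$ref), as.character(b$ref))

  p1 <- simulate_population(c(chr1 = 50000L), n_snps = 100L, seed = 9)
  p2 <- simulate_population(c(chr1 = 50000L), n_snps = 100L, seed = 9)
  expect_identical(p1$geno$calls, p2$geno$calls)
  expect_identical(p1$truth, p2$truth)

  f1 <- simulate_f1(c(chr1 = 1e6), n_markers = 50L, n_progeny = 10L,
                    seed = 10)
  f2 <- simulate_f1(c(chr1 = 1e6), n_markers = 50L, n_progeny = 10L,
                    seed = 10)
  expect_identical(f1$geno$calls, f2$geno$calls)
  expect_identical(f1$truth, f2$truth)
})

test_that("simulated genomes hit the requested GC within binomial error", {
  sim <- simulate_genome(c(chr1 = 100000L), gc = 0.5, seed = 15)
  gcf <- gc_content(as.character(sim$ref[[1]]))
  expect_lt(abs(gcf - 0.5), 0.02)
  sim2 <- simulate_genome(c(chr1 = 100000L), gc = 0.35, seed = 16)
  expect_lt(abs(gc_content(as.character(sim2$ref[[1]])) - 0.35), 0.02)
})

test_that("planted repeats are recorded and defeat probe specificity", {
  reps <- data.frame(chrom = "chr1", start = 5000L, end = 5044L,
                     n_copies = 6L, mismatches = 0L)
  sim <- simulate_genome(c(chr1 = 40000L), repeats = reps, seed = 18)
  expect_equal(nrow(sim$truth), 6L)
  expect_true(all(sim$truth$mismatches == 0L))
  # the planted copies really are on-genome copies of the source
  src <- Biostrings::subseq(sim$ref[[1]], 5000, 5044)
  hit1 <- Biostrings::subseq(sim$ref[[sim$truth$chrom[1]]],
                             sim$truth$start[1], sim$truth$end[1])
  expect_equal(nchar(as.character(hit1)), 45L)

  pr <- evaluate_probe(sim$ref, "chr1", 5100L)
  expect_gte(pr$hit_count, 5L)
  expect_false(pr$specificity_pass)
})

test_that("population model respects maf floor and Hardy-Weinberg", {
  pop <- simulate_population(c(chr1 = 500000L), n_snps = 300L,
                             samples_per_pop = 60L, F = 0.1,
                             maf_floor = 0.35, seed = 19)
  expect_true(all(pmin(pop$truth$p_anc, 1 - pop$truth$p_anc) >= 0.35))

  # genotype frequencies within one population fit HWE at its realized
  # allele frequency (chi-square GOF, Bonferroni over sites)
  g <- pop$geno$calls[pop$pops == "pop1", ]
  pvals <- apply(g, 2, function(x) {
    n <- length(x)
    p <- sum(x) / (2 * n)
    if (p == 0 || p == 1) return(1)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    o <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
  })
  expect_equal(sum(pvals < 0.01 / length(pvals)), 0L)
})

test_that("panmixia limit gives near-zero Fst", {
  pop <- simulate_population(c(chr1 = 500000L), n_snps = 1000L, F = 0,
                             samples_per_pop = 50L, seed = 20)
  expect_lt(abs(fst_wc(pop$geno, pop$pops)$fst_global), 0.01)
})

test_that("F1 crossover counts follow the Poisson map-length model", {
  lens <- c(chr1 = 1e6)
  # zero map length: no breakpoints, all progeny non-recombinant
  f0 <- simulate_f1(lens, n_markers = 100L, n_progeny = 30L,
                    map_length_cM = c(P1 = 0, P2 = 0), seed = 21)
  expect_equal(nrow(f0$truth), 0L)
  for (parent in 1:2) {
    rc <- recode_origin(f0$geno, f0$gP1, f0$gP2, parent)
    expect_equal(nrow(build_bins(rc$origin, rc$sites)$bins), 1L)
  }

  # 100 cM: about one crossover per gamete (3 SE over 2 x 250 gametes)
  f1 <- simulate_f1(lens, n_markers = 100L, n_progeny = 250L,
                    map_length_cM = c(P1 = 100, P2 = 100), seed = 22)
  n_gametes <- 2 * 250
  rate <- nrow(f1$truth) / n_gametes
  se <- sqrt(1 / n_gametes)   # Poisson(1) sd = 1
  expect_lt(abs(rate - 1), 3 * se)
})

test_that("error-free crosses allow exact breakpoint recovery", {
  lens <- c(chr1 = 2e6, chr2 = 1e6)
  sim <- simulate_f1(lens, n_markers = 300L, n_progeny = 60L, seed = 23)
  for (parent in 1:2) {
    rc <- recode_origin(sim$geno, sim$gP1, sim$gP2, parent)
    bm <- build_bins(rc$origin, rc$sites)
    truth <- sim$truth[sim$truth$parent == paste0("P", parent), ]
    for (ch in names(lens)) {
      mpos <- sort(rc$sites$pos[rc$sites$chrom == ch])
      # effective truth: intervals (between informative markers) crossed
      # an odd number of times within a gamete, pooled over progeny
      tr <- truth[truth$chrom == ch, ]
      ivs <- unlist(lapply(split(findInterval(tr$pos, mpos),
                                 tr$progeny), function(iv) {
        tab <- table(iv)
        as.integer(names(tab)[tab %% 2 == 1])
      }))
      ivs <- unique(ivs[ivs >= 1 & ivs < length(mpos)])
      n_bins <- sum(bm$bins$chrom == ch)
      expect_equal(n_bins, length(ivs) + 1L)
      # each recovered boundary sits exactly between the flanking markers
      b <- bm$bins[bm$bins$chrom == ch, ]
      if (nrow(b) > 1L) {
        bounds <- cbind(b$end[-nrow(b)], b$start[-1])
        expected <- cbind(mpos[sort(ivs)], mpos[sort(ivs) + 1L])
        expect_equal(unname(bounds), unname(expected))
      }
    }
  }
})

test_that("kinship gene drop produces the configured classes", {
  sim <- simulate_kinship_pairs(n_pairs = 5L, n_loci = 50L, seed = 24,
                                classes = c("clone", "unrelated"))
  expect_equal(length(sim$pairs), 10L)
  expect_true(all(vapply(sim$pairs[1:5], function(p)
    identical(p$gA, p$gB), logical(1))))
  expect_true(all(sim$freqs >= 0.35 & sim$freqs <= 0.5))
})
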