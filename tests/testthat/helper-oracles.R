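# Independent oracles used to validate the estimators.

# Exhaustive homology oracle: every probe window of every rule length is
# searched over both strands with Biostrings::matchPattern at the rule's
# mismatch budget; hit windows are unioned, merged within `gap` bp and the
# self locus excluded. Semantically the all-offset sliding-window scan.
oracle_homology_regions <- function(probe, ref, self_chrom = NULL,
                                    self_start = NULL, self_end = NULL,
                                    gap = 10L) {
  rules <- homology_rules()
  specs <- rbind(data.frame(len = rules$min_run + 1L, mm = 0L),
                 data.frame(len = rules$windows$len,
                            mm = rules$windows$len - rules$windows$min_match))
  strands <- c(probe,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(probe))))
  out <- lapply(names(ref), function(ch) {
    subj <- ref[[ch]]
    ivs <- list()
    for (p in strands) for (k in seq_len(nrow(specs))) {
      W <- specs$len[k]
      if (nchar(p) < W) next
      for (i in 1:(nchar(p) - W + 1L)) {
        m <- Biostrings::matchPattern(substr(p, i, i + W - 1L), subj,
                                      max.mismatch = specs$mm[k])
        if (length(m))
          ivs[[length(ivs) + 1L]] <-
            data.frame(start = Biostrings::start(m),
                       end = Biostrings::end(m))
      }
    }
    iv <- do.call(rbind, ivs)
    if (is.null(iv)) return(NULL)
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    merged <- list()
    cur <- c(iv$start[1], iv$end[1])
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] <= cur[2] + gap) cur[2] <- max(cur[2], iv$end[i])
      else { merged[[length(merged) + 1L]] <- cur; cur <- c(iv$start[i], iv$end[i]) }
    }
    merged[[length(merged) + 1L]] <- cur
    m <- do.call(rbind, merged)
    if (!is.null(self_chrom) && ch == self_chrom)
      m <- m[!(m[, 1] <= self_end & m[, 2] >= self_start), , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    data.frame(chrom = ch, start = m[, 1], end = m[, 2])
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  res
}

# Weir & Cockerham (1984) per-site variance components, transcribed
# independently: scalar arithmetic over per-population genotype vectors.
oracle_wc_site <- function(geno_by_pop) {
  r <- length(geno_by_pop)
  n <- p <- h <- numeric(r)
  for (i in seq_len(r)) {
    gi <- geno_by_pop[[i]]
    gi <- gi[gi >= 0]
    n[i] <- length(gi)
    p[i] <- sum(gi) / (2 * n[i])
    h[i] <- mean(gi == 1)
  }
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

# Tajima's D constants, transcribed independently from the closed form.
oracle_tajima_d <- function(n, S, theta_pi) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (theta_pi - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# brute-force per-site pi: mean pairwise difference over all allele pairs
oracle_site_pi <- function(calls_at_site) {
  g <- calls_at_site[calls_at_site >= 0]
  alleles <- unlist(lapply(g, function(x) switch(as.character(x),
                                                 "0" = c(0, 0),
                                                 "1" = c(0, 1),
                                                 "2" = c(1, 1))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + (alleles[i] != alleles[j])
  tot / (n * (n - 1) / 2)
}
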