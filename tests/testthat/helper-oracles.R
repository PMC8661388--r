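# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: brute-force model fits via lm()/anova(),
# a gamete-level selfing simulation for RIL recombination, and the Holm
# adjustment written straight from its definition.

# Two-locus selfed-RIL Monte Carlo: simulate diplotypes (pairs of two-locus
# haplotypes) through `generations` of selfing with per-meiosis
# recombination r, and return the fraction of lines fixed recombinant.
# Near-fixation lines keep their first haplotype.
ril_two_locus_mc <- function(r, n, generations = 15L) {
  h1 <- matrix(0L, n, 2L)  # parent-0 haplotype at both loci
  h2 <- matrix(1L, n, 2L)
  gamete <- function(h1, h2) {
    pick1 <- stats::runif(nrow(h1)) < 0.5          # haplotype at locus 1
    rec <- stats::runif(nrow(h1)) < r              # crossover between loci
    a1 <- ifelse(pick1, h1[, 1L], h2[, 1L])
    pick2 <- xor(pick1, rec)
    a2 <- ifelse(pick2, h1[, 2L], h2[, 2L])
    cbind(a1, a2)
  }
  for (g in seq_len(generations)) {
    g1 <- gamete(h1, h2)
    g2 <- gamete(h1, h2)
    h1 <- g1; h2 <- g2
  }
  mean(h1[, 1L] != h1[, 2L])
}

# Holm adjustment straight from the step-down definition.
holm_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# Brute-force per-marker partial F p-values via anova(lm()).
scan_oracle <- function(y, codes, cond_idx = integer()) {
  test_idx <- setdiff(seq_len(ncol(codes)), cond_idx)
  vapply(test_idx, function(j) {
    d <- data.frame(y = y, x = codes[, j])
    if (length(cond_idx)) {
      C <- codes[, cond_idx, drop = FALSE]
      colnames(C) <- paste0("c", seq_len(ncol(C)))
      d <- cbind(d, C)
      f <- stats::as.formula(paste("y ~", paste(colnames(C), collapse = " + "), "+ x"))
    } else {
      f <- y ~ x
    }
    a <- stats::anova(stats::lm(f, data = d))
    a["x", "Pr(>F)"]
  }, numeric(1))
}

# Brute-force joint-linkage p-values via anova(lm(y ~ family + marker:family)).
joint_scan_oracle <- function(y, codes, family, cond_idx = integer()) {
  fam <- factor(family)
  test_idx <- setdiff(seq_len(ncol(codes)), cond_idx)
  vapply(test_idx, function(j) {
    d <- data.frame(y = y, fam = fam, x = codes[, j])
    rhs <- "fam"
    if (length(cond_idx)) {
      C <- codes[, cond_idx, drop = FALSE]
      colnames(C) <- paste0("c", seq_len(ncol(C)))
      d <- cbind(d, C)
      rhs <- paste(rhs, "+", paste(paste0(colnames(C), ":fam"), collapse = " + "))
    }
    f <- stats::as.formula(paste("y ~", rhs, "+ x:fam"))
    a <- stats::anova(stats::lm(f, data = d))
    a["fam:x", "Pr(>F)"]
  }, numeric(1))
}

# Brute-force LOD-drop interval: all contiguous runs containing the peak
# with every LOD above the cutoff; report the maximal one.
lod_interval_oracle <- function(scan, peak_marker, lod_drop = 1) {
  i <- match(peak_marker, scan$marker)
  s <- scan[scan$chr == scan$chr[i], ]
  s <- s[order(s$pos_cM, s$pos_bp), ]
  j <- match(peak_marker, s$marker)
  cut <- s$lod[j] - lod_drop
  best <- c(j, j)
  for (lo in seq_len(j)) {
    for (hi in j:nrow(s)) {
      if (all(s$lod[lo:hi] >= cut) && hi - lo > best[2] - best[1]) best <- c(lo, hi)
    }
  }
  c(s$pos_bp[best[1]], s$pos_bp[best[2]]) / 1e6
}

# Small genotype fixture shared by scan tests.
make_fixture <- function(n = 80, n_chr = 2, m_per_chr = 6, spacing = 8, seed = 1) {
  map <- simulate_map(n_chr, m_per_chr, spacing, seed = seed)
  simulate_ril_family(map, n, seed = seed + 1)
}
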