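test_that("marker_scan matches the brute-force anova(lm()) oracle", {
  for (i in 1:10) {
    g <- make_fixture(n = 60, seed = 20 + i)
    set.seed(40 + i)
    y <- rnorm(60) + 0.4 * g$codes[, 3]
    cond <- if (i %% 2 == 0) c(2L, 7L) else integer()
    sc <- marker_scan(y, g, conditioned = cond)
    expect_equal(sc$p, scan_oracle(y, g$codes, cond), tolerance = 1e-10)
  }
})

test_that("scan p-values are invariant to affine phenotype transforms", {
  g <- make_fixture(seed = 5)
  set.seed(6); y <- rnorm(80)
  expect_equal(marker_scan(y, g)$p, marker_scan(3 * y - 10, g)$p, tolerance = 1e-12)
})

test_that("scan handles exact fits, conditioning and degenerate markers", {
  g <- make_fixture(n = 50, seed = 7)
  # phenotype equal to a marker's codes: p underflows, LOD maximal there
  y <- as.numeric(g$codes[, 4])
  sc <- marker_scan(y, g)
  expect_lt(sc$p[sc$marker == "m0004"], 1e-100)
  expect_equal(which.max(sc$lod), which(sc$marker == "m0004"))

  # conditioned markers are excluded from the output
  sc2 <- marker_scan(rnorm(50), g, conditioned = "m0002")
  expect_false("m0002" %in% sc2$marker)

  # marker collinear with the conditioned set -> p = 1 with flag
  codes <- g$codes; codes[, 5] <- codes[, 2]
  g2 <- geno_matrix(codes, g$map, family = g$family)
  sc3 <- marker_scan(rnorm(50), g2, conditioned = "m0002")
  expect_equal(sc3$p[sc3$marker == "m0005"], 1)
  expect_true(sc3$collinear[sc3$marker == "m0005"])

  expect_error(marker_scan(rep(1, 50), g), "constant")

  # rows missing the test marker's genotype are dropped for that marker only
  codes_na <- g$codes; codes_na[1:5, 3] <- NA
  g3 <- geno_matrix(codes_na, g$map)
  set.seed(1); y3 <- rnorm(50)
  sc4 <- marker_scan(y3, g3)
  expect_equal(sc4$n_used[sc4$marker == "m0003"], 45L)
  keep <- !is.na(codes_na[, 3])
  expect_equal(sc4$p[sc4$marker == "m0003"],
               scan_oracle(y3[keep], codes_na[keep, 3, drop = FALSE]),
               tolerance = 1e-10)
})

test_that("compute_tpve equals 100 * (1 - RSS/TSS) from an independent fit", {
  g <- make_fixture(n = 70, seed = 9)
  set.seed(10); y <- rnorm(70) + 0.5 * g$codes[, 2] - 0.3 * g$codes[, 8]
  expect_equal(compute_tpve(y, g, NULL), 0)
  expect_equal(compute_tpve(as.numeric(g$codes[, 2]), g, "m0002"), 100)
  fit <- lm(y ~ g$codes[, 2] + g$codes[, 8])
  oracle <- 100 * (1 - sum(resid(fit)^2) / sum((y - mean(y))^2))
  expect_equal(compute_tpve(y, g, c("m0002", "m0008")), oracle, tolerance = 1e-10)
})

test_that("LOD support intervals match a brute-force contiguous search", {
  g <- make_fixture(n = 100, n_chr = 2, m_per_chr = 10, seed = 11)
  set.seed(12)
  for (i in 1:5) {
    y <- rnorm(100) + runif(1, 0.3, 0.8) * g$codes[, sample(10, 1)]
    sc <- marker_scan(y, g)
    peak <- sc$marker[which.max(sc$lod)]
    expect_equal(lod_support_interval(sc, peak, 1), lod_interval_oracle(sc, peak, 1))
    expect_equal(lod_support_interval(sc, peak, 2), lod_interval_oracle(sc, peak, 2))
  }
  # flat profile spans the chromosome; sharp peak collapses to one marker
  flat <- sc; flat$lod <- rep(1, nrow(flat))
  expect_equal(lod_support_interval(flat, flat$marker[3], 1),
               range(flat$pos_bp[flat$chr == flat$chr[3]]) / 1e6)
  sharp <- sc; sharp$lod <- c(10, rep(0, nrow(sc) - 1))
  expect_equal(lod_support_interval(sharp, sharp$marker[1], 1),
               rep(sharp$pos_bp[1] / 1e6, 2))
  expect_error(lod_support_interval(sc, "nope"), "not on scan")
})

test_that("permutation thresholds follow the order-statistic null", {
  # effectively single-marker genome (two fully linked markers): the
  # minimum p is Uniform(0,1), so the threshold estimates alpha
  map <- genetic_map(c("a", "b"), c(1, 1), c(1, 1), c(1e6, 1e6 + 1))
  set.seed(13)
  x <- sample(c(0, 2), 400, replace = TRUE)
  g <- geno_matrix(cbind(x, x), map)
  y <- rnorm(400)
  thr <- permutation_threshold(y, g, config = scan_config(2000, 0.05, seed = 14))
  expect_lt(abs(thr - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  # threshold shrinks as the scanned genome grows
  g_big <- make_fixture(n = 400, n_chr = 5, m_per_chr = 20, seed = 15)
  thr_big <- permutation_threshold(rnorm(400), g_big,
                                   config = scan_config(500, 0.05, seed = 16))
  expect_lt(thr_big, thr)

  # fixed seed reproduces the threshold; alpha*n < 1 is rejected
  g1 <- make_fixture(seed = 17)
  y1 <- rnorm(80)
  cfg <- scan_config(100, 0.05, seed = 18)
  expect_identical(permutation_threshold(y1, g1, config = cfg),
                   permutation_threshold(y1, g1, config = cfg))
  expect_error(permutation_threshold(y1, g1, config = scan_config(10, 0.05)),
               class = "namqtl_invalid_parameter")
})

test_that("stepwise selection recovers simulated QTL architecture", {
  map <- simulate_map(3, 15, 8, seed = 19)
  g <- simulate_ril_family(map, 250, seed = 20)
  # two strong unlinked QTL with opposite effect signs
  truth <- sim_truth(qtl = data.frame(marker_index = c(5, 20), effect = c(1, -1)),
                     h2 = 0.5)
  ph <- simulate_phenotype(g, truth, seed = 21)
  fit <- stepwise_qtl(ph, g, scan_config(200, 0.05, seed = 22))
  expect_gte(nrow(fit), 2)
  hits <- vapply(c(5, 20), function(j) {
    any(fit$chr == map$chr[j] & abs(fit$peak_Mb - map$pos_bp[j] / 1e6) < 10)
  }, logical(1))
  expect_true(all(hits))
  # cumulative TPVE nondecreasing; support interval contains the peak
  expect_true(all(diff(fit$tpve) >= -1e-12))
  expect_true(all(fit$ci_lo_Mb <= fit$peak_Mb & fit$peak_Mb <= fit$ci_hi_Mb))
  # effect signs: code-2 allele raises the trait at QTL 1, lowers it at QTL 2
  e1 <- fit$effect[fit$chr == map$chr[5] & abs(fit$peak_Mb - map$pos_bp[5] / 1e6) < 10]
  e2 <- fit$effect[fit$chr == map$chr[20] & abs(fit$peak_Mb - map$pos_bp[20] / 1e6) < 10]
  expect_true(all(e1 > 0) && all(e2 < 0))
})

test_that("stepwise with threshold 1 and one step returns the best scan marker", {
  g <- make_fixture(n = 90, seed = 23)
  set.seed(24); y <- rnorm(90) + 0.5 * g$codes[, 6]
  fit <- stepwise_qtl(y, g, scan_config(50, 0.05, seed = 25),
                      threshold = 1, max_steps = 1)
  sc <- marker_scan(y, g)
  expect_equal(fit$marker, sc$marker[which.min(sc$p)])
  expect_equal(fit$p_value, min(sc$p), tolerance = 1e-12)
})

test_that("ties in the minimum p are broken by lowest chromosome then position", {
  map <- genetic_map(paste0("m", 1:4), c(1, 1, 2, 2),
                     c(0, 5, 0, 5), c(1e6, 5e6, 1e6, 5e6))
  set.seed(26)
  x <- sample(c(0, 2), 60, replace = TRUE)
  other <- sample(c(0, 2), 60, replace = TRUE)
  # the informative column duplicated on both chromosomes: identical p
  g <- geno_matrix(cbind(x, other, x, other), map)
  y <- x + rnorm(60, 0, 0.8)
  fit <- stepwise_qtl(y, g, threshold = 1, max_steps = 1,
                      config = scan_config(50, 0.05, seed = 27))
  expect_equal(fit$marker, "m1")
  expect_equal(fit$chr, 1L)
})
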