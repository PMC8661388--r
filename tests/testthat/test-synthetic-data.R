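test_that("simulated maps hit the requested spacing, order and determinism", {
  map <- simulate_map(10, 84, 1.6, seed = 7)
  expect_equal(nrow(map), 840)
  for (ch in 1:10) {
    d <- diff(map$pos_cM[map$chr == ch])
    expect_equal(mean(d), 1.6, tolerance = 1e-12)  # rescaled to the exact mean
    expect_true(all(d > 0))
  }
  expect_true(all(diff(map$pos_bp[map$chr == 3]) > 0))
  expect_identical(map, simulate_map(10, 84, 1.6, seed = 7))
  expect_false(identical(map, simulate_map(10, 84, 1.6, seed = 8)))

  two <- simulate_map(1, 2, 10, seed = 1)
  expect_equal(diff(two$pos_cM), 10)

  expect_error(simulate_map(0, 5, 1), class = "namqtl_invalid_parameter")
  expect_error(simulate_map(1, 1, 1), class = "namqtl_invalid_parameter")
  expect_error(simulate_map(1, 5, -2), class = "namqtl_invalid_parameter")
})

test_that("RIL genotypes follow the two-locus selfing recombination expectation", {
  # completely linked markers segregate together
  map0 <- genetic_map(c("a", "b"), c(1, 1), c(3, 3), c(3e6, 3e6 + 1))
  g0 <- simulate_ril_family(map0, 300, residual_het_rate = 0, seed = 1)
  expect_identical(g0$codes[, 1], g0$codes[, 2])

  # markers on different chromosomes are independent: R ~ 0.5
  map_ind <- genetic_map(c("a", "b", "c", "d"), c(1, 1, 2, 2),
                         c(0, 1, 0, 1), c(1, 1e6, 1, 1e6))
  gi <- simulate_ril_family(map_ind, 10000, residual_het_rate = 0, seed = 2)
  Robs <- mean(gi$codes[, 1] != gi$codes[, 3])
  expect_lt(abs(Robs - 0.5), 3 * sqrt(0.25 / 10000))

  # 10 cM apart: R = 2r/(1+2r), r from Haldane; checked against both the
  # closed form and an independent gamete-level selfing Monte Carlo
  map10 <- genetic_map(c("a", "b"), c(1, 1), c(0, 10), c(1, 1e7))
  g10 <- simulate_ril_family(map10, 10000, residual_het_rate = 0, seed = 3)
  r <- 0.5 * (1 - exp(-0.2))
  R_exp <- 2 * r / (1 + 2 * r)
  se <- sqrt(R_exp * (1 - R_exp) / 10000)
  expect_lt(abs(mean(g10$codes[, 1] != g10$codes[, 2]) - R_exp), 3 * se)
  set.seed(42)
  R_mc <- ril_two_locus_mc(r, 10000)
  expect_lt(abs(R_mc - R_exp), 3 * se)  # oracle agrees with the closed form

  # per-marker allele frequency ~ 0.5 and determinism
  freq0 <- colMeans(g10$codes == 0)
  expect_true(all(abs(freq0 - 0.5) < 3 * sqrt(0.25 / 10000) + 1e-12))
  expect_identical(g10$codes, simulate_ril_family(map10, 10000,
                                                  residual_het_rate = 0, seed = 3)$codes)

  expect_error(simulate_ril_family(map10, 0), class = "namqtl_invalid_parameter")
  expect_error(simulate_ril_family(map10, 10, residual_het_rate = 0.7),
               class = "namqtl_invalid_parameter")
})

test_that("observed recombination is monotone in map distance", {
  map <- genetic_map(paste0("m", 1:5), rep(1, 5),
                     c(0, 2, 8, 20, 50), c(1, 2e6, 8e6, 2e7, 5e7))
  g <- simulate_ril_family(map, 4000, residual_het_rate = 0, seed = 11)
  Robs <- vapply(2:5, function(j) mean(g$codes[, 1] != g$codes[, j]), numeric(1))
  expect_true(all(diff(Robs) > -0.02))  # nondecreasing up to sampling noise
})

test_that("residual heterozygosity is injected at the requested rate", {
  map <- simulate_map(1, 50, 2, seed = 1)
  g <- simulate_ril_family(map, 400, residual_het_rate = 0.05, seed = 5)
  het <- mean(g$codes == 1)
  expect_lt(abs(het - 0.05), 3 * sqrt(0.05 * 0.95 / length(g$codes)))
})

test_that("NAM panels stack families with consistent labels", {
  map <- simulate_map(2, 10, 5, seed = 1)
  spec <- c(CML103 = 154, CML333 = 159, NC358 = 151, Tx303 = 160)
  nam <- simulate_nam(map, spec, seed = 9)
  expect_equal(nrow(nam$codes), 624)
  expect_equal(as.vector(table(nam$family)[names(spec)]), unname(spec))
  # family labels partition rows exactly
  expect_equal(sum(table(nam$family)), length(nam$ril_ids))
  expect_false(anyDuplicated(nam$ril_ids) > 0)

  # one family reproduces simulate_ril_family under the documented
  # substream derivation (family i uses seed + 1000*i)
  one <- simulate_nam(map, c(CML103 = 25), seed = 9)
  ref <- simulate_ril_family(map, 25, seed = 9 + 1000, family = "CML103")
  expect_identical(one$codes, ref$codes)

  expect_error(simulate_nam(map, c(A = 5, A = 5)), class = "namqtl_invalid_parameter")
  expect_error(simulate_nam(map, integer()), class = "namqtl_invalid_parameter")
})

test_that("simulated phenotypes realize the target heritability", {
  map <- simulate_map(1, 10, 10, seed = 1)
  g <- simulate_ril_family(map, 1000, seed = 2)
  truth <- sim_truth(qtl = data.frame(marker_index = 5, effect = 1), h2 = 0.12)

  # h2 = 1: exact linear function of the codes
  ph1 <- simulate_phenotype(g, sim_truth(data.frame(marker_index = 5, effect = 1), h2 = 1),
                            seed = 3)
  expect_equal(ph1$value, as.numeric(g$codes[, 5]), tolerance = 1e-12)

  # h2 = 0: no marker association beyond chance
  ph0 <- simulate_phenotype(g, sim_truth(h2 = 0), seed = 4)
  expect_gt(summary(lm(ph0$value ~ g$codes[, 5]))$coefficients[2, 4], 0.001)

  # single QTL targeting 12%: realized marker R^2 ~ 0.12 (analytic
  # variance decomposition fixes var(e) = var(g)(1-h2)/h2)
  r2 <- vapply(1:30, function(i) {
    ph <- simulate_phenotype(g, truth, seed = i)
    summary(lm(ph$value ~ g$codes[, 5]))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.12), 3 * sd(r2) / sqrt(length(r2)))

  # determinism and validation
  expect_identical(simulate_phenotype(g, truth, seed = 3),
                   simulate_phenotype(g, truth, seed = 3))
  const <- geno_matrix(matrix(0, 10, 2), simulate_map(1, 2, 5, seed = 1))
  expect_error(
    simulate_phenotype(const, sim_truth(data.frame(marker_index = 1, effect = 1), h2 = 1)),
    class = "namqtl_invalid_parameter"
  )
  expect_error(sim_truth(h2 = 1.2), class = "namqtl_invalid_parameter")
})

test_that("field trials reproduce the augmented incomplete-block layout", {
  vals <- data.frame(genotype = sprintf("g%03d", 1:200),
                     value = rnorm(200), stringsAsFactors = FALSE)
  des <- field_design(block_size = 22, checks_per_block = 2, years = 2015,
                      year_effect_sd = 0, block_effect_sd = 0, residual_sd = 0)
  expect_equal(des$check_fraction, 2 / 22)
  tr <- simulate_field_trial(vals, des, seed = 1,
                             checks = c(B73 = 0, CML103 = 1))
  expect_equal(length(unique(tr$block)), 10)        # 200 / 20 test entries
  expect_equal(mean(tr$is_check), 40 / 440)         # ~10% check plots
  expect_true(all(tapply(tr$is_check, tr$block, sum) == 2))
  expect_true(all(tr$genotype[tr$is_check] %in% c("B73", "CML103")))
  # B73, the common parent, appears in every block
  b73_blocks <- unique(tr$block[tr$genotype == "B73"])
  expect_equal(sort(b73_blocks), sort(unique(tr$block)))

  # zero design variance: plot value equals the genotype value
  m <- match(tr$genotype[!tr$is_check], vals$genotype)
  expect_equal(tr$value[!tr$is_check], vals$value[m], tolerance = 1e-12)

  # same seed reproduces layout and noise
  des2 <- field_design(block_size = 22, years = c(2015, 2019),
                       year_effect_sd = 1, block_effect_sd = 1, residual_sd = 0.3)
  expect_identical(simulate_field_trial(vals, des2, seed = 5),
                   simulate_field_trial(vals, des2, seed = 5))

  expect_error(simulate_field_trial(vals[1:10, ], des),
               class = "namqtl_invalid_parameter")
  expect_error(field_design(block_size = 2, checks_per_block = 2),
               class = "namqtl_invalid_parameter")
})

test_that("sim-truth sidecars round-trip through JSON", {
  truth <- sim_truth(qtl = data.frame(marker_index = c(3L, 8L), effect = c(0.5, -0.2)),
                     h2 = 0.4, family_offsets = c(CML103 = 0.3, Tx303 = -0.1))
  f <- tempfile(fileext = ".json")
  write_sim_truth(truth, f)
  back <- read_sim_truth(f)
  expect_equal(back$qtl$marker_index, truth$qtl$marker_index)
  expect_equal(back$qtl$effect, truth$qtl$effect)
  expect_equal(back$h2, truth$h2)
  expect_equal(back$family_offsets, truth$family_offsets)
})
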