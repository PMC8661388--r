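#' Simulate one biparental selfed RIL family
#'
#' Genotypes are generated chromosome by chromosome as a two-state Markov
#' chain along the marker order: each RIL starts at a random parental state
#' (code 0 or 2 with probability 1/2) and switches between adjacent markers
#' with the RIL recombination fraction \eqn{R = 2r/(1+2r)}, where \eqn{r}
#' comes from the Haldane map function on the cM distance. This is the
#' closed-form equivalent of simulating Haldane-crossover gametes through
#' repeated selfing to near-fixation (single-seed descent). Residual
#' heterozygosity is then injected by replacing random cells with code 1,
#' and missingness (if requested) by blanking random cells.
#'
#' @param map a [genetic_map()].
#' @param n_rils number of lines to simulate (>= 1).
#' @param residual_het_rate per-cell probability of a heterozygous call
#'   (default 0.001, i.e. 0.1%; NAM RILs are near-fixed).
#' @param seed integer seed.
#' @param missing_rate per-cell probability of a missing call (default 0).
#' @param family family label for the block.
#' @param ril_prefix prefix for generated RIL ids.
#' @return a [geno_matrix()] of `n_rils` rows.
#' @examples
#' map <- simulate_map(2, 20, 5, seed = 1)
#' g <- simulate_ril_family(map, 50, seed = 2)
#' colMeans(g$codes) / 2   # allele frequency ~ 0.5 per marker
#' @export
simulate_ril_family <- function(map, n_rils, residual_het_rate = 0.001, seed = 1L,
                                missing_rate = 0, family = "F1", ril_prefix = family) {
  if (!inherits(map, "genetic_map") || nrow(map) == 0L) {
    stop_invalid("a non-empty genetic_map is required")
  }
  if (n_rils < 1) stop_invalid("n_rils must be >= 1")
  if (residual_het_rate < 0 || residual_het_rate >= 0.5) {
    stop_invalid("residual_het_rate must lie in [0, 0.5)")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop_invalid("missing_rate must lie in [0, 1)")
  codes <- with_seed(seed, {
    out <- matrix(0L, n_rils, nrow(map))
    for (ch in unique(map$chr)) {
      idx <- which(map$chr == ch)
      R <- ril_R(haldane_r(diff(map$pos_cM[idx])))
      state <- matrix(0L, n_rils, length(idx))
      state[, 1L] <- stats::rbinom(n_rils, 1L, 0.5)
      if (length(idx) > 1L) {
        flips <- matrix(
          stats::rbinom(n_rils * (length(idx) - 1L), 1L, rep(R, each = n_rils)),
          n_rils, length(idx) - 1L
        )
        # parental state = initial state xor cumulative number of switches
        cum <- flips
        if (ncol(cum) > 1L) {
          for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1L] + cum[, j]
        }
        state <- (matrix(state[, 1L], n_rils, length(idx)) + cbind(0L, cum)) %% 2L
      }
      out[, idx] <- 2L * state
    }
    if (residual_het_rate > 0) {
      het <- stats::runif(length(out)) < residual_het_rate
      out[het] <- 1L
    }
    if (missing_rate > 0) {
      out[stats::runif(length(out)) < missing_rate] <- NA_integer_
    }
    out
  }, substream = 2L)
  geno_matrix(codes, map,
              ril_ids = sprintf("%s_%04d", ril_prefix, seq_len(n_rils)),
              family = family)
}

#' Simulate a NAM panel of RIL families sharing a common parent
#'
#' @param map a shared [genetic_map()].
#' @param family_specs named integer vector: family name -> number of RILs,
#'   e.g. `c(CML103 = 154, CML333 = 159, NC358 = 151, Tx303 = 160)`.
#' @param residual_het_rate,missing_rate,seed as [simulate_ril_family()];
#'   family `i` draws from the derived seed `seed + 1000 * i`, so a single
#'   family simulated via `simulate_nam(map, spec, seed = s)` reproduces
#'   `simulate_ril_family(map, n, seed = s + 1000)` exactly.
#' @return a [geno_matrix()] with families stacked in the given order and
#'   per-row family labels.
#' @export
simulate_nam <- function(map, family_specs, residual_het_rate = 0.001, seed = 1L,
                         missing_rate = 0) {
  if (length(family_specs) < 1L) stop_invalid("at least one family is required")
  if (is.null(names(family_specs)) || any(!nzchar(names(family_specs)))) {
    stop_invalid("family_specs must be a named vector")
  }
  if (anyDuplicated(names(family_specs))) stop_invalid("duplicate family names")
  fams <- lapply(seq_along(family_specs), function(i) {
    simulate_ril_family(map, family_specs[[i]], residual_het_rate,
                        seed = seed + 1000L * i, missing_rate = missing_rate,
                        family = names(family_specs)[i])
  })
  codes <- do.call(rbind, lapply(fams, `[[`, "codes"))
  geno_matrix(codes, map,
              ril_ids = unlist(lapply(fams, `[[`, "ril_ids"), use.names = FALSE),
              family = unlist(lapply(fams, `[[`, "family"), use.names = FALSE))
}

#' Ground truth for a simulated trait
#'
#' Bundles the additive QTL architecture used by [simulate_phenotype()]:
#' which markers are causal, their additive effects (trait units per unit
#' of the 0/1/2 allele code), the target narrow-sense heritability and
#' optional per-family mean shifts.
#'
#' @param qtl data frame with columns `marker_index` and `effect` (may have
#'   zero rows for a null trait).
#' @param h2 target heritability in `[0, 1]`: the fraction of phenotypic
#'   variance contributed by the QTL term.
#' @param family_offsets named numeric vector of family mean shifts
#'   (families absent from the vector shift by 0).
#' @return a `sim_truth` object.
#' @export
sim_truth <- function(qtl = data.frame(marker_index = integer(), effect = numeric()),
                      h2 = 0.5, family_offsets = numeric()) {
  qtl <- as.data.frame(qtl)
  stopifnot(all(c("marker_index", "effect") %in% names(qtl)))
  if (h2 < 0 || h2 > 1) stop_invalid("h2 must lie in [0, 1]")
  structure(list(qtl = qtl, h2 = h2, family_offsets = family_offsets),
            class = "sim_truth")
}

#' Simulate genotype-level trait values from an additive QTL model
#'
#' Each RIL's value is
#' \deqn{y_i = \mu_{fam(i)} + \sum_k a_k x_{ik} + e_i,\quad e_i \sim N(0, \sigma_e^2),}
#' with \eqn{x_{ik}} the 0/1/2 code at QTL k. The residual variance is set
#' from the realized genetic variance in the sample so that the genetic
#' fraction of variance equals the target `h2`:
#' \eqn{\sigma_e^2 = \mathrm{var}(g)\,(1-h^2)/h^2}. With `h2 = 0` the trait
#' is pure standard-normal noise around the family means (QTL effects are
#' ignored; a fixed nonzero effect cannot coexist with zero heritability),
#' and with `h2 = 1` the trait is an exact linear function of the codes.
#'
#' @param geno a [geno_matrix()] (missing codes are treated as the marker
#'   mean when forming genetic values).
#' @param truth a [sim_truth()] whose `marker_index` values are valid
#'   columns of `geno`.
#' @param seed integer seed.
#' @return data frame with columns `genotype`, `family`, `value`
#'   (one row per RIL).
#' @export
simulate_phenotype <- function(geno, truth, seed = 1L) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(truth, "sim_truth"))
  n <- nrow(geno$codes)
  k <- nrow(truth$qtl)
  if (k > 0 && (any(truth$qtl$marker_index < 1) ||
                any(truth$qtl$marker_index > ncol(geno$codes)))) {
    stop_invalid("QTL marker indices outside the map")
  }
  g <- rep(0, n)
  if (k > 0 && truth$h2 > 0) {
    x <- geno$codes[, truth$qtl$marker_index, drop = FALSE]
    if (anyNA(x)) {
      for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
    }
    g <- drop(x %*% truth$qtl$effect)
  }
  vg <- stats::var(g)
  if (truth$h2 == 1 && vg == 0) stop_invalid("h2 = 1 requires nonzero genetic variance")
  sigma_e <- if (truth$h2 == 0) 1 else if (truth$h2 == 1) 0 else sqrt(vg * (1 - truth$h2) / truth$h2)
  offs <- rep(0, n)
  if (length(truth$family_offsets)) {
    m <- truth$family_offsets[geno$family]
    offs <- ifelse(is.na(m), 0, m)
  }
  e <- with_seed(seed, stats::rnorm(n, 0, sigma_e), substream = 3L)
  data.frame(genotype = geno$ril_ids, family = geno$family,
             value = offs + g + e, stringsAsFactors = FALSE)
}

#' Augmented incomplete-block field design
#'
#' @param block_size total plots per block (test entries plus checks).
#' @param checks_per_block replicated check plots per block (>= 1).
#' @param years vector of year labels (one trial per year).
#' @param year_effect_sd,block_effect_sd,residual_sd standard deviations of
#'   the random year, block-within-year and plot residual effects, in trait
#'   units.
#' @return a `field_design` object. The implied check fraction
#'   `checks_per_block / block_size` is reported on print.
#' @export
field_design <- function(block_size = 22L, checks_per_block = 2L,
                         years = c(2015L, 2019L),
                         year_effect_sd = 0, block_effect_sd = 0, residual_sd = 0) {
  if (checks_per_block < 1 || block_size <= checks_per_block) {
    stop_invalid("block_size must exceed checks_per_block >= 1")
  }
  if (min(year_effect_sd, block_effect_sd, residual_sd) < 0) {
    stop_invalid("effect standard deviations must be >= 0")
  }
  structure(list(block_size = as.integer(block_size),
                 checks_per_block = as.integer(checks_per_block),
                 check_fraction = checks_per_block / block_size,
                 years = years, year_effect_sd = year_effect_sd,
                 block_effect_sd = block_effect_sd, residual_sd = residual_sd),
            class = "field_design")
}

#' Simulate a blocked, augmented field trial from genotype values
#'
#' Test genotypes are randomized anew to incomplete blocks each year
#' (`block_size - checks_per_block` test entries per block); every block
#' additionally carries the replicated checks, always including the common
#' parent. Each plot observation is
#' `genotype value + year effect + block-within-year effect + residual`.
#'
#' @param genotype_values data frame with columns `genotype` and `value`
#'   (e.g. from [simulate_phenotype()]).
#' @param design a [field_design()].
#' @param seed integer seed (layout and noise are reproducible).
#' @param checks named numeric vector of check-line values; the first entry
#'   is treated as the common parent. Default: a single check named `B73`
#'   at the mean of the genotype values.
#' @return plot-level data frame with columns `genotype`, `year`, `block`,
#'   `is_check`, `value`. Blocks are labelled uniquely within year.
#' @export
simulate_field_trial <- function(genotype_values, design, seed = 1L, checks = NULL) {
  stopifnot(inherits(design, "field_design"))
  gv <- genotype_values
  stopifnot(all(c("genotype", "value") %in% names(gv)))
  per_block <- design$block_size - design$checks_per_block
  if (nrow(gv) < per_block) stop_invalid("fewer genotypes than one block of test entries")
  if (is.null(checks)) checks <- c(B73 = mean(gv$value))
  if (length(checks) < design$checks_per_block) {
    # recycle founder checks so every block carries checks_per_block plots
    checks <- rep(checks, length.out = design$checks_per_block)
    names(checks) <- make.unique(names(checks))
  }
  with_seed(seed, {
    rows <- lapply(design$years, function(yr) {
      ord <- sample.int(nrow(gv))
      n_blocks <- ceiling(nrow(gv) / per_block)
      blk <- rep(seq_len(n_blocks), each = per_block)[seq_along(ord)]
      yeff <- stats::rnorm(1, 0, design$year_effect_sd)
      beff <- stats::rnorm(n_blocks, 0, design$block_effect_sd)
      # each block: test entries plus the replicated checks (common parent
      # first, then rotating founder checks)
      check_idx <- lapply(seq_len(n_blocks), function(b) {
        k <- design$checks_per_block
        if (length(checks) == 1L) rep(1L, k)
        else c(1L, 2L + (b - 1L + seq_len(k - 1L) - 1L) %% (length(checks) - 1L))
      })
      geno <- c(gv$genotype[ord], unlist(lapply(check_idx, function(i) names(checks)[i])))
      base <- c(gv$value[ord], unlist(lapply(check_idx, function(i) unname(checks[i]))))
      block <- c(blk, rep(seq_len(n_blocks), lengths(check_idx)))
      is_check <- c(rep(FALSE, length(ord)), rep(TRUE, sum(lengths(check_idx))))
      data.frame(
        genotype = geno, year = yr,
        block = sprintf("%s_b%02d", yr, block), is_check = is_check,
        value = base + yeff + beff[block] +
          stats::rnorm(length(base), 0, design$residual_sd),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  }, substream = 4L)
}

#' Write / read the simulation ground-truth sidecar
#'
#' Serializes a [sim_truth()] (QTL positions, effects, target heritability,
#' family offsets) to JSON next to simulated data sets so that recovery
#' tests can compare mapped QTL against the truth.
#'
#' @param truth a [sim_truth()].
#' @param path file path for the JSON sidecar.
#' @return `write_sim_truth()` returns `path` invisibly; `read_sim_truth()`
#'   returns the [sim_truth()].
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(
    list(qtl = truth$qtl, h2 = truth$h2,
         family_offsets = as.list(truth$family_offsets)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  offs <- unlist(x$family_offsets)
  sim_truth(qtl = as.data.frame(x$qtl), h2 = x$h2,
            family_offsets = if (length(offs)) offs else numeric())
}
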