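#' Best linear unbiased estimates of genotype values from a blocked trial
#'
#' Fits the mixed model used for augmented incomplete-block RIL trials:
#' genotype as a fixed effect, year and block-nested-within-year as random
#' intercepts, plot residual
#' \deqn{y_{ijk} = g_i + u_j + b_{jk} + e_{ijk},\quad
#'       u_j \sim N(0,\sigma^2_y),\ b_{jk} \sim N(0,\sigma^2_b),\
#'       e_{ijk} \sim N(0,\sigma^2_e).}
#' Variance components are estimated by REML (via \pkg{lme4}) and genotype
#' estimates are the generalized-least-squares solutions at those
#' components. Because genotype is the only fixed factor the fixed-effect
#' solution equals the least-squares means, so the returned values are the
#' BLUEs on the trait's own scale. With a single year the year component is
#' dropped automatically; replicate plot rows of the same
#' (genotype, year, block) are averaged to one plot value before fitting.
#'
#' The replicated checks are what connect blocks: if no genotype appears in
#' more than one block the design is disconnected and block effects are
#' confounded with genotype effects; a warning is raised and estimates are
#' still returned.
#'
#' @param table plot-level data frame with columns `genotype`, `year`,
#'   `block` and the trait column (see `trait`). Blocks must be uniquely
#'   labelled within year (as produced by [simulate_field_trial()]). An
#'   optional `plot` column identifies plots; rows sharing
#'   (genotype, year, block, plot) — repeat measurements of the plants in
#'   one plot — are averaged before fitting.
#' @param trait name of the trait column (default `"value"`).
#' @return a `blue_table`: list with `blues` (data frame `genotype`,
#'   `blue`, `se`) and `varcomp` (named numeric: `year`, `block_in_year`,
#'   `residual`).
#' @examples
#' truth <- sim_truth(h2 = 0)
#' g <- simulate_ril_family(simulate_map(1, 5, 10, seed = 1), 60, seed = 1)
#' ph <- simulate_phenotype(g, truth, seed = 1)
#' trial <- simulate_field_trial(ph, field_design(block_size = 22,
#'   block_effect_sd = 1, residual_sd = 0.5), seed = 1)
#' fit <- fit_blue(trial)
#' head(fit$blues)
#' @export
fit_blue <- function(table, trait = "value") {
  needed <- c("genotype", "year", "block", trait)
  if (!all(needed %in% names(table))) {
    stop_invalid("table must have columns ", paste(needed, collapse = ", "))
  }
  df <- data.frame(
    genotype = factor(table$genotype),
    year = factor(table$year),
    block = factor(paste(table$year, table$block, sep = ":")),
    y = as.numeric(table[[trait]]),
    stringsAsFactors = FALSE
  )
  if ("plot" %in% names(table)) df$plot <- factor(table$plot)
  df <- df[!is.na(df$y), , drop = FALSE]
  if (!nrow(df)) stop_invalid("no non-missing observations")
  # average plants sampled within a plot to one plot value; without plot
  # labels, replicates within (genotype, year, block) collapse to one row
  df <- if ("plot" %in% names(df)) {
    stats::aggregate(y ~ genotype + year + block + plot, data = df, FUN = mean)
  } else {
    stats::aggregate(y ~ genotype + year + block, data = df, FUN = mean)
  }

  n_year <- nlevels(droplevels(df$year))
  n_block <- nlevels(droplevels(df$block))
  blocks_per_geno <- tapply(df$block, df$genotype, function(b) length(unique(b)))
  if (n_block > 1L && max(blocks_per_geno) == 1L) {
    warning("disconnected design: no genotype is shared across blocks; ",
            "block effects are confounded with genotype estimates")
  }

  rand <- character()
  if (n_year > 1L) rand <- c(rand, "(1 | year)")
  if (n_block > n_year) rand <- c(rand, "(1 | block)")
  p_fixed <- nlevels(droplevels(df$genotype))
  if (nrow(df) - p_fixed <= 0L && length(rand)) {
    stop("zero residual degrees of freedom: ", nrow(df), " plot values for ",
         p_fixed, " genotypes")
  }

  if (length(rand)) {
    form <- stats::as.formula(paste("y ~ 0 + genotype +", paste(rand, collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore",
                                             calc.derivs = FALSE))
    ))
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    getvc <- function(grp) {
      v <- vc$vcov[vc$grp == grp]
      if (length(v)) v[1L] else 0
    }
    varcomp <- c(year = getvc("year"), block_in_year = getvc("block"),
                 residual = stats::sigma(fit)^2)
  } else {
    fit <- stats::lm(y ~ 0 + genotype, data = df)
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    s2 <- if (stats::df.residual(fit) > 0) summary(fit)$sigma^2 else 0
    varcomp <- c(year = 0, block_in_year = 0, residual = s2)
  }
  genos <- sub("^genotype", "", names(est))
  structure(
    list(blues = data.frame(genotype = genos, blue = unname(est),
                            se = unname(se), stringsAsFactors = FALSE),
         varcomp = varcomp),
    class = "blue_table"
  )
}

#' @export
print.blue_table <- function(x, ...) {
  cat("<blue_table> ", nrow(x$blues), " genotype BLUEs\n", sep = "")
  cat(sprintf("  variance components: year %.4g, block-in-year %.4g, residual %.4g\n",
              x$varcomp["year"], x$varcomp["block_in_year"], x$varcomp["residual"]))
  invisible(x)
}
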