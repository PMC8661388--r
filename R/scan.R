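# Single-family stepwise-regression QTL mapping.
#
# The scan regresses the phenotype on each marker's numeric 0/1/2 code
# (plus any already-accepted "conditioned" markers) and records the
# partial F-test p-value for the test marker, exactly as anova(lm(...))
# would report it. Genome-wide significance comes from the permutation
# distribution of the minimum scan p-value, and QTL models are built by
# forward stepwise selection against that threshold.

#' Scan configuration
#'
#' @param n_permutations number of phenotype permutations for the
#'   genome-wide threshold (200 is the standard single-family choice,
#'   1000 per family for joint linkage).
#' @param alpha genome-wide significance level in (0, 1).
#' @param seed integer seed controlling the permutations.
#' @param lod_drop LOD units defining support intervals (default 1).
#' @return a `scan_config` list.
#' @export
scan_config <- function(n_permutations = 200L, alpha = 0.05, seed = 1L, lod_drop = 1) {
  if (n_permutations < 1) stop_invalid("n_permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  if (lod_drop <= 0) stop_invalid("lod_drop must be positive")
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 seed = as.integer(seed), lod_drop = lod_drop),
            class = "scan_config")
}

# Align a phenotype (numeric vector or data.frame genotype/value) to the
# rows of a geno_matrix; returns numeric vector with NAs for absent RILs.
align_pheno <- function(pheno, geno, trait = "value") {
  if (is.data.frame(pheno)) {
    if (!all(c("genotype", trait) %in% names(pheno))) {
      stop_invalid("phenotype data frame needs columns 'genotype' and '", trait, "'")
    }
    y <- pheno[[trait]][match(geno$ril_ids, pheno$genotype)]
  } else {
    y <- as.numeric(pheno)
    if (length(y) != nrow(geno$codes)) {
      stop_invalid("phenotype length does not match the genotype matrix")
    }
  }
  y
}

resolve_markers <- function(markers, map) {
  if (is.null(markers) || length(markers) == 0L) return(integer())
  idx <- if (is.character(markers)) match(markers, map$marker) else as.integer(markers)
  if (anyNA(idx) || any(idx < 1L) || any(idx > nrow(map))) {
    stop_invalid("unknown marker in conditioned set")
  }
  idx
}

#' Per-marker regression scan
#'
#' For every marker not in the conditioned set, fits
#' `phenotype ~ conditioned markers + test marker` with all markers as
#' numeric 0/1/2 covariates and records the partial F-test p-value for the
#' test marker together with the regression LOD score
#' \eqn{\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_{reduced}/\mathrm{RSS}_{full})}.
#' RILs with missing phenotype are dropped throughout; RILs missing the
#' test marker's genotype are dropped for that marker only. A test marker
#' collinear with the conditioned set gets `p = 1` with `collinear = TRUE`.
#'
#' @param pheno numeric phenotype aligned to the rows of `geno`, or a data
#'   frame with columns `genotype` and `value`.
#' @param geno a [geno_matrix()].
#' @param conditioned marker ids (or column indices) already in the model.
#' @return a `scan_result` data frame with columns `marker`, `chr`,
#'   `pos_cM`, `pos_bp`, `p`, `lod`, `n_used`, `collinear`; attributes
#'   `conditioned` and `rss0` carry the reduced-model context.
#' @export
marker_scan <- function(pheno, geno, conditioned = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  y <- align_pheno(pheno, geno)
  keep <- !is.na(y)
  if (sum(keep) < 3L) stop_invalid("need at least 3 RILs with phenotype")
  y <- y[keep]
  if (stats::var(y) == 0) stop("phenotype is constant; scan undefined")
  codes <- geno$codes[keep, , drop = FALSE]
  map <- geno$map
  cond_idx <- resolve_markers(conditioned, map)
  test_idx <- setdiff(seq_len(ncol(codes)), cond_idx)

  n_mark <- length(test_idx)
  p <- rep(NA_real_, n_mark); lod <- rep(NA_real_, n_mark)
  n_used <- rep(NA_integer_, n_mark); collinear <- rep(FALSE, n_mark)

  X0 <- cbind(`(Intercept)` = 1, codes[, cond_idx, drop = FALSE])
  no_na <- !anyNA(codes[, test_idx, drop = FALSE]) && !anyNA(X0)
  if (no_na) {
    q0 <- qr(X0)
    r0 <- q0$rank
    ry <- qr.resid(q0, y)
    rss0 <- sum(ry^2)
    RG <- qr.resid(q0, codes[, test_idx, drop = FALSE])
    sxx <- colSums(RG^2)
    scale <- colSums(codes[, test_idx, drop = FALSE]^2) + 1
    ok <- sxx > 1e-10 * scale
    n <- length(y)
    df2 <- n - r0 - 1L
    if (df2 < 1L) stop("no residual degrees of freedom in the conditional scan")
    cross <- drop(crossprod(RG, ry))
    expl <- ifelse(ok, cross^2 / sxx, 0)
    rss1 <- pmax(rss0 - expl, 0)
    Fst <- expl / (rss1 / df2)
    p <- ifelse(ok, stats::pf(Fst, 1, df2, lower.tail = FALSE), 1)
    lod <- ifelse(ok, (n / 2) * log10(rss0 / rss1), 0)
    n_used <- rep(n, n_mark)
    collinear <- !ok
  } else {
    for (i in seq_along(test_idx)) {
      j <- test_idx[i]
      rows <- stats::complete.cases(cbind(X0, codes[, j]))
      Xr <- X0[rows, , drop = FALSE]
      q0 <- qr(Xr)
      yr <- y[rows]
      ry <- qr.resid(q0, yr)
      rss0 <- sum(ry^2)
      rg <- qr.resid(q0, codes[rows, j])
      sxx <- sum(rg^2)
      n <- sum(rows)
      df2 <- n - q0$rank - 1L
      n_used[i] <- n
      if (sxx <= 1e-10 * (sum(codes[rows, j]^2) + 1) || df2 < 1L) {
        p[i] <- 1; lod[i] <- 0; collinear[i] <- TRUE
        next
      }
      expl <- sum(rg * ry)^2 / sxx
      rss1 <- max(rss0 - expl, 0)
      p[i] <- stats::pf(expl / (rss1 / df2), 1, df2, lower.tail = FALSE)
      lod[i] <- (n / 2) * log10(rss0 / rss1)
    }
  }
  out <- data.frame(
    marker = map$marker[test_idx], chr = map$chr[test_idx],
    pos_cM = map$pos_cM[test_idx], pos_bp = map$pos_bp[test_idx],
    p = p, lod = lod, n_used = n_used, collinear = collinear,
    stringsAsFactors = FALSE
  )
  attr(out, "conditioned") <- map$marker[cond_idx]
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Permutation-derived genome-wide p-value threshold
#'
#' Permutes the phenotype across RILs `n_permutations` times (destroying
#' marker-trait association while preserving the markers' linkage
#' structure), reruns the scan, and records each permutation's minimum
#' p-value. The threshold is the empirical alpha-quantile of those minima,
#' taken as the lower order statistic `ceiling(alpha * n_permutations)`
#' (with 200 permutations at alpha 0.05: the 10th smallest minimum). When
#' a conditioned set is supplied its marker codes are permuted together
#' with the phenotype, preserving their joint relationship.
#'
#' @inheritParams marker_scan
#' @param config a [scan_config()].
#' @return the threshold (numeric scalar) with attribute `min_p` holding
#'   the full permutation minima.
#' @export
permutation_threshold <- function(pheno, geno, conditioned = NULL,
                                  config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  if (config$alpha * config$n_permutations < 1) {
    stop_invalid("n_permutations * alpha < 1: quantile undefined")
  }
  k <- ceiling(config$alpha * config$n_permutations)
  y <- align_pheno(pheno, geno)
  keep <- !is.na(y)
  y <- y[keep]
  codes <- geno$codes[keep, , drop = FALSE]
  map <- geno$map
  cond_idx <- resolve_markers(conditioned, map)
  n <- length(y)
  P <- config$n_permutations
  perms <- with_seed(config$seed,
                     matrix(replicate(P, sample.int(n)), n, P),
                     substream = 5L)
  if (length(cond_idx) == 0L && !anyNA(codes)) {
    yc <- y - mean(y)
    Yp <- matrix(yc[perms], n, P)
    Gc <- sweep(codes, 2L, colMeans(codes))
    sxx <- colSums(Gc^2)
    ok <- sxx > 1e-10 * (colSums(codes^2) + 1)
    syy <- sum(yc^2)
    cross <- crossprod(Yp, Gc)            # P x M
    expl <- sweep(cross^2, 2L, pmax(sxx, 1e-300), `/`)
    expl[, !ok] <- 0
    Fst <- expl * (n - 2) / pmax(syy - expl, 1e-300)
    pmat <- stats::pf(Fst, 1, n - 2, lower.tail = FALSE)
    pmat[, !ok] <- 1
    min_p <- apply(pmat, 1L, min)
  } else {
    g2 <- geno
    g2$codes <- codes
    g2$family <- geno$family[keep]
    g2$ril_ids <- geno$ril_ids[keep]
    min_p <- vapply(seq_len(P), function(b) {
      gp <- g2
      gp$codes[, cond_idx] <- g2$codes[perms[, b], cond_idx]
      min(marker_scan(y[perms[, b]], gp, conditioned = cond_idx)$p)
    }, numeric(1))
  }
  structure(sort(min_p)[k], min_p = min_p)
}

#' Total percent of variation explained by a marker set
#'
#' `100 * R^2` of the joint ordinary-least-squares model of the phenotype
#' on all selected markers (numeric codes, with intercept). An empty
#' marker set returns 0.
#'
#' @inheritParams marker_scan
#' @param markers marker ids or column indices of the selected markers.
#' @return percentage in `[0, 100]`.
#' @export
compute_tpve <- function(pheno, geno, markers = NULL) {
  y <- align_pheno(pheno, geno)
  idx <- resolve_markers(markers, geno$map)
  keep <- !is.na(y) & stats::complete.cases(geno$codes[, idx, drop = FALSE])
  y <- y[keep]
  if (length(idx) == 0L) return(0)
  X <- cbind(1, geno$codes[keep, idx, drop = FALSE])
  rss <- sum(qr.resid(qr(X), y)^2)
  tss <- sum((y - mean(y))^2)
  100 * (1 - rss / tss)
}

#' 1-LOD (or general LOD-drop) support interval around a scan peak
#'
#' Returns the physical extent (Mb) of the maximal contiguous run of
#' markers around `peak_marker`, on its own chromosome, whose LOD score
#' stays within `lod_drop` of the peak's LOD.
#'
#' @param scan a `scan_result` from [marker_scan()] or [joint_scan()].
#' @param peak_marker marker id of the peak (normally the scan's
#'   maximum-LOD marker on its chromosome).
#' @param lod_drop drop in LOD units defining the interval (default 1).
#' @return numeric `c(lo, hi)` in Mb.
#' @export
lod_support_interval <- function(scan, peak_marker, lod_drop = 1) {
  if (lod_drop <= 0) stop_invalid("lod_drop must be positive")
  i <- match(peak_marker, scan$marker)
  if (is.na(i)) stop("peak marker ", peak_marker, " not on scan")
  chr_rows <- scan[scan$chr == scan$chr[i], , drop = FALSE]
  chr_rows <- chr_rows[order(chr_rows$pos_cM, chr_rows$pos_bp), , drop = FALSE]
  j <- match(peak_marker, chr_rows$marker)
  cut <- chr_rows$lod[j] - lod_drop
  lo <- j
  while (lo > 1L && chr_rows$lod[lo - 1L] >= cut) lo <- lo - 1L
  hi <- j
  while (hi < nrow(chr_rows) && chr_rows$lod[hi + 1L] >= cut) hi <- hi + 1L
  c(chr_rows$pos_bp[lo], chr_rows$pos_bp[hi]) / 1e6
}

#' Forward stepwise QTL model building
#'
#' Repeats the scan-and-condition cycle of single-family stepwise
#' regression mapping: scan all markers, take the minimum-p marker (ties
#' broken by lowest chromosome then position), accept it if its p-value
#' beats the genome-wide permutation threshold, add it to the model, and
#' rescan conditioning on everything accepted so far. Stops at the first
#' non-significant scan minimum. Each accepted QTL is reported with the
#' p-value at its acceptance step, its additive effect from the final
#' joint model (trait units per 0/1/2 allele-code unit; positive means the
#' alternative-parent allele raises the trait), the cumulative TPVE of the
#' model up to that step, and a LOD-drop support interval from a final
#' scan conditioned on the other accepted QTL.
#'
#' @inheritParams marker_scan
#' @param config a [scan_config()]; its `seed` drives the permutations.
#' @param threshold optional pre-computed p-value threshold (skips the
#'   permutation step).
#' @param recompute_threshold if `TRUE`, the permutation threshold is
#'   recomputed after each acceptance with the current conditioned set
#'   (permuted together with the phenotype). Default `FALSE`: the
#'   unconditioned threshold is reused across steps.
#' @param max_steps cap on the number of accepted QTL.
#' @return a `qtl_model` data frame (possibly 0 rows) with columns `step`,
#'   `marker`, `family`, `chr`, `peak_Mb`, `p_value`, `tpve`, `effect`,
#'   `ci_lo_Mb`, `ci_hi_Mb`; attributes `threshold`, `r_squared` (final
#'   model R^2) and `n_used`.
#' @examples
#' map <- simulate_map(3, 15, 8, seed = 1)
#' g <- simulate_ril_family(map, 200, seed = 2)
#' truth <- sim_truth(qtl = data.frame(marker_index = 8, effect = 1), h2 = 0.2)
#' ph <- simulate_phenotype(g, truth, seed = 3)
#' fit <- stepwise_qtl(ph, g, scan_config(n_permutations = 100, seed = 4))
#' fit
#' @export
stepwise_qtl <- function(pheno, geno, config = scan_config(), threshold = NULL,
                         recompute_threshold = FALSE, max_steps = Inf) {
  stopifnot(inherits(config, "scan_config"))
  y <- align_pheno(pheno, geno)
  if (is.null(threshold)) {
    threshold <- permutation_threshold(y, geno, conditioned = NULL, config = config)
  }
  thr <- as.numeric(threshold)
  selected <- character()
  accept_p <- numeric()
  repeat {
    if (length(selected) >= max_steps) break
    sc <- marker_scan(y, geno, conditioned = selected)
    sc <- sc[order(sc$p, sc$chr, sc$pos_cM, sc$pos_bp), , drop = FALSE]
    if (nrow(sc) == 0L || sc$p[1L] >= thr) break
    selected <- c(selected, sc$marker[1L])
    accept_p <- c(accept_p, sc$p[1L])
    if (recompute_threshold) {
      thr <- as.numeric(permutation_threshold(y, geno, conditioned = selected,
                                              config = config))
    }
  }
  build_qtl_model(y, geno, selected, accept_p, threshold = thr,
                  lod_drop = config$lod_drop)
}

# Assemble the per-step report for an ordered set of accepted markers.
build_qtl_model <- function(y, geno, selected, accept_p, threshold, lod_drop) {
  map <- geno$map
  fam <- if (length(unique(geno$family)) == 1L) geno$family[1L] else NA_character_
  k <- length(selected)
  if (k == 0L) {
    out <- data.frame(step = integer(), marker = character(), family = character(),
                      chr = integer(), peak_Mb = numeric(), p_value = numeric(),
                      tpve = numeric(), effect = numeric(),
                      ci_lo_Mb = numeric(), ci_hi_Mb = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "threshold") <- threshold
    attr(out, "r_squared") <- 0
    class(out) <- c("qtl_model", "data.frame")
    return(out)
  }
  idx <- resolve_markers(selected, map)
  keep <- !is.na(y) & stats::complete.cases(geno$codes[, idx, drop = FALSE])
  X <- cbind(1, geno$codes[keep, idx, drop = FALSE])
  fit <- stats::lm.fit(X, y[keep])
  effects <- fit$coefficients[-1L]
  tpve <- vapply(seq_len(k), function(s) compute_tpve(y, geno, selected[seq_len(s)]),
                 numeric(1))
  ci <- t(vapply(seq_len(k), function(s) {
    csc <- marker_scan(y, geno, conditioned = setdiff(selected, selected[s]))
    lod_support_interval(csc, selected[s], lod_drop)
  }, numeric(2)))
  out <- data.frame(
    step = seq_len(k), marker = selected, family = fam,
    chr = map$chr[idx], peak_Mb = map$pos_bp[idx] / 1e6,
    p_value = accept_p, tpve = tpve, effect = unname(effects),
    ci_lo_Mb = ci[, 1L], ci_hi_Mb = ci[, 2L], stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  attr(out, "r_squared") <- tpve[k] / 100
  attr(out, "n_used") <- sum(keep)
  class(out) <- c("qtl_model", "data.frame")
  out
}

#' @export
print.qtl_model <- function(x, ...) {
  cat("<qtl_model> ", nrow(x), " QTL; permutation threshold p < ",
      format(attr(x, "threshold"), digits = 3), "\n", sep = "")
  if (nrow(x)) print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
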