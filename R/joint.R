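# Joint-linkage mapping across NAM families.
#
# The joint model carries a family mean term plus marker effects nested
# within family: y ~ family + marker:family. The family term absorbs
# between-family mean differences, and the nested slopes let each family
# carry its own QTL allele effect against the common parent. Each marker
# is tested by the partial F-test of its block of family-nested slopes.

# One indicator column per family level (works for a single family too,
# where model.matrix's contrast machinery would balk).
family_indicators <- function(family) {
  f <- factor(family)
  X <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  X[cbind(seq_along(f), as.integer(f))] <- 1
  X
}

# Family-nested design columns for one marker: code * family indicator for
# every family in which the marker segregates (within-family variance > 0).
nested_columns <- function(x, fam_list) {
  cols <- lapply(fam_list, function(rows) {
    z <- numeric(length(x))
    z[rows] <- x[rows]
    z
  })
  seg <- vapply(fam_list, function(rows) {
    v <- x[rows]
    length(unique(v[!is.na(v)])) > 1L
  }, logical(1))
  list(cols = do.call(cbind, cols[seg]), families = names(fam_list)[seg])
}

#' Joint-linkage marker scan with family-nested effects
#'
#' For each marker not in the conditioned set, fits
#' `phenotype ~ family + (conditioned markers):family + (test marker):family`
#' and records the partial F-test p-value for the block of family-nested
#' test-marker slopes (one slope per family in which the marker
#' segregates; non-segregating families are dropped from the block and
#' flagged via `df1`). With a single family the model reduces exactly to
#' [marker_scan()]. LOD is the regression LOD of the full vs reduced
#' model.
#'
#' @inheritParams marker_scan
#' @param geno a multi-family [geno_matrix()].
#' @return a `scan_result` data frame as in [marker_scan()], with an extra
#'   column `df1` (size of the tested block).
#' @export
joint_scan <- function(pheno, geno, conditioned = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  y <- align_pheno(pheno, geno)
  keep <- !is.na(y)
  if (sum(keep) < 3L) stop_invalid("need at least 3 RILs with phenotype")
  y <- y[keep]
  if (stats::var(y) == 0) stop("phenotype is constant; scan undefined")
  codes <- geno$codes[keep, , drop = FALSE]
  family <- geno$family[keep]
  map <- geno$map
  cond_idx <- resolve_markers(conditioned, map)
  test_idx <- setdiff(seq_len(ncol(codes)), cond_idx)
  fam_list <- split(seq_along(family), family)
  n <- length(y)

  # reduced-model design: family means + nested slopes of conditioned markers
  X0 <- family_indicators(family)
  for (j in cond_idx) {
    nc <- nested_columns(codes[, j], fam_list)
    if (!is.null(nc$cols)) X0 <- cbind(X0, nc$cols)
  }
  if (anyNA(X0)) stop_invalid("conditioned markers must be imputed before the joint scan")
  q0 <- qr(X0)
  r0 <- q0$rank
  ry <- qr.resid(q0, y)
  rss0 <- sum(ry^2)

  n_mark <- length(test_idx)
  p <- rep(1, n_mark); lod <- rep(0, n_mark); df1 <- rep(0L, n_mark)
  collinear <- rep(FALSE, n_mark); n_used <- rep(n, n_mark)
  for (i in seq_along(test_idx)) {
    x <- codes[, test_idx[i]]
    if (anyNA(x)) {
      rows <- !is.na(x)
      # refit reduced model on the complete rows for this marker
      q0i <- qr(X0[rows, , drop = FALSE])
      ryi <- qr.resid(q0i, y[rows])
      rss0i <- sum(ryi^2)
      nc <- nested_columns(x[rows], lapply(fam_list, function(r) {
        match(intersect(r, which(rows)), which(rows))
      }))
      res <- nested_block_test(nc, q0i, ryi, rss0i, sum(rows), q0i$rank)
      n_used[i] <- sum(rows)
    } else {
      nc <- nested_columns(x, fam_list)
      res <- nested_block_test(nc, q0, ry, rss0, n, r0)
    }
    p[i] <- res$p; lod[i] <- res$lod; df1[i] <- res$df1; collinear[i] <- res$collinear
  }
  out <- data.frame(
    marker = map$marker[test_idx], chr = map$chr[test_idx],
    pos_cM = map$pos_cM[test_idx], pos_bp = map$pos_bp[test_idx],
    p = p, lod = lod, n_used = n_used, df1 = df1, collinear = collinear,
    stringsAsFactors = FALSE
  )
  attr(out, "conditioned") <- map$marker[cond_idx]
  class(out) <- c("scan_result", "data.frame")
  out
}

# Partial F-test of one marker's nested-slope block given the reduced-model
# QR decomposition and residuals.
nested_block_test <- function(nc, q0, ry, rss0, n, r0) {
  if (is.null(nc$cols)) {
    return(list(p = 1, lod = 0, df1 = 0L, collinear = TRUE))
  }
  Z <- qr.resid(q0, nc$cols)
  # drop columns absorbed by the reduced model (qr()'s rank check compares
  # a pivoted column against its own starting norm, so a column that is
  # tiny from the outset would still be counted)
  absorbed <- colSums(Z^2) <= 1e-16 * (colSums(nc$cols^2) + 1)
  Z <- Z[, !absorbed, drop = FALSE]
  if (ncol(Z) == 0L) return(list(p = 1, lod = 0, df1 = 0L, collinear = TRUE))
  qz <- qr(Z)
  q <- qz$rank
  if (q == 0L) return(list(p = 1, lod = 0, df1 = 0L, collinear = TRUE))
  expl <- sum(qr.qty(qz, ry)[seq_len(q)]^2)
  rss1 <- rss0 - expl
  df2 <- n - r0 - q
  if (df2 < 1L || rss1 <= 0) {
    return(list(p = 0, lod = Inf, df1 = as.integer(q), collinear = FALSE))
  }
  Fst <- (expl / q) / (rss1 / df2)
  list(p = stats::pf(Fst, q, df2, lower.tail = FALSE),
       lod = (n / 2) * log10(rss0 / rss1),
       df1 = as.integer(q), collinear = FALSE)
}

#' Within-family permutation threshold for joint-linkage scans
#'
#' Permutes the phenotype within each family independently (preserving
#' every family's mean exactly, hence the family term of the joint model),
#' reruns the unconditioned [joint_scan()], and records the genome-wide
#' minimum p-value of each permutation. The threshold is the lower order
#' statistic `ceiling(alpha * n_permutations)` of those minima.
#'
#' @inheritParams joint_scan
#' @param config a [scan_config()] (1000 permutations per family is the
#'   standard joint-linkage choice).
#' @return threshold with attribute `min_p`, as [permutation_threshold()].
#' @export
joint_permutation_threshold <- function(pheno, geno, config = scan_config(1000L)) {
  stopifnot(inherits(config, "scan_config"))
  if (config$alpha * config$n_permutations < 1) {
    stop_invalid("n_permutations * alpha < 1: quantile undefined")
  }
  k <- ceiling(config$alpha * config$n_permutations)
  y <- align_pheno(pheno, geno)
  keep <- !is.na(y)
  y <- y[keep]
  codes <- geno$codes[keep, , drop = FALSE]
  family <- geno$family[keep]
  fam_list <- split(seq_along(family), family)
  n <- length(y)
  P <- config$n_permutations
  perms <- with_seed(config$seed, {
    # permute row indices within each family block, jointly for all perms
    m <- matrix(seq_len(n), n, P)
    for (rows in fam_list) {
      m[rows, ] <- vapply(seq_len(P), function(b) rows[sample.int(length(rows))],
                          integer(length(rows)))
    }
    m
  }, substream = 6L)
  if (!anyNA(codes)) {
    # within-family centering == residual on the family-means model; the
    # nested block columns are family-disjoint, so the block F statistic
    # decomposes into per-family simple-regression contributions
    yc <- y
    Gc <- codes
    for (rows in fam_list) {
      yc[rows] <- y[rows] - mean(y[rows])
      Gc[rows, ] <- sweep(codes[rows, , drop = FALSE], 2L,
                          colMeans(codes[rows, , drop = FALSE]))
    }
    rss0 <- sum(yc^2)
    M <- ncol(codes)
    expl <- matrix(0, P, M)
    qmat <- integer(M)
    for (f in seq_along(fam_list)) {
      rows <- fam_list[[f]]
      Gf <- Gc[rows, , drop = FALSE]
      sxx <- colSums(Gf^2)
      seg <- sxx > 1e-10 * (colSums(codes[rows, , drop = FALSE]^2) + 1)
      qmat <- qmat + as.integer(seg)
      Yp <- matrix(yc[perms[rows, , drop = FALSE]], length(rows), P)
      cr <- crossprod(Yp, Gf)             # P x M
      contrib <- sweep(cr^2, 2L, pmax(sxx, 1e-300), `/`)
      contrib[, !seg] <- 0
      expl <- expl + contrib
    }
    nfam <- length(fam_list)
    df2 <- matrix(rep(n - nfam - qmat, each = P), P, ncol(codes))
    Fst <- sweep(expl, 2L, pmax(qmat, 1L), `/`) / ((rss0 - expl) / df2)
    pmat <- stats::pf(Fst, matrix(rep(qmat, each = P), P, ncol(codes)), df2,
                      lower.tail = FALSE)
    pmat[, qmat == 0L] <- 1
    min_p <- apply(pmat, 1L, min)
  } else {
    g2 <- geno
    g2$codes <- codes
    g2$family <- family
    g2$ril_ids <- geno$ril_ids[keep]
    min_p <- vapply(seq_len(P), function(b) {
      min(joint_scan(y[perms[, b]], g2)$p)
    }, numeric(1))
  }
  structure(sort(min_p)[k], min_p = min_p)
}

#' Joint-linkage stepwise QTL model
#'
#' Forward selection on [joint_scan()] p-values against a within-family
#' permutation threshold ([joint_permutation_threshold()]). Each accepted
#' QTL is reported once, assigned to the family whose nested effect has
#' the smallest marginal p-value in the final model (the full per-family
#' effect table is kept in the `nested_effects` attribute), with the
#' cumulative TPVE computed as the percent of within-family phenotypic
#' variation (residual variation of the family-means model) explained by
#' the QTL terms up to that step, and a LOD-drop support interval from a
#' final joint scan conditioned on the other accepted QTL.
#'
#' @inheritParams joint_scan
#' @param config a [scan_config()].
#' @param threshold optional pre-computed threshold.
#' @param max_steps cap on accepted QTL.
#' @return a `joint_model` (also `qtl_model`) data frame with the same
#'   columns as [stepwise_qtl()]; attributes `threshold`, `r_squared`,
#'   `nested_effects` (list of per-family effect tables, one per QTL).
#' @export
joint_stepwise <- function(pheno, geno, config = scan_config(1000L),
                           threshold = NULL, max_steps = Inf) {
  stopifnot(inherits(config, "scan_config"))
  y <- align_pheno(pheno, geno)
  if (is.null(threshold)) {
    threshold <- joint_permutation_threshold(y, geno, config = config)
  }
  thr <- as.numeric(threshold)
  selected <- character()
  accept_p <- numeric()
  repeat {
    if (length(selected) >= max_steps) break
    sc <- joint_scan(y, geno, conditioned = selected)
    sc <- sc[order(sc$p, sc$chr, sc$pos_cM, sc$pos_bp), , drop = FALSE]
    if (nrow(sc) == 0L || sc$p[1L] >= thr) break
    selected <- c(selected, sc$marker[1L])
    accept_p <- c(accept_p, sc$p[1L])
  }
  build_joint_model(y, geno, selected, accept_p, threshold = thr,
                    lod_drop = config$lod_drop)
}

build_joint_model <- function(y, geno, selected, accept_p, threshold, lod_drop) {
  map <- geno$map
  k <- length(selected)
  empty <- data.frame(step = integer(), marker = character(), family = character(),
                      chr = integer(), peak_Mb = numeric(), p_value = numeric(),
                      tpve = numeric(), effect = numeric(),
                      ci_lo_Mb = numeric(), ci_hi_Mb = numeric(),
                      stringsAsFactors = FALSE)
  if (k == 0L) {
    attr(empty, "threshold") <- threshold
    attr(empty, "r_squared") <- 0
    attr(empty, "nested_effects") <- list()
    class(empty) <- c("joint_model", "qtl_model", "data.frame")
    return(empty)
  }
  keep <- !is.na(y)
  yk <- y[keep]
  codes <- geno$codes[keep, , drop = FALSE]
  family <- geno$family[keep]
  fam_list <- split(seq_along(family), family)
  idx <- resolve_markers(selected, map)
  Xf <- family_indicators(family)
  rss_fam <- sum(qr.resid(qr(Xf), yk)^2)

  # final joint model: family means + nested slopes of every accepted QTL
  X <- Xf
  col_info <- data.frame(qtl = integer(), family = character(), stringsAsFactors = FALSE)
  for (s in seq_len(k)) {
    nc <- nested_columns(codes[, idx[s]], fam_list)
    X <- cbind(X, nc$cols)
    col_info <- rbind(col_info, data.frame(qtl = s, family = nc$families,
                                           stringsAsFactors = FALSE))
  }
  fit <- stats::lm.fit(X, yk)
  dfres <- length(yk) - fit$rank
  s2 <- sum(fit$residuals^2) / max(dfres, 1L)
  coefs <- fit$coefficients            # NA for aliased columns
  ok <- !is.na(coefs)
  se <- rep(NA_real_, ncol(X))
  XtXi <- tryCatch(chol2inv(chol(crossprod(X[, ok, drop = FALSE]))),
                   error = function(e) NULL)
  if (!is.null(XtXi)) se[ok] <- sqrt(s2 * diag(XtXi))
  nfam_cols <- ncol(Xf)
  nested <- lapply(seq_len(k), function(s) {
    rows <- which(col_info$qtl == s) + nfam_cols
    tstat <- coefs[rows] / se[rows]
    data.frame(family = col_info$family[col_info$qtl == s],
               effect = unname(coefs[rows]), se = unname(se[rows]),
               p = 2 * stats::pt(abs(tstat), dfres, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  pick <- function(d) if (all(is.na(d$p))) 1L else which.min(d$p)
  assigned <- vapply(nested, function(d) d$family[pick(d)], character(1))
  effect <- vapply(nested, function(d) d$effect[pick(d)], numeric(1))

  # cumulative TPVE: share of within-family variation explained at step s
  tpve <- vapply(seq_len(k), function(s) {
    Xs <- Xf
    for (t in seq_len(s)) Xs <- cbind(Xs, nested_columns(codes[, idx[t]], fam_list)$cols)
    rss_s <- sum(qr.resid(qr(Xs), yk)^2)
    100 * (rss_fam - rss_s) / rss_fam
  }, numeric(1))

  ci <- t(vapply(seq_len(k), function(s) {
    csc <- joint_scan(yk, subset_geno(geno, rils = which(keep)),
                      conditioned = setdiff(selected, selected[s]))
    lod_support_interval(csc, selected[s], lod_drop)
  }, numeric(2)))

  out <- data.frame(
    step = seq_len(k), marker = selected, family = assigned,
    chr = map$chr[idx], peak_Mb = map$pos_bp[idx] / 1e6,
    p_value = accept_p, tpve = tpve, effect = effect,
    ci_lo_Mb = ci[, 1L], ci_hi_Mb = ci[, 2L], stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  attr(out, "r_squared") <- tpve[k] / 100
  attr(out, "nested_effects") <- stats::setNames(nested, selected)
  class(out) <- c("joint_model", "qtl_model", "data.frame")
  out
}

#' Remove one family from a NAM genotype/phenotype pair
#'
#' @param geno a multi-family [geno_matrix()].
#' @param pheno phenotype data frame (with `genotype` column) or numeric
#'   vector aligned to `geno`'s rows.
#' @param family_name family to drop.
#' @return list with elements `geno` and `pheno`, rows of the named family
#'   removed from both consistently.
#' @export
drop_family <- function(geno, pheno, family_name) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (!family_name %in% geno$family) stop("unknown family: ", family_name)
  keep <- geno$family != family_name
  g2 <- subset_geno(geno, rils = which(keep))
  p2 <- if (is.data.frame(pheno)) {
    pheno[pheno$genotype %in% g2$ril_ids, , drop = FALSE]
  } else {
    pheno[keep]
  }
  list(geno = g2, pheno = p2)
}
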