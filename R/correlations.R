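#' Holm step-down adjustment of p-values
#'
#' Familywise-error control by Holm's sequentially rejective procedure:
#' sort the m p-values ascending and set
#' `adjusted_(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))`, returning
#' the values in the original order. Delegates to
#' `stats::p.adjust(method = "holm")` after validating the input.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA`s pass through).
#' @return adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Pearson correlation matrix over trait means with Holm adjustment
#'
#' Computes all pairwise Pearson correlations among the requested trait
#' columns of a genotype-by-trait table of mean values. Each pair uses the
#' genotypes where both traits are observed (pairwise-complete, the
#' default) or, with `use = "listwise"`, only genotypes complete for every
#' requested trait. Two-sided p-values come from the t-distribution with
#' `n - 2` degrees of freedom, and Holm's adjustment is applied across all
#' off-diagonal pairs tested. A trait with zero variance on a pair's
#' complete subset yields an undefined `r`, reported as `NA` with
#' `degenerate = TRUE`.
#'
#' @param traits data frame of genotype-level trait means; one column per
#'   trait.
#' @param trait_names columns to correlate (default: all numeric columns).
#' @param use `"pairwise"` (default) or `"listwise"` complete observations.
#' @return a `correlation_result`: long data frame with columns `trait_a`,
#'   `trait_b`, `n_used`, `r`, `p_raw`, `p_holm`, `degenerate`, plus a
#'   symmetric correlation matrix (diagonal 1) in the `r_matrix` attribute.
#' @examples
#' set.seed(1)
#' d <- data.frame(d13C = rnorm(50))
#' d$Mo <- 0.2 * d$d13C + rnorm(50)
#' pearson_matrix(d)
#' @export
pearson_matrix <- function(traits, trait_names = NULL, use = c("pairwise", "listwise")) {
  use <- match.arg(use)
  if (is.null(trait_names)) {
    trait_names <- names(traits)[vapply(traits, is.numeric, logical(1))]
  }
  if (length(trait_names) < 2L) stop_invalid("need at least two traits")
  if (!all(trait_names %in% names(traits))) stop_invalid("unknown trait column")
  x <- as.matrix(traits[, trait_names, drop = FALSE])
  if (use == "listwise") x <- x[stats::complete.cases(x), , drop = FALSE]
  pairs <- utils::combn(trait_names, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- x[, pairs[1L, i]]; b <- x[, pairs[2L, i]]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    if (n < 3L) stop_invalid("fewer than 3 complete pairs for ",
                             pairs[1L, i], " vs ", pairs[2L, i])
    if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) {
      return(data.frame(trait_a = pairs[1L, i], trait_b = pairs[2L, i],
                        n_used = n, r = NA_real_, p_raw = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    r <- stats::cor(a[ok], b[ok])
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- if (abs(r) == 1) 0 else 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
    data.frame(trait_a = pairs[1L, i], trait_b = pairs[2L, i], n_used = n,
               r = r, p_raw = p, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- holm_adjust(out$p_raw)
  out <- out[, c("trait_a", "trait_b", "n_used", "r", "p_raw", "p_holm", "degenerate")]
  rmat <- diag(1, length(trait_names))
  dimnames(rmat) <- list(trait_names, trait_names)
  for (i in seq_len(nrow(out))) {
    rmat[out$trait_a[i], out$trait_b[i]] <- out$r[i]
    rmat[out$trait_b[i], out$trait_a[i]] <- out$r[i]
  }
  attr(out, "r_matrix") <- rmat
  class(out) <- c("correlation_result", "data.frame")
  out
}
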