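#' RIL genotype matrix
#'
#' Container for numeric RIL genotypes in the biparental coding used
#' throughout the package: 0 = homozygous for the common (reference)
#' parent, 1 = heterozygous, 2 = homozygous for the family's alternative
#' parent, `NA` = missing. Rows are RILs, columns are the markers of a
#' [genetic_map()].
#'
#' @param codes integer/numeric matrix (RIL x marker) over `{0, 1, 2, NA}`.
#' @param map the [genetic_map()] describing the columns.
#' @param ril_ids character RIL ids (row names); defaults to `RIL_0001 ...`.
#' @param family character family label per RIL (recycled if length 1).
#' @param parents data frame with columns `family`, `reference_parent`,
#'   `alternative_parent`; defaults to B73 vs one unnamed donor per family.
#' @return a `geno_matrix` object (list with elements `codes`, `map`,
#'   `ril_ids`, `family`, `parents`).
#' @export
geno_matrix <- function(codes, map, ril_ids = NULL, family = "F1", parents = NULL) {
  codes <- as.matrix(codes)
  if (ncol(codes) != nrow(map)) stop_invalid("column count does not match the map")
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad)) stop_invalid("genotype codes must be 0, 1, 2 or NA")
  n <- nrow(codes)
  if (is.null(ril_ids)) ril_ids <- sprintf("RIL_%04d", seq_len(n))
  if (length(ril_ids) != n) stop_invalid("ril_ids length does not match rows")
  if (anyDuplicated(ril_ids)) stop_invalid("ril_ids must be unique")
  if (length(family) == 1L) family <- rep(family, n)
  if (length(family) != n) stop_invalid("family labels must cover every RIL")
  fams <- unique(family)
  if (is.null(parents)) {
    parents <- data.frame(
      family = fams, reference_parent = "B73",
      alternative_parent = paste0(fams, "_donor"), stringsAsFactors = FALSE
    )
  }
  dimnames(codes) <- list(ril_ids, map$marker)
  structure(
    list(codes = codes, map = map, ril_ids = as.character(ril_ids),
         family = as.character(family), parents = parents),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  fams <- table(x$family)
  cat("<geno_matrix> ", nrow(x$codes), " RILs x ", ncol(x$codes), " markers on ",
      length(unique(x$map$chr)), " chromosome(s)\n", sep = "")
  cat("  families: ", paste(names(fams), " (", fams, ")", sep = "", collapse = ", "), "\n", sep = "")
  miss <- mean(is.na(x$codes))
  cat(sprintf("  missing: %.2f%%  heterozygous: %.2f%%\n",
              100 * miss, 100 * mean(x$codes == 1, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param rils logical/integer/character index of RILs to keep.
#' @param markers logical/integer/character index of markers to keep.
#' @return a `geno_matrix` restricted to the selection.
#' @export
subset_geno <- function(x, rils = NULL, markers = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  codes <- x$codes
  family <- x$family
  map <- x$map
  if (!is.null(rils)) {
    if (is.character(rils)) rils <- match(rils, x$ril_ids)
    codes <- codes[rils, , drop = FALSE]
    family <- family[rils]
  }
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, map$marker)
    codes <- codes[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
    class(map) <- c("genetic_map", "data.frame")
  }
  geno_matrix(codes, map, ril_ids = rownames(codes), family = family,
              parents = x$parents[x$parents$family %in% unique(family), , drop = FALSE])
}
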