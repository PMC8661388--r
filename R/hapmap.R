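# HapMap text I/O and biparental numeric recoding.
#
# HapMap genotype files are tab-delimited with 11 marker-metadata columns
# (rs#, alleles, chrom, pos, strand, assembly#, center, protLSID, assayLSID,
# panelLSID, QCcode) followed by one column of calls per sample. Two call
# dialects circulate: two-letter diploid calls ("AA", "AT", "NN") and
# single-letter calls where heterozygotes are IUPAC ambiguity codes
# ("A", "W", "N"). Both are accepted; strand is ignored.

HAPMAP_META <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

IUPAC_HET <- c(AC = "M", CA = "M", AG = "R", GA = "R", AT = "W", TA = "W",
               CG = "S", GC = "S", CT = "Y", TC = "Y", GT = "K", TG = "K")

#' Read a HapMap-format genotype file
#'
#' Parses the standard 11-metadata-column HapMap layout and returns the
#' marker map together with the raw calls, preserved verbatim. Markers are
#' returned sorted by (chromosome, position); if the input was unsorted a
#' warning is raised. Genetic positions, which HapMap files do not carry,
#' are taken as `pos / 1e6` cM (exact for files written by
#' [write_hapmap()], which places markers at 1 Mb per cM).
#'
#' @param path path to a tab-delimited HapMap text file.
#' @return list with elements `map` (a [genetic_map()]) and `calls`
#'   (character matrix, markers x samples, dimnames set).
#' @export
read_hapmap <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop_invalid("HapMap file has no marker rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 12L || tolower(header[1L]) != "rs#") {
    stop("malformed HapMap header at line 1: expected 11 metadata columns ",
         "starting with 'rs#' plus at least one sample column")
  }
  n_col <- length(header)
  ragged <- setdiff(which(lengths(fields) != n_col), 1L)
  if (length(ragged)) {
    stop("ragged HapMap row at line ", ragged[1L], ": expected ", n_col,
         " fields, found ", lengths(fields)[ragged[1L]])
  }
  body <- do.call(rbind, fields[-1L])
  chr <- suppressWarnings(as.integer(body[, 3L]))
  pos <- suppressWarnings(as.numeric(body[, 4L]))
  if (anyNA(chr) || anyNA(pos)) {
    bad <- which(is.na(chr) | is.na(pos))[1L] + 1L
    stop("non-numeric chrom/pos in HapMap file at line ", bad)
  }
  ord <- order(chr, pos)
  if (any(ord != seq_along(ord))) {
    warning("HapMap markers were not sorted by (chromosome, position); sorting")
  }
  body <- body[ord, , drop = FALSE]
  calls <- body[, 12:n_col, drop = FALSE]
  dimnames(calls) <- list(body[, 1L], header[12:n_col])
  map <- genetic_map(marker = body[, 1L], chr = chr[ord],
                     pos_cM = pos[ord] / 1e6, pos_bp = pos[ord])
  list(map = map, calls = calls)
}

#' Write a genotype matrix as HapMap text
#'
#' Numeric 0/1/2 codes are rendered as nucleotide calls using per-marker
#' reference/alternative alleles (`A`/`T` throughout by default, matching
#' [encode_numeric()]'s defaults on round-trip). Missing codes become `N`.
#'
#' @param geno a [geno_matrix()].
#' @param path output file path.
#' @param ref_allele,alt_allele single letters (recycled per marker) for
#'   the reference (code 0) and alternative (code 2) homozygotes.
#' @param diploid if `TRUE` write two-letter calls ("AA", "AT", "NN");
#'   otherwise single-letter calls with IUPAC heterozygotes.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(geno, path, ref_allele = "A", alt_allele = "T",
                         diploid = FALSE) {
  stopifnot(inherits(geno, "geno_matrix"))
  m <- nrow(geno$map)
  ref <- rep(ref_allele, length.out = m)
  alt <- rep(alt_allele, length.out = m)
  codes <- t(geno$codes)  # markers x samples
  calls <- matrix("", nrow(codes), ncol(codes))
  for (j in seq_len(ncol(codes))) {
    x <- codes[, j]
    calls[, j] <- if (diploid) {
      ifelse(is.na(x), "NN",
             ifelse(x == 0, paste0(ref, ref),
                    ifelse(x == 2, paste0(alt, alt), paste0(ref, alt))))
    } else {
      ifelse(is.na(x), "N",
             ifelse(x == 0, ref,
                    ifelse(x == 2, alt, unname(IUPAC_HET[paste0(ref, alt)]))))
    }
  }
  meta <- cbind(geno$map$marker, paste0(ref, "/", alt), geno$map$chr,
                format(geno$map$pos_bp, scientific = FALSE, trim = TRUE),
                "+", "NA", "NA", "NA", "NA", "NA", "NA")
  out <- rbind(c(HAPMAP_META, rownames(geno$codes)), cbind(meta, calls))
  writeLines(apply(out, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Convert HapMap calls to biparental numeric codes
#'
#' Implements the standard NAM coding: 0 for the homozygous common-parent
#' (reference, e.g. B73) call, 1 for a heterozygote, 2 for the homozygous
#' alternative-parent call. Calls matching neither parent allele are set to
#' missing and counted; markers where the two parents carry the same allele
#' are dropped with a warning (uninformative in a biparental family).
#'
#' @param calls character matrix markers x samples (from [read_hapmap()]).
#' @param ref_alleles,alt_alleles single letters per marker (recycled) for
#'   the reference and alternative parent.
#' @return numeric matrix markers x samples over `{0, 1, 2, NA}`, with an
#'   attribute `n_nonparental` counting calls that matched neither parent.
#' @export
encode_numeric <- function(calls, ref_alleles = "A", alt_alleles = "T") {
  calls <- as.matrix(calls)
  m <- nrow(calls)
  ref <- toupper(rep(ref_alleles, length.out = m))
  alt <- toupper(rep(alt_alleles, length.out = m))
  mono <- ref == alt
  if (any(mono)) {
    warning("dropping ", sum(mono), " marker(s) monomorphic between parents: ",
            paste(utils::head(rownames(calls)[mono], 5L), collapse = ", "))
    calls <- calls[!mono, , drop = FALSE]
    ref <- ref[!mono]; alt <- alt[!mono]
    m <- nrow(calls)
  }
  het1 <- unname(IUPAC_HET[paste0(ref, alt)])  # single-letter het code per marker
  out <- matrix(NA_real_, m, ncol(calls), dimnames = dimnames(calls))
  n_nonparental <- 0L
  for (i in seq_len(m)) {
    x <- toupper(calls[i, ])
    two <- nchar(x) == 2L
    a1 <- substr(x, 1L, 1L)
    a2 <- ifelse(two, substr(x, 2L, 2L), a1)
    code <- rep(NA_real_, length(x))
    is_missing <- x %in% c("N", "NN", "-", "--", "", "NA")
    hom_ref <- a1 == ref[i] & a2 == ref[i]
    hom_alt <- a1 == alt[i] & a2 == alt[i]
    het <- (two & ((a1 == ref[i] & a2 == alt[i]) | (a1 == alt[i] & a2 == ref[i]))) |
      (!two & !is.na(het1[i]) & x == het1[i])
    code[hom_ref] <- 0; code[hom_alt] <- 2; code[het] <- 1
    n_nonparental <- n_nonparental +
      sum(!is_missing & is.na(code))
    out[i, ] <- code
  }
  if (n_nonparental > 0L) {
    message(n_nonparental, " call(s) matched neither parent allele; set to missing")
  }
  structure(out, n_nonparental = n_nonparental)
}

#' Filter markers by minor allele frequency
#'
#' MAF is computed on non-missing allele counts (a heterozygous code 1
#' contributes one allele of each parent). Markers with MAF strictly below
#' `threshold` are removed; a marker exactly at the threshold is retained.
#'
#' @param geno a [geno_matrix()].
#' @param threshold MAF cutoff in `[0, 0.5]` (default 0.05).
#' @return a filtered [geno_matrix()] (possibly with zero markers).
#' @export
filter_maf <- function(geno, threshold = 0.05) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (threshold < 0 || threshold > 0.5) stop_invalid("threshold must lie in [0, 0.5]")
  codes <- geno$codes
  n_obs <- colSums(!is.na(codes))
  alt_freq <- colSums(codes, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  maf <- pmin(alt_freq, 1 - alt_freq)
  maf[n_obs == 0L] <- 0
  keep <- maf >= threshold
  subset_geno(geno, markers = which(keep))
}

#' Impute missing genotype codes from flanking markers
#'
#' Each missing cell is replaced by its expected code given the nearest
#' informative flanking markers on the same chromosome within the same RIL,
#' under the two-state RIL transmission model: a neighbour at code `v` and
#' RIL recombination fraction `R` (from [ril_R()] on the Haldane-mapped cM
#' distance) implies alternative-allele probability
#' `p = (v/2)(1-R) + (1-v/2)R`; left and right neighbours combine
#' multiplicatively under the Markov assumption, and the expected code `2p`
#' is rounded to the nearest of `{0, 1, 2}`. Cells with no informative
#' marker on their chromosome within their family fall back to the rounded
#' cross-family mean code for that marker, with a warning naming marker and
#' family (the rectangular code matrix cannot drop a marker for a single
#' family). Observed codes are never altered.
#'
#' @param geno a [geno_matrix()].
#' @return a [geno_matrix()] with no missing codes and a logical attribute
#'   `imputed` (same shape as the codes) flagging filled cells.
#' @export
impute_missing <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  codes <- geno$codes
  imputed <- is.na(codes)
  if (!any(imputed)) {
    out <- geno
    attr(out, "imputed") <- imputed
    return(out)
  }
  map <- geno$map
  fallback_warned <- character()
  for (i in which(rowSums(is.na(codes)) > 0L)) {
    row <- codes[i, ]
    for (j in which(is.na(row))) {
      ch <- map$chr[j]
      on_chr <- which(map$chr == ch & !is.na(row))
      left <- on_chr[on_chr < j]
      right <- on_chr[on_chr > j]
      left <- if (length(left)) max(left) else NA_integer_
      right <- if (length(right)) min(right) else NA_integer_
      p_from <- function(k) {
        R <- ril_R(haldane_r(abs(map$pos_cM[j] - map$pos_cM[k])))
        pv <- row[k] / 2
        pv * (1 - R) + (1 - pv) * R
      }
      if (is.na(left) && is.na(right)) {
        mk <- map$marker[j]; fam <- geno$family[i]
        key <- paste(mk, fam)
        if (!key %in% fallback_warned) {
          warning("marker ", mk, " has no informative call for RIL ",
                  geno$ril_ids[i], " (family ", fam,
                  "); filled with cross-family expectation")
          fallback_warned <- c(fallback_warned, key)
        }
        mu <- mean(codes[, j], na.rm = TRUE)
        codes[i, j] <- if (is.nan(mu)) 1 else round(mu)
        next
      }
      p <- if (is.na(right)) {
        p_from(left)
      } else if (is.na(left)) {
        p_from(right)
      } else {
        w_alt <- p_from(left) * p_from(right)
        w_ref <- (1 - p_from(left)) * (1 - p_from(right))
        w_alt / (w_alt + w_ref)
      }
      codes[i, j] <- round(2 * p)
    }
  }
  out <- geno
  out$codes <- codes
  attr(out$codes, "imputed") <- NULL
  attr(out, "imputed") <- imputed
  out
}
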