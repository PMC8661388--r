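#' Genetic map container
#'
#' A genetic map is a data frame with one row per marker and columns
#' `marker` (unique id), `chr` (integer chromosome), `pos_cM` (genetic
#' position, non-decreasing within chromosome) and `pos_bp` (physical
#' position in base pairs, positive and non-decreasing within chromosome).
#'
#' @param marker character vector of unique marker ids.
#' @param chr integer chromosome per marker.
#' @param pos_cM numeric genetic positions (cM).
#' @param pos_bp numeric physical positions (bp).
#' @return a `genetic_map` data frame.
#' @export
genetic_map <- function(marker, chr, pos_cM, pos_bp) {
  m <- data.frame(
    marker = as.character(marker), chr = as.integer(chr),
    pos_cM = as.numeric(pos_cM), pos_bp = as.numeric(pos_bp),
    stringsAsFactors = FALSE
  )
  validate_genetic_map(m)
}

validate_genetic_map <- function(m) {
  if (anyDuplicated(m$marker)) stop_invalid("marker ids must be unique")
  if (any(m$pos_cM < 0)) stop_invalid("genetic positions must be >= 0")
  if (any(m$pos_bp <= 0)) stop_invalid("physical positions must be positive")
  for (ch in unique(m$chr)) {
    i <- m$chr == ch
    if (sum(i) < 2L) stop_invalid("each chromosome needs at least 2 markers")
    if (is.unsorted(m$pos_cM[i]) || is.unsorted(m$pos_bp[i])) {
      stop_invalid("positions must be non-decreasing within chromosome ", ch)
    }
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Simulate a multi-chromosome genetic map
#'
#' Marker spacings are drawn from a moderately dispersed uniform
#' distribution and rescaled so the realized mean adjacent spacing equals
#' `mean_spacing_cM` exactly on every chromosome. Physical positions follow
#' the genetic positions at a constant 1 Mb/cM (only marker order and
#' reported coordinates use them).
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param markers_per_chromosome markers on each chromosome (>= 2).
#' @param mean_spacing_cM target mean adjacent-marker spacing in cM (> 0).
#' @param seed integer seed; identical seeds give identical maps.
#' @return a [genetic_map()] with `n_chromosomes * markers_per_chromosome`
#'   markers named `m0001, m0002, ...` in map order.
#' @examples
#' map <- simulate_map(10, 84, 1.6, seed = 1)  # ~ 840 markers, 1.6 cM apart
#' @export
simulate_map <- function(n_chromosomes, markers_per_chromosome, mean_spacing_cM, seed = 1L) {
  if (n_chromosomes < 1 || markers_per_chromosome < 2) {
    stop_invalid("need >= 1 chromosome and >= 2 markers per chromosome")
  }
  if (mean_spacing_cM <= 0) stop_invalid("mean spacing must be positive")
  with_seed(seed, {
    chr <- rep(seq_len(n_chromosomes), each = markers_per_chromosome)
    pos <- unlist(lapply(seq_len(n_chromosomes), function(ch) {
      gaps <- stats::runif(markers_per_chromosome - 1L, 0.4, 1.6)
      gaps <- gaps * mean_spacing_cM / mean(gaps)  # exact mean spacing
      cumsum(c(0, gaps))
    }), use.names = FALSE)
    genetic_map(
      marker = sprintf("m%04d", seq_along(chr)),
      chr = chr, pos_cM = pos,
      pos_bp = pmax(pos, 1e-3) * 1e6  # 1 Mb per cM; keep positions positive
    )
  }, substream = 1L)
}
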