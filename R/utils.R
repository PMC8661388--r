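# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `substream` offsets the seed so that each
# operation draws from a documented, distinct stream of one user seed.
with_seed <- function(seed, expr, substream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  # keep derived seeds inside 32-bit integer range
  set.seed((as.integer(seed) + 1664525L * as.integer(substream)) %% .Machine$integer.max)
  force(expr)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("namqtl_invalid_parameter", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Haldane map function and RIL recombination
#'
#' `haldane_r()` converts a genetic distance in centimorgan to a per-meiosis
#' recombination fraction under the Haldane (no crossover interference) map
#' function, \eqn{r = (1 - e^{-2d})/2} with \eqn{d} in Morgans. `ril_R()`
#' converts that to the expected proportion of recombinant lines among
#' selfed single-seed-descent RILs, \eqn{R = 2r/(1+2r)}, which accounts for
#' the map expansion accumulated over repeated selfing generations.
#'
#' @param d_cM genetic distance in centimorgan (non-negative).
#' @param r per-meiosis recombination fraction in `[0, 0.5]`.
#' @return numeric vector of fractions in `[0, 0.5]`.
#' @examples
#' haldane_r(10)            # 0.5 * (1 - exp(-0.2))
#' ril_R(haldane_r(10))
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) stop_invalid("genetic distances must be non-negative")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' @rdname haldane_r
#' @export
ril_R <- function(r) {
  if (any(r < 0 | r > 0.5)) stop_invalid("recombination fractions must lie in [0, 0.5]")
  2 * r / (1 + 2 * r)
}
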