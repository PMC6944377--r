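#' Sample crossover positions under the Poisson model
#'
#' Positions along one meiosis, in Morgans from the chromosome start.
#' Inter-arrival distances (including the distance from 0 to the first
#' event) are i.i.d. Exponential with rate 1 per Morgan; sampling stops at
#' the first event beyond `length`.
#'
#' @param length chromosome genetic length, Morgans (>= 0).
#' @return sorted numeric vector of crossover positions in `(0, length)`.
#' @export
sample_poisson_crossovers <- function(length) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) || length < 0) {
    stop("`length` must be a single non-negative number", call. = FALSE)
  }
  cpp_sample_crossovers(length, FALSE, 1, 0)
}

#' Sample crossover positions under the Housworth-Stahl interference model
#'
#' The returned positions are the superposition of (i) a Poisson process
#' with rate `p` per Morgan (crossovers that escape interference) and (ii)
#' a stationary gamma(`nu`, rate `2 * nu * (1 - p)`) chiasma renewal
#' process thinned by independent probability-1/2 coin flips (no chromatid
#' interference).  The long-run mean inter-crossover distance is 1 Morgan.
#' Stationarity of the regulated pathway is achieved by starting the
#' renewal from a burn-in offset of `max(10, 5 / (2 nu (1 - p)))` Morgans
#' before coordinate 0.  With `p = 1` the regulated pathway has zero rate
#' and the sample is pure Poisson.
#'
#' @param length chromosome genetic length, Morgans (>= 0).
#' @param params an [interference_params()] object.
#' @return sorted numeric vector of crossover positions in `(0, length)`.
#' @export
sample_stahl_crossovers <- function(length, params) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) || length < 0) {
    stop("`length` must be a single non-negative number", call. = FALSE)
  }
  if (!inherits(params, "interference_params")) {
    stop("`params` must be an interference_params object", call. = FALSE)
  }
  cpp_sample_crossovers(length, TRUE, params$nu, params$p)
}
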