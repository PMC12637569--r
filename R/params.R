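#' Kinetic and coupling parameters for an RyR2 cluster model
#'
#' Bundles every rate constant and gating rule of the model. Each RyR2 channel
#' is a ring of four two-state subunits (closed = -1, open = +1). A closed
#' subunit opens at rate `kfo * Ca * gamma` and an open subunit closes at rate
#' `kb / gamma`, where `gamma = exp(delta * (s_prev + s_next) + sigma * sum of
#' inter-channel contact states)` is the cooperativity factor and `Ca` is the
#' dyadic calcium concentration shared by the whole cluster,
#' `Ca = c0 + g * n_open` (rapid-diffusion approximation).
#'
#' Defaults are the reference parameter set used throughout: they keep single
#' channels reliably shut at diastolic calcium (~0.1 uM) while allowing fast
#' activation at the concentrations reached during L-type channel openings.
#'
#' @param kfo Ca-binding rate constant for subunit opening, per uM per ms.
#' @param kb Ca-independent subunit closing rate, per ms (0.3/ms gives a mean
#'   subunit open time of ~3 ms).
#' @param delta Dimensionless conformational-mismatch penalty (beta * J); it
#'   multiplies the signed sum of neighbour states in the rate exponent.
#' @param sigma Dimensionless inter-channel coupling strength (beta * J', on
#'   the same energetic scale as `delta`), used as the default edge weight
#'   when building coupling graphs. Graphs store a weight per edge, so
#'   unequal contact strengths remain possible.
#' @param g Dyadic calcium increment contributed by one open channel, uM.
#' @param c0 Bulk (diastolic/cytosolic) calcium concentration, uM.
#' @param open_subunit_min Number of open subunits required for a conducting
#'   channel (majority rule; default 3 of 4).
#' @param nc Spark threshold: the spark waiting time is the first time the
#'   open-channel count reaches `nc`.
#'
#' @return An object of class `rate_params` (a validated list).
#' @examples
#' p <- rate_params()
#' local_calcium(3, p)
#' @export
rate_params <- function(kfo = 0.005, kb = 0.3, delta = 0.5, sigma = 0.5,
                        g = 25, c0 = 0.1, open_subunit_min = 3L, nc = 5L) {
  p <- list(kfo = as.numeric(kfo), kb = as.numeric(kb),
            delta = as.numeric(delta), sigma = as.numeric(sigma),
            g = as.numeric(g), c0 = as.numeric(c0),
            open_subunit_min = as.integer(open_subunit_min),
            nc = as.integer(nc))
  validate_rate_params(p)
  class(p) <- "rate_params"
  p
}

validate_rate_params <- function(p) {
  stopifnot(
    is.numeric(p$kfo), length(p$kfo) == 1L, is.finite(p$kfo), p$kfo >= 0,
    is.numeric(p$kb), length(p$kb) == 1L, is.finite(p$kb), p$kb > 0,
    is.numeric(p$delta), length(p$delta) == 1L, is.finite(p$delta),
    is.numeric(p$sigma), length(p$sigma) == 1L, is.finite(p$sigma),
    is.numeric(p$g), length(p$g) == 1L, is.finite(p$g), p$g >= 0,
    is.numeric(p$c0), length(p$c0) == 1L, is.finite(p$c0), p$c0 >= 0,
    length(p$open_subunit_min) == 1L, !is.na(p$open_subunit_min),
    p$open_subunit_min >= 1L, p$open_subunit_min <= 4L,
    length(p$nc) == 1L, !is.na(p$nc), p$nc >= 1L
  )
  invisible(p)
}

#' @method print rate_params
#' @export
print.rate_params <- function(x, ...) {
  cat("RyR2 cluster rate parameters\n")
  cat(sprintf("  kfo   = %g /(uM ms)   kb = %g /ms\n", x$kfo, x$kb))
  cat(sprintf("  delta = %g   sigma = %g\n", x$delta, x$sigma))
  cat(sprintf("  g     = %g uM   c0 = %g uM\n", x$g, x$c0))
  cat(sprintf("  channel open rule: >= %d of 4 subunits; spark threshold nc = %d\n",
              x$open_subunit_min, x$nc))
  invisible(x)
}

#' Dyadic calcium concentration for a given number of open channels
#'
#' Rapid diffusion in the dyadic cleft makes calcium effectively uniform across
#' the cluster, so the local concentration is `c0 + g * n_open`.
#'
#' @param n_open Number of open channels (non-negative; vectorised).
#' @param params A [rate_params()] object supplying `c0` and `g`.
#' @return Calcium concentration(s) in uM.
#' @examples
#' local_calcium(0:3, rate_params(c0 = 0.1, g = 25))
#' @export
local_calcium <- function(n_open, params) {
  validate_rate_params(params)
  if (length(n_open) < 1L || anyNA(n_open) || any(n_open < 0))
    stop("'n_open' must be non-negative")
  params$c0 + params$g * n_open
}
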