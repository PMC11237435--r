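# Synthetic ice forcing: analytic velocity fields with exact strain-rate
# oracles, and flowline-segment scenarios with closed-form solutions.

#' Analytic velocity field sampled on a grid
#'
#' Three textbook fields with known strain rates, for testing the tracing
#' and strain machinery against exact answers: `uniform` (`u = u0, v = v0`,
#' `ezz = 0`), `divergent` (`u = k x, v = 0`, `ezz = -k`) and `rotational`
#' (`u = -k y, v = k x`, `ezz = 0`, circular streamlines).
#'
#' @param kind `"uniform"`, `"divergent"` or `"rotational"`.
#' @param k Field strength (1/yr) for the non-uniform kinds.
#' @param u0,v0 Components of the uniform field (m/yr).
#' @param x,y Grid coordinates (m).
#' @return A [velocity_field()] with attributes `ezz_fn` (exact strain-rate
#'   function of `(x, y)`) and `kind`.
#' @export
make_velocity_field <- function(kind = c("uniform", "divergent", "rotational"),
                                k = 1, u0 = 100, v0 = 0,
                                x = seq(-1e4, 1e4, length.out = 41),
                                y = seq(-1e4, 1e4, length.out = 41)) {
  kind <- match.arg(kind)
  g <- expand.grid(x = x, y = y)
  uv <- switch(kind,
    uniform    = list(u = rep(u0, nrow(g)), v = rep(v0, nrow(g)),
                      ezz = function(x, y) 0),
    divergent  = list(u = k * g$x, v = rep(0, nrow(g)),
                      ezz = function(x, y) -k),
    rotational = list(u = -k * g$y, v = k * g$x,
                      ezz = function(x, y) 0))
  fld <- velocity_field(
    x, y,
    matrix(uv$u, length(y), length(x), byrow = TRUE),
    matrix(uv$v, length(y), length(x), byrow = TRUE))
  attr(fld, "ezz_fn") <- uv$ezz
  attr(fld, "kind") <- kind
  fld
}

#' Synthetic ice forcing scenario
#'
#' Describes segment-level forcing for the layer model. `a` is the
#' accretion rate magnitude (m/yr; applied as basal rate `ab = -a`), `eps`
#' the vertical thinning rate magnitude (1/yr; applied as `ezz = -eps`),
#' `melt_rate` the melting rate during the melt episode, and
#' `episode` the segment-index bounds `c(from, to)` of that episode.
#' `sigma_ab` is the 1-sigma basal-rate uncertainty attached to every
#' segment.
#'
#' Magnitudes of order 1 m/yr and strain rates of order 1e-3/yr are typical
#' of ice-shelf basal mass balance; the `paper_like` scenario is a
#' qualitative synthetic stand-in (accretion early along the flowline, a
#' melt episode near the end), not a reconstruction of any real shelf.
#'
#' @param name One of `constant_accretion`, `steady_strain`,
#'   `accretion_with_melt_episode`, `paper_like`.
#' @param a Accretion-rate magnitude (m/yr).
#' @param eps Thinning-rate magnitude (1/yr).
#' @param n_segments Number of flowline segments.
#' @param dt Segment duration (yr).
#' @param melt_rate Melt-rate magnitude during the episode (m/yr).
#' @param episode Segment-index bounds of the melt episode.
#' @param sigma_ab Basal-rate 1-sigma uncertainty (m/yr).
#' @param seed RNG seed (used by `paper_like` noise).
#' @return An object of class `ice_scenario`.
#' @export
ice_scenario <- function(name = c("constant_accretion", "steady_strain",
                                  "accretion_with_melt_episode", "paper_like"),
                         a = 0.5, eps = 0.005, n_segments = 100, dt = 1,
                         melt_rate = 1, episode = NULL, sigma_ab = 0,
                         seed = 1) {
  name <- match.arg(name)
  stopifnot(a >= 0, eps >= 0, n_segments >= 1, dt > 0, sigma_ab >= 0)
  if (is.null(episode))
    episode <- c(floor(0.8 * n_segments) + 1L, n_segments)
  structure(list(name = name, a = a, eps = eps, n_segments = n_segments,
                 dt = dt, melt_rate = melt_rate, episode = episode,
                 sigma_ab = sigma_ab, seed = seed),
            class = "ice_scenario")
}

#' Generate flowline segments for a synthetic scenario
#'
#' Deterministic under the scenario seed. Where a closed-form solution for
#' the final marine-ice thickness exists it is attached as attribute
#' `closed_form` (a function of transit time `t`):
#' `constant_accretion` gives `H(t) = a t` with linear ages, and
#' `steady_strain` gives `H(t) = (a / eps) (1 - exp(-eps t))`, the solution
#' of `dH/dt = a - eps H`.
#'
#' @param scenario An [ice_scenario()].
#' @return A `flowline_segments` data frame (columns `i, length, x_mid,
#'   y_mid, speed, dt, ab, sigma, ezz`) with attributes `closed_form`
#'   (function or `NULL`) and `scenario`.
#' @export
make_segments <- function(scenario) {
  stopifnot(inherits(scenario, "ice_scenario"))
  n <- scenario$n_segments
  dt <- scenario$dt
  ab <- rep(-scenario$a, n)
  ezz <- rep(0, n)
  closed_form <- NULL
  sc <- scenario
  if (sc$name == "constant_accretion") {
    closed_form <- function(t) sc$a * t
  } else if (sc$name == "steady_strain") {
    ezz <- rep(-sc$eps, n)
    closed_form <- function(t) (sc$a / sc$eps) * (1 - exp(-sc$eps * t))
  } else if (sc$name == "accretion_with_melt_episode") {
    idx <- seq(sc$episode[1], sc$episode[2])
    ab[idx] <- sc$melt_rate
  } else if (sc$name == "paper_like") {
    set.seed(sc$seed)
    # accretion over the first ~60% of the flowline, a melt episode over
    # the last ~20%, weak transition in between; mild seeded variability
    frac <- seq_len(n) / n
    base <- ifelse(frac <= 0.6, -sc$a,
                   ifelse(frac <= 0.8, -0.2 * sc$a, sc$melt_rate))
    ab <- base + stats::rnorm(n, 0, 0.1 * max(sc$a, sc$melt_rate))
    ezz <- rep(-sc$eps, n)
  }
  seg <- data.frame(i = seq_len(n), length = NA_real_, x_mid = NA_real_,
                    y_mid = NA_real_, speed = NA_real_, dt = dt,
                    ab = ab, sigma = sc$sigma_ab, ezz = ezz)
  class(seg) <- c("flowline_segments", "data.frame")
  attr(seg, "closed_form") <- closed_form
  attr(seg, "scenario") <- sc
  seg
}
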