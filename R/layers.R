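#' Marine-ice layer stack
#'
#' Ordered layers of marine ice under the meteoric column. Index 1 is the
#' oldest layer (adjacent to the meteoric ice at the top of the marine
#' column); the last index is the newest ice at the ice-ocean interface.
#' Each layer stores its thickness `h` (m) and the transit-time interval
#' `[tau0, tau]` (yr since departure from the grounding line) over which it
#' accreted; `tau` is the accretion timestamp used for ordering and dating.
#'
#' @param h Layer thicknesses (m), oldest first. All `> 0`.
#' @param tau Accretion timestamps (yr), strictly increasing.
#' @param tau0 Accretion start times (yr); defaults to `tau`.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(h = numeric(), tau = numeric(), tau0 = tau) {
  stopifnot(length(h) == length(tau), length(tau0) == length(tau))
  if (any(h <= 0)) stop("layer_stack: layer thicknesses must be > 0")
  if (length(tau) > 1 && any(diff(tau) <= 0))
    stop("layer_stack: accretion timestamps must be strictly increasing")
  structure(list(h = as.numeric(h), tau = as.numeric(tau),
                 tau0 = as.numeric(tau0)),
            class = "layer_stack")
}

#' Total marine-ice thickness of a stack
#' @param stack A [layer_stack()].
#' @return Total thickness Hm (m).
#' @export
total_thickness <- function(stack) sum(stack$h)

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layers, Hm = %.3f m\n",
              length(x$h), total_thickness(x)))
  invisible(x)
}

#' Marine-ice thickness change over one segment
#'
#' `dHm = -ab * dt`, with `ab` positive for melting, so a negative basal
#' rate (accretion) yields a positive thickness change.
#'
#' @param ab Basal melt/accretion rate (m/yr, positive = melting).
#' @param dt Segment duration (yr, > 0).
#' @return Thickness change (m); positive = accretion.
#' @export
basal_mass_change <- function(ab, dt) {
  stopifnot(all(dt > 0))
  -ab * dt
}

#' Accrete a new marine-ice layer
#'
#' Appends a layer of thickness `dHm` at the bottom of the stack (the
#' ice-ocean interface) with accretion timestamp `t_now`.
#'
#' @param stack A [layer_stack()].
#' @param dHm Thickness to accrete (m, > 0).
#' @param t_now Transit time at the end of the accreting segment (yr).
#' @param t_start Transit time at the start of the segment (defaults to
#'   `t_now`); used only to date the upper boundary of the layer.
#' @return The updated stack.
#' @export
accrete <- function(stack, dHm, t_now, t_start = t_now) {
  stopifnot(inherits(stack, "layer_stack"))
  if (!(dHm > 0)) stop("accrete: dHm must be > 0")
  n <- length(stack$h)
  if (n > 0 && t_now <= stack$tau[n])
    stop("accrete: accretion timestamps must increase")
  stack$h <- c(stack$h, dHm)
  stack$tau <- c(stack$tau, t_now)
  stack$tau0 <- c(stack$tau0, t_start)
  stack
}

#' Melt marine ice from the newest layer downward
#'
#' Removes `|dHm|` of ice in last-in-first-out order: the newest layer is
#' thinned first; exhausted layers are deleted together with their accretion
#' ages, cascading into older layers. If the stack empties before the demand
#' is met, the shortfall is returned as `melt_deficit` (the model never eats
#' into meteoric ice) and a warning is emitted.
#'
#' @param stack A [layer_stack()].
#' @param dHm Thickness change (m, < 0).
#' @return List with `stack` (updated) and `melt_deficit` (m, >= 0).
#' @export
melt <- function(stack, dHm) {
  stopifnot(inherits(stack, "layer_stack"))
  if (!(dHm < 0)) stop("melt: dHm must be < 0")
  demand <- -dHm
  while (demand > 0 && length(stack$h) > 0) {
    n <- length(stack$h)
    if (stack$h[n] > demand + 1e-15) {
      stack$h[n] <- stack$h[n] - demand
      demand <- 0
    } else {
      demand <- demand - stack$h[n]
      stack$h <- stack$h[-n]
      stack$tau <- stack$tau[-n]
      stack$tau0 <- stack$tau0[-n]
    }
  }
  deficit <- max(demand, 0)
  if (deficit > 1e-12)
    warning(sprintf("melt exhausted the marine column; deficit %.6g m", deficit))
  list(stack = stack, melt_deficit = deficit)
}

#' Thin every layer by the vertical strain rate
#'
#' Multiplies every layer thickness by the strain factor over the segment.
#' The default factor `exp(ezz * dt)` is the exact solution of
#' `dh/dt = ezz * h`; the first-order factor `1 + ezz * dt` is available via
#' `method = "linear"`. Ages and layer order are unchanged.
#'
#' @param stack A [layer_stack()].
#' @param ezz Vertical strain rate (1/yr); negative = thinning.
#' @param dt Segment duration (yr, > 0).
#' @param method `"exp"` (default) or `"linear"`.
#' @return The updated stack.
#' @export
apply_thinning <- function(stack, ezz, dt, method = c("exp", "linear")) {
  stopifnot(inherits(stack, "layer_stack"), dt > 0)
  method <- match.arg(method)
  f <- if (method == "exp") exp(ezz * dt) else 1 + ezz * dt
  if (f <= 0) stop("apply_thinning: strain factor must be positive")
  stack$h <- stack$h * f
  stack
}

#' Run the layer model along a segmented flowline
#'
#' Iterates the flowline segments in order. For each segment the basal mass
#' change `dHm = -(ab + ab_offset) * dt` is applied (accretion appends a new
#' bottom layer; melting consumes ice newest-first), then every layer --
#' including one accreted this segment -- is thinned by the vertical strain
#' over the segment duration. Transit time accumulates as `sum(dt)`.
#'
#' @param segments A `flowline_segments` data frame (columns `dt`, `ab`,
#'   `ezz`; see [segment_flowline()] / [make_segments()]).
#' @param ab_offset Additive shift of the basal rate (m/yr): scalar or one
#'   value per segment. Used for uncertainty reruns.
#' @param thinning Strain-factor method, see [apply_thinning()].
#' @return List of class `flowline_run` with `stack` (final
#'   [layer_stack()]), `steps` (one [data.frame] row per segment: `i`, `dHm`,
#'   `Hm`, `n_layers`, `melt_deficit`) and `total_time` (yr).
#' @export
run_flowline <- function(segments, ab_offset = 0,
                         thinning = c("exp", "linear")) {
  thinning <- match.arg(thinning)
  segments <- as.data.frame(segments)
  n <- nrow(segments)
  if (n == 0) stop("run_flowline: no segments")
  if (!length(ab_offset) %in% c(1L, n))
    stop("run_flowline: ab_offset must be scalar or one value per segment")
  ab <- segments$ab + ab_offset
  stack <- layer_stack()
  steps <- data.frame(i = seq_len(n), dHm = NA_real_, Hm = NA_real_,
                      n_layers = NA_integer_, melt_deficit = 0)
  t_now <- 0
  for (k in seq_len(n)) {
    dt <- segments$dt[k]
    dHm <- basal_mass_change(ab[k], dt)
    t_prev <- t_now
    t_now <- t_now + dt
    if (dHm > 0) {
      stack <- accrete(stack, dHm, t_now, t_prev)
    } else if (dHm < 0 && length(stack$h) > 0) {
      m <- suppressWarnings(melt(stack, dHm))
      stack <- m$stack
      steps$melt_deficit[k] <- m$melt_deficit
    } else if (dHm < 0) {
      steps$melt_deficit[k] <- -dHm
    }
    if (length(stack$h) > 0)
      stack <- apply_thinning(stack, segments$ezz[k], dt, method = thinning)
    steps$dHm[k] <- dHm
    steps$Hm[k] <- total_thickness(stack)
    steps$n_layers[k] <- length(stack$h)
  }
  structure(list(stack = stack, steps = steps, total_time = t_now),
            class = "flowline_run")
}

#' @export
print.flowline_run <- function(x, ...) {
  cat(sprintf(
    "<flowline_run> %d segments over %.1f yr; final Hm = %.2f m in %d layers\n",
    nrow(x$steps), x$total_time, total_thickness(x$stack),
    length(x$stack$h)))
  invisible(x)
}

#' Age-depth profile of the marine-ice column
#'
#' Depth is measured downward from the meteoric/marine interface (0 at the
#' interface). The oldest marine ice sits at the interface, the youngest at
#' the ice-ocean interface, so age decreases with depth. The age of layer
#' `j` is `total_transit_time - tau_j + drill_lag` (years before drilling);
#' ages at arbitrary depth are interpolated linearly between layer
#' boundaries.
#'
#' @param stack A non-empty [layer_stack()].
#' @param total_transit_time Total flowline transit time (yr).
#' @param drill_lag Years between the column reaching the core site and
#'   drilling (default 0).
#' @return A data frame of class `age_depth_profile` with columns `depth`
#'   (m, layer boundaries from 0 to Hm) and `age` (yr before drilling).
#' @export
age_depth_profile <- function(stack, total_transit_time, drill_lag = 0) {
  stopifnot(inherits(stack, "layer_stack"))
  if (length(stack$h) == 0)
    stop("age_depth_profile: empty layer stack, no profile")
  depth <- c(0, cumsum(stack$h))
  age <- c(total_transit_time - stack$tau0[1],
           total_transit_time - stack$tau) + drill_lag
  prof <- data.frame(depth = depth, age = age)
  class(prof) <- c("age_depth_profile", "data.frame")
  prof
}

#' Age at a given depth below the meteoric/marine interface
#'
#' @param profile An [age_depth_profile()].
#' @param depth Depth (m), within `[0, Hm]`.
#' @return Interpolated age (yr before drilling).
#' @export
age_at_depth <- function(profile, depth) {
  hm <- max(profile$depth)
  if (any(depth < 0 | depth > hm + 1e-9))
    stop(sprintf("depth out of range [0, %.3f m]", hm))
  stats::approx(profile$depth, profile$age, xout = pmin(depth, hm))$y
}

#' Age at depth with melt-rate-driven uncertainty
#'
#' The best estimate runs the layer model with the basal rates as given.
#' Bounds come either from two systematic reruns with every segment's rate
#' shifted by its +/- 1-sigma uncertainty (`mode = "systematic"`), or from
#' the envelope of `n_mc` Monte-Carlo reruns with independent per-segment
#' Gaussian perturbations (`mode = "mc"`).
#'
#' @param segments A `flowline_segments` data frame with a `sigma` column.
#' @param depth Depth below the meteoric/marine interface (m).
#' @param mode `"systematic"` (default) or `"mc"`.
#' @param n_mc Number of Monte-Carlo reruns (mode `"mc"`).
#' @param seed RNG seed for mode `"mc"`.
#' @param drill_lag Passed to [age_depth_profile()].
#' @return Named numeric `c(age_lo, age_best, age_hi)` (yr before drilling).
#' @export
age_with_uncertainty <- function(segments, depth,
                                 mode = c("systematic", "mc"),
                                 n_mc = 100, seed = 1, drill_lag = 0) {
  mode <- match.arg(mode)
  segments <- as.data.frame(segments)
  if (is.null(segments$sigma)) segments$sigma <- 0
  age_for <- function(offset, label) {
    run <- run_flowline(segments, ab_offset = offset)
    if (length(run$stack$h) == 0)
      stop(sprintf("scenario '%s': marine column empty, depth %.1f m unreachable",
                   label, depth))
    prof <- age_depth_profile(run$stack, run$total_time, drill_lag)
    if (depth > max(prof$depth) + 1e-9)
      stop(sprintf("depth %.1f m exceeds modeled thickness %.1f m in scenario '%s'",
                   depth, max(prof$depth), label))
    age_at_depth(prof, depth)
  }
  best <- age_for(0, "best")
  if (mode == "systematic") {
    others <- c(age_for(-segments$sigma, "ab - sigma"),
                age_for(+segments$sigma, "ab + sigma"))
  } else {
    set.seed(seed)
    others <- vapply(seq_len(n_mc), function(r)
      age_for(stats::rnorm(nrow(segments), 0, segments$sigma),
              sprintf("mc replicate %d", r)), numeric(1))
  }
  c(age_lo = min(best, others), age_best = best, age_hi = max(best, others))
}

#' Write an age-depth profile as TSV
#'
#' @param profile An [age_depth_profile()]; optional columns `age_lo`,
#'   `age_hi` are preserved.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
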