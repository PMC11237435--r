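#' Trace a flowline through a gridded velocity field
#'
#' Integrates the streamline through `field` downstream from `start` using
#' classical 4th-order Runge-Kutta parameterised by arc length, so each step
#' advances a fixed distance along the path regardless of speed. Integration
#' terminates at the domain edge, at `max_length_m`, or when the local speed
#' drops below `stagnation_ms` (transit time diverges as speed goes to 0).
#'
#' @param field A [velocity_field()].
#' @param start Numeric `c(x, y)` start point (m), e.g. on the grounding line.
#' @param step_m Integration step in metres of arc length (default 50).
#' @param max_length_m Maximum path length to trace (m).
#' @param stagnation_ms Speed (m/yr) below which flow is considered stagnant.
#' @return A `flow_path`: list with `vertices` (n x 2 matrix) and `s`
#'   (cumulative arc length, m).
#' @export
trace_flowline <- function(field, start, step_m = 50,
                           max_length_m = 1e5, stagnation_ms = 1) {
  stopifnot(inherits(field, "velocity_field"), step_m > 0)
  if (!in_domain(field, start))
    stop(sprintf("start point (%g, %g) outside the velocity-field domain",
                 start[1], start[2]))
  dir_at <- function(p) {
    if (!in_domain(field, p)) return(NULL)
    uv <- interpolate_velocity(field, p)
    sp <- sqrt(sum(uv^2))
    if (sp < stagnation_ms) return(NA)
    uv / sp
  }
  d0 <- dir_at(start)
  if (is.null(d0)) stop("start point outside domain")
  if (anyNA(d0))
    stop(sprintf("stagnant flow at start point (%g, %g): speed below %g m/yr",
                 start[1], start[2], stagnation_ms))

  n_max <- ceiling(max_length_m / step_m) + 1L
  verts <- matrix(NA_real_, n_max, 2L)
  verts[1L, ] <- start
  p <- start; s <- 0; k <- 1L
  while (s + step_m <= max_length_m + 1e-9) {
    k1 <- dir_at(p)
    if (is.null(k1) || anyNA(k1)) break
    k2 <- dir_at(p + step_m / 2 * k1)
    if (is.null(k2) || anyNA(k2)) break
    k3 <- dir_at(p + step_m / 2 * k2)
    if (is.null(k3) || anyNA(k3)) break
    k4 <- dir_at(p + step_m * k3)
    if (is.null(k4) || anyNA(k4)) break
    p_new <- p + step_m / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!in_domain(field, p_new)) break
    k <- k + 1L
    verts[k, ] <- p_new
    p <- p_new
    s <- s + step_m
  }
  verts <- verts[seq_len(k), , drop = FALSE]
  structure(list(vertices = verts,
                 s = seq(0, by = step_m, length.out = k)),
            class = "flow_path")
}

# linear interpolation of path coordinates at arc length s
path_point_at <- function(path, s) {
  c(stats::approx(path$s, path$vertices[, 1], xout = s)$y,
    stats::approx(path$s, path$vertices[, 2], xout = s)$y)
}

#' Cut a flow path into fixed-length segments with sampled forcing
#'
#' Resamples the path at `seg_len_m` arc-length intervals (a trailing
#' remainder becomes a final, shorter segment so total transit time is
#' conserved). Speed, vertical strain rate and basal rate are sampled at each
#' segment midpoint, and the segment duration is `dt = length / speed`.
#'
#' @param path A `flow_path` from [trace_flowline()].
#' @param field The [velocity_field()] the path was traced through.
#' @param basal A [scalar_field()] of basal melt/accretion rates (`ab`,
#'   positive for melting) with 1-sigma uncertainties.
#' @param seg_len_m Segment length in metres (default 250).
#' @param stagnation_ms Speed threshold (m/yr) below which a midpoint errors.
#' @return A data frame of class `flowline_segments` with columns
#'   `i, length, x_mid, y_mid, speed, dt, ab, sigma, ezz`.
#' @export
segment_flowline <- function(path, field, basal, seg_len_m = 250,
                             stagnation_ms = 1) {
  stopifnot(inherits(path, "flow_path"))
  total <- path$s[length(path$s)]
  if (total < seg_len_m)
    stop("path shorter than one segment")
  bounds <- seq(0, total, by = seg_len_m)
  if (total - bounds[length(bounds)] > 1e-6) bounds <- c(bounds, total)
  n <- length(bounds) - 1L
  out <- data.frame(i = seq_len(n), length = diff(bounds),
                    x_mid = NA_real_, y_mid = NA_real_, speed = NA_real_,
                    dt = NA_real_, ab = NA_real_, sigma = NA_real_,
                    ezz = NA_real_)
  for (k in seq_len(n)) {
    mid <- path_point_at(path, (bounds[k] + bounds[k + 1L]) / 2)
    uv <- interpolate_velocity(field, mid)
    sp <- sqrt(sum(uv^2))
    if (sp < stagnation_ms)
      stop(sprintf("stagnant flow at segment %d midpoint: speed %.3g m/yr", k, sp))
    ab <- interpolate_scalar(basal, mid)
    out$x_mid[k] <- mid[1]; out$y_mid[k] <- mid[2]
    out$speed[k] <- sp
    out$dt[k] <- out$length[k] / sp
    out$ab[k] <- ab[["value"]]; out$sigma[k] <- ab[["sigma"]]
    out$ezz[k] <- vertical_strain_rate(field, mid)
  }
  class(out) <- c("flowline_segments", "data.frame")
  out
}

#' Write flowline segments as TSV
#'
#' @param segments A `flowline_segments` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(as.data.frame(segments), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read flowline segments from TSV
#'
#' @param path TSV written by [write_segments()] (columns `i, length, x_mid,
#'   y_mid, speed, dt, ab, sigma, ezz`; only `dt`, `ab`, `ezz` are required
#'   by the layer model).
#' @return A `flowline_segments` data frame.
#' @export
read_segments <- function(path) {
  d <- utils::read.delim(path)
  need <- c("dt", "ab", "ezz")
  if (!all(need %in% names(d)))
    stop("segments TSV must have at least columns dt, ab, ezz")
  if (!"i" %in% names(d)) d$i <- seq_len(nrow(d))
  if (!"sigma" %in% names(d)) d$sigma <- 0
  class(d) <- c("flowline_segments", "data.frame")
  d
}
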