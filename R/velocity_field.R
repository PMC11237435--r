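#' Gridded 2-D ice velocity field
#'
#' Container for a horizontal shelf velocity field sampled on a rectilinear
#' grid. Components are stored as matrices with one row per `y` ordinate and
#' one column per `x` abscissa.
#'
#' @param x Ascending grid abscissae (m).
#' @param y Ascending grid ordinates (m).
#' @param u East velocity component, `length(y) x length(x)` matrix (m/yr).
#' @param v North velocity component, same shape (m/yr).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(x, y, u, v) {
  x <- as.numeric(x); y <- as.numeric(y)
  u <- as.matrix(u); v <- as.matrix(v)
  if (length(x) < 2L || length(y) < 2L)
    stop("velocity_field: grid needs at least 2 nodes per axis")
  if (any(diff(x) <= 0) || any(diff(y) <= 0))
    stop("velocity_field: grid coordinates must be strictly ascending")
  if (!all(dim(u) == c(length(y), length(x))) ||
      !all(dim(v) == c(length(y), length(x))))
    stop("velocity_field: u and v must be length(y) x length(x) matrices")
  if (anyNA(u) || anyNA(v))
    stop("velocity_field: missing values inside the grid")
  structure(list(x = x, y = y, u = u, v = v), class = "velocity_field")
}

#' Gridded scalar field (basal melt/accretion rate with uncertainty)
#'
#' @param x,y Grid coordinates as in [velocity_field()].
#' @param values Basal rate `ab` (m/yr, positive for melting).
#' @param sigma 1-sigma uncertainty of `ab` (m/yr, non-negative).
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(x, y, values, sigma = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  values <- as.matrix(values)
  if (is.null(sigma)) sigma <- matrix(0, nrow(values), ncol(values))
  sigma <- as.matrix(sigma)
  if (any(diff(x) <= 0) || any(diff(y) <= 0))
    stop("scalar_field: grid coordinates must be strictly ascending")
  if (!all(dim(values) == c(length(y), length(x))))
    stop("scalar_field: values must be length(y) x length(x)")
  if (!all(dim(sigma) == dim(values)))
    stop("scalar_field: sigma must match values in shape")
  if (any(sigma < 0)) stop("scalar_field: sigma must be >= 0 everywhere")
  structure(list(x = x, y = y, values = values, sigma = sigma),
            class = "scalar_field")
}

in_domain <- function(field, point) {
  point[1] >= field$x[1] && point[1] <= field$x[length(field$x)] &&
    point[2] >= field$y[1] && point[2] <= field$y[length(field$y)]
}

# bilinear sample of one matrix layer; assumes point inside bounding box
bilinear_sample <- function(x, y, z, px, py) {
  nx <- length(x); ny <- length(y)
  ix <- findInterval(px, x, rightmost.closed = TRUE)
  iy <- findInterval(py, y, rightmost.closed = TRUE)
  ix <- min(max(ix, 1L), nx - 1L)
  iy <- min(max(iy, 1L), ny - 1L)
  tx <- (px - x[ix]) / (x[ix + 1L] - x[ix])
  ty <- (py - y[iy]) / (y[iy + 1L] - y[iy])
  (1 - tx) * (1 - ty) * z[iy, ix] + tx * (1 - ty) * z[iy, ix + 1L] +
    (1 - tx) * ty * z[iy + 1L, ix] + tx * ty * z[iy + 1L, ix + 1L]
}

#' Bilinear velocity interpolation
#'
#' @param field A [velocity_field()].
#' @param point Numeric `c(x, y)` in metres.
#' @return Named numeric `c(u, v)` in m/yr.
#' @export
interpolate_velocity <- function(field, point) {
  stopifnot(inherits(field, "velocity_field"))
  if (!in_domain(field, point))
    stop(sprintf("point (%g, %g) outside the velocity-field domain",
                 point[1], point[2]))
  c(u = bilinear_sample(field$x, field$y, field$u, point[1], point[2]),
    v = bilinear_sample(field$x, field$y, field$v, point[1], point[2]))
}

#' Bilinear sample of a scalar field and its uncertainty
#'
#' @param field A [scalar_field()].
#' @param point Numeric `c(x, y)`.
#' @return Named numeric `c(value, sigma)`.
#' @export
interpolate_scalar <- function(field, point) {
  stopifnot(inherits(field, "scalar_field"))
  if (!(point[1] >= field$x[1] && point[1] <= field$x[length(field$x)] &&
        point[2] >= field$y[1] && point[2] <= field$y[length(field$y)]))
    stop(sprintf("point (%g, %g) outside the scalar-field domain",
                 point[1], point[2]))
  c(value = bilinear_sample(field$x, field$y, field$values,
                            point[1], point[2]),
    sigma = bilinear_sample(field$x, field$y, field$sigma,
                            point[1], point[2]))
}

#' Vertical strain rate from horizontal velocity divergence
#'
#' Incompressibility ties the vertical strain rate of the ice column to the
#' horizontal divergence: `ezz = -(du/dx + dv/dy)`. The divergence is
#' evaluated by central finite differences at the four grid nodes of the
#' cell containing the point and interpolated bilinearly, which is exact for
#' fields linear in x and y. Points within one grid cell of the boundary
#' raise an error rather than silently degrading to one-sided differences.
#'
#' @param field A [velocity_field()].
#' @param point Numeric `c(x, y)`.
#' @return Vertical strain rate (1/yr); negative means thinning.
#' @export
vertical_strain_rate <- function(field, point) {
  stopifnot(inherits(field, "velocity_field"))
  x <- field$x; y <- field$y
  nx <- length(x); ny <- length(y)
  if (nx < 3L || ny < 3L)
    stop("vertical_strain_rate: grid too small for central differences")
  if (point[1] < x[2] || point[1] > x[nx - 1L] ||
      point[2] < y[2] || point[2] > y[ny - 1L])
    stop(sprintf(
      "point (%g, %g) is within one grid cell of the boundary; central differences undefined",
      point[1], point[2]))
  ix <- min(max(findInterval(point[1], x, rightmost.closed = TRUE), 2L), nx - 2L)
  iy <- min(max(findInterval(point[2], y, rightmost.closed = TRUE), 2L), ny - 2L)
  div_at <- function(j, i) {
    dudx <- (field$u[j, i + 1L] - field$u[j, i - 1L]) / (x[i + 1L] - x[i - 1L])
    dvdy <- (field$v[j + 1L, i] - field$v[j - 1L, i]) / (y[j + 1L] - y[j - 1L])
    dudx + dvdy
  }
  corners <- matrix(c(div_at(iy, ix),        div_at(iy, ix + 1L),
                      div_at(iy + 1L, ix),   div_at(iy + 1L, ix + 1L)),
                    nrow = 2L, byrow = TRUE)
  tx <- (point[1] - x[ix]) / (x[ix + 1L] - x[ix])
  ty <- (point[2] - y[iy]) / (y[iy + 1L] - y[iy])
  div <- (1 - tx) * (1 - ty) * corners[1, 1] + tx * (1 - ty) * corners[1, 2] +
    (1 - tx) * ty * corners[2, 1] + tx * ty * corners[2, 2]
  -div
}

#' Read a velocity field from long-format CSV
#'
#' Expects columns `x,y,u,v` covering a complete rectilinear grid.
#'
#' @param path CSV file path.
#' @return A [velocity_field()].
#' @export
read_velocity_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x", "y", "u", "v")
  if (!all(need %in% names(d)))
    stop("velocity CSV must have columns x,y,u,v")
  grid_from_long(d, c("u", "v"), velocity_field)
}

#' Read a basal melt/accretion-rate field from long-format CSV
#'
#' Expects columns `x,y,ab,sigma` covering a complete rectilinear grid.
#'
#' @param path CSV file path.
#' @return A [scalar_field()].
#' @export
read_basal_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x", "y", "ab", "sigma")
  if (!all(need %in% names(d)))
    stop("basal-rate CSV must have columns x,y,ab,sigma")
  grid_from_long(d, c("ab", "sigma"), function(x, y, a, b)
    scalar_field(x, y, a, b))
}

grid_from_long <- function(d, vars, ctor) {
  xs <- sort(unique(d$x)); ys <- sort(unique(d$y))
  if (nrow(d) != length(xs) * length(ys))
    stop("long-format grid is incomplete: need every (x, y) combination")
  ord <- order(d$y, d$x)
  mats <- lapply(vars, function(v)
    matrix(d[[v]][ord], nrow = length(ys), ncol = length(xs), byrow = TRUE))
  ctor(xs, ys, mats[[1]], mats[[2]])
}

#' Write a velocity or scalar field as long-format CSV
#'
#' @param field A [velocity_field()] or [scalar_field()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  g <- expand.grid(x = field$x, y = field$y)
  if (inherits(field, "velocity_field")) {
    g$u <- as.vector(t(field$u)); g$v <- as.vector(t(field$v))
  } else {
    g$ab <- as.vector(t(field$values)); g$sigma <- as.vector(t(field$sigma))
  }
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
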