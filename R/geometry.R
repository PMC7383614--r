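#' Euclidean distance between two points
#'
#' Exact 3-space distance in Angstrom.  Coordinates are Cartesian, right
#' handed; no periodic-boundary handling (active-site frames are assumed
#' imaged).
#'
#' @param a,b Numeric 3-vectors (Angstrom).
#' @return Non-negative length in Angstrom.
#' @examples
#' dist3d(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
dist3d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L)
    stop("dist3d() expects 3-vectors", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("dist3d(): non-finite input coordinates", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Interior angle at a vertex
#'
#' Angle a-vertex-c in degrees, in \[0, 180\].
#'
#' @param a,vertex,c Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @examples
#' angle3d(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
angle3d <- function(a, vertex, c) {
  a <- as.numeric(a); vertex <- as.numeric(vertex); c <- as.numeric(c)
  if (!all(is.finite(c(a, vertex, c))))
    stop("angle3d(): non-finite input coordinates", call. = FALSE)
  u <- a - vertex
  v <- c - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("angle3d(): zero-length arm at vertex", call. = FALSE)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# Row-wise distance between two n x 3 coordinate matrices.
.dist_rows <- function(a, b) {
  d <- a - b
  sqrt(d[, 1L]^2 + d[, 2L]^2 + d[, 3L]^2)
}

# Row-wise angle a-vertex-c (degrees) for n x 3 coordinate matrices.
.angle_rows <- function(a, vertex, c) {
  u <- a - vertex
  v <- c - vertex
  nu <- sqrt(u[, 1L]^2 + u[, 2L]^2 + u[, 3L]^2)
  nv <- sqrt(v[, 1L]^2 + v[, 2L]^2 + v[, 3L]^2)
  cosang <- (u[, 1L] * v[, 1L] + u[, 2L] * v[, 2L] + u[, 3L] * v[, 3L]) /
    (nu * nv)
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

# Closed interval test, bounds inclusive (the criterion windows are printed
# as closed ranges).
.in_range <- function(x, range) x >= range[1L] & x <= range[2L]
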