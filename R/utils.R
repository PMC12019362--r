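#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Unit vector
#' @noRd
unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

#' Rotation matrix about z by `theta` radians (right-handed)
#' @noRd
rotz <- function(theta) {
  c0 <- cos(theta); s0 <- sin(theta)
  matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix about an arbitrary unit axis by `theta` radians (right-handed)
#' @noRd
rot_axis <- function(axis, theta) {
  a <- unitv(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Angle in degrees between two vectors
#' @noRd
vec_angle <- function(u, v) {
  cu <- sum(unitv(u) * unitv(v))
  rad2deg(acos(max(-1, min(1, cu))))
}

vnorm <- function(v) sqrt(sum(v^2))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf  <- function(fmt, ...) message(sprintf(fmt, ...))
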