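# Rigid transforms. All public interfaces take degrees (the profile tables
# are in degrees); radians are internal only. Transforms act on control
# points; knots and weights are untouched, so evaluation commutes with the
# transform (affine equivariance).

deg2rad <- function(d) d * pi / 180

apply_to_points <- function(g, f) {
  if (is.matrix(g)) return(f(g))
  if (is.numeric(g) && length(g) == 3L) return(drop(f(matrix(g, 1L))))
  if (inherits(g, "nurbs_curve")) {
    g$control <- f(g$control)
    return(g)
  }
  if (inherits(g, "nurbs_surface")) {
    d <- dim(g$control)
    flat <- matrix(g$control, d[1L] * d[2L], 3L)
    g$control <- array(f(flat), d)
    return(g)
  }
  if (is.list(g)) return(lapply(g, apply_to_points, f = f))
  stop("cannot transform object of class ", paste(class(g), collapse = "/"),
       call. = FALSE)
}

#' Rotate about the valve (z) axis
#'
#' @param g A point (length-3 vector), point matrix, `nurbs_curve`,
#'   `nurbs_surface`, or list thereof.
#' @param angle Rotation angle in degrees (right-handed about +z).
#' @return Transformed object of the same type.
#' @export
rotate_z <- function(g, angle) {
  a <- deg2rad(angle)
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
  apply_to_points(g, function(P) P %*% t(R))
}

#' Reflect across a vertical plane through the z axis
#'
#' The mirror plane contains the z axis at azimuth `plane_phi` degrees.
#' Control-point order is preserved (reversal, when needed, is the caller's
#' choice).
#'
#' @inheritParams rotate_z
#' @param plane_phi Azimuth of the mirror plane in degrees.
#' @return Transformed object of the same type.
#' @export
reflect <- function(g, plane_phi) {
  a <- deg2rad(plane_phi)
  # reflection across plane at azimuth a: rotate -a, mirror y, rotate +a
  c2 <- cos(2 * a); s2 <- sin(2 * a)
  M <- matrix(c(c2, s2, 0, s2, -c2, 0, 0, 0, 1), 3L, 3L)
  apply_to_points(g, function(P) P %*% t(M))
}

#' Translate by a vector
#'
#' @inheritParams rotate_z
#' @param vector Length-3 translation in mm.
#' @return Transformed object of the same type.
#' @export
translate <- function(g, vector) {
  v <- as.numeric(vector)
  if (length(v) != 3L) stop("translation vector must have length 3", call. = FALSE)
  apply_to_points(g, function(P) sweep(P, 2L, v, "+"))
}

# Cylindrical <-> Cartesian helpers (phi in degrees).
cyl_to_cart <- function(r, phi, z) {
  a <- deg2rad(phi)
  cbind(r * cos(a), r * sin(a), z, deparse.level = 0)
}

cart_to_cyl <- function(P) {
  P <- if (is.matrix(P)) P else matrix(P, 1L)
  cbind(r = sqrt(P[, 1L]^2 + P[, 2L]^2),
        phi = atan2(P[, 2L], P[, 1L]) * 180 / pi,
        z = P[, 3L])
}

# Reverse a curve's direction (exact).
reverse_curve <- function(crv) {
  n <- nrow(crv$control)
  U <- crv$knots
  a <- U[1L]; b <- U[length(U)]
  nurbs_curve(crv$control[n:1, , drop = FALSE],
              knots = rev(a + b - U),
              weights = rev(crv$weights), degree = crv$degree)
}
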