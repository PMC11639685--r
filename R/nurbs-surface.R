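# NURBS tensor-product surface container and evaluation.

#' Construct a NURBS surface
#'
#' @param control Numeric array `c(nu, nv, 3)` of control points in mm.
#' @param knots_u,knots_v Clamped knot vectors.
#' @param weights `nu x nv` matrix of positive weights (default all 1).
#' @param degree_u,degree_v Degrees per direction.
#' @return Object of class `nurbs_surface`.
#' @export
nurbs_surface <- function(control, knots_u = NULL, knots_v = NULL,
                          weights = NULL, degree_u = 3L, degree_v = 3L) {
  if (length(dim(control)) != 3L || dim(control)[3L] != 3L) {
    stop("control must be an nu x nv x 3 array", call. = FALSE)
  }
  nu <- dim(control)[1L]
  nv <- dim(control)[2L]
  degree_u <- as.integer(degree_u)
  degree_v <- as.integer(degree_v)
  if (is.null(knots_u)) knots_u <- open_uniform_knots(nu, degree_u)
  if (is.null(knots_v)) knots_v <- open_uniform_knots(nv, degree_v)
  if (is.null(weights)) weights <- matrix(1, nu, nv)
  if (length(knots_u) != nu + degree_u + 1L ||
      length(knots_v) != nv + degree_v + 1L) {
    stop("knot vector lengths inconsistent with the control net", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  structure(list(degree_u = degree_u, degree_v = degree_v,
                 control = control, weights = weights,
                 knots_u = as.numeric(knots_u), knots_v = as.numeric(knots_v)),
            class = "nurbs_surface")
}

#' @export
print.nurbs_surface <- function(x, ...) {
  ec <- element_count(x)
  cat(sprintf("<nurbs_surface> degrees (%d, %d), net %d x %d, elements %d x %d\n",
              x$degree_u, x$degree_v, dim(x$control)[1L], dim(x$control)[2L],
              ec[["u"]], ec[["v"]]))
  invisible(x)
}

surface_domain <- function(srf) {
  pu <- srf$degree_u; pv <- srf$degree_v
  list(u = c(srf$knots_u[pu + 1L], srf$knots_u[length(srf$knots_u) - pu]),
       v = c(srf$knots_v[pv + 1L], srf$knots_v[length(srf$knots_v) - pv]))
}

#' Evaluate a NURBS surface
#'
#' @param srf A `nurbs_surface`.
#' @param u,v Parameter vectors of equal length (or length 1, recycled).
#' @return Matrix of points, one row per (u, v) pair.
#' @export
eval_surface <- function(srf, u, v) {
  m <- max(length(u), length(v))
  u <- rep_len(as.numeric(u), m)
  v <- rep_len(as.numeric(v), m)
  dom <- surface_domain(srf)
  u <- pmin(pmax(u, dom$u[1]), dom$u[2])
  v <- pmin(pmax(v, dom$v[1]), dom$v[2])
  pu <- srf$degree_u; pv <- srf$degree_v
  nu <- dim(srf$control)[1L]; nv <- dim(srf$control)[2L]
  W <- srf$weights
  out <- matrix(0, m, 3L)
  for (k in seq_len(m)) {
    iu <- find_span(u[k], pu, srf$knots_u, nu)
    iv <- find_span(v[k], pv, srf$knots_v, nv)
    Nu <- basis_funs(iu, u[k], pu, srf$knots_u)
    Nv <- basis_funs(iv, v[k], pv, srf$knots_v)
    ru <- (iu - pu):iu
    rv <- (iv - pv):iv
    wloc <- W[ru, rv, drop = FALSE]
    denom <- drop(Nu %*% wloc %*% Nv)
    pt <- numeric(3L)
    for (d in 1:3) {
      pt[d] <- drop(Nu %*% (srf$control[ru, rv, d] * wloc) %*% Nv) / denom
    }
    out[k, ] <- pt
  }
  out
}

# Swap the u and v directions.
surface_transpose <- function(srf) {
  nurbs_surface(aperm(srf$control, c(2L, 1L, 3L)),
                knots_u = srf$knots_v, knots_v = srf$knots_u,
                weights = t(srf$weights),
                degree_u = srf$degree_v, degree_v = srf$degree_u)
}

# Extract an iso-curve at fixed v (or fixed u with direction = "u").
iso_curve <- function(srf, value, direction = c("v", "u")) {
  direction <- match.arg(direction)
  if (direction == "u") return(iso_curve(surface_transpose(srf), value, "v"))
  nv <- dim(srf$control)[2L]
  pv <- srf$degree_v
  iv <- find_span(value, pv, srf$knots_v, nv)
  Nv <- basis_funs(iv, value, pv, srf$knots_v)
  rv <- (iv - pv):iv
  w <- drop(srf$weights[, rv, drop = FALSE] %*% Nv)
  ctrl <- matrix(0, dim(srf$control)[1L], 3L)
  for (d in 1:3) {
    ctrl[, d] <- drop((srf$control[, rv, d] * srf$weights[, rv, drop = FALSE]) %*% Nv) / w
  }
  nurbs_curve(ctrl, knots = srf$knots_u, weights = w, degree = srf$degree_u)
}
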