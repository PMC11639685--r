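# NURBS curve container and evaluation.

#' Construct a NURBS curve
#'
#' A curve is a list with fields `degree`, `control` (n x 3 matrix, mm),
#' `weights` (positive, length n; all 1 for non-rational curves) and `knots`
#' (clamped, nondecreasing, length n + degree + 1).
#'
#' @param control Numeric n x 3 matrix of control points in mm.
#' @param knots Clamped knot vector; defaults to an open uniform vector.
#' @param weights Positive weights; default all 1 (non-rational).
#' @param degree Polynomial degree; default 3.
#' @return Object of class `nurbs_curve`.
#' @export
nurbs_curve <- function(control, knots = NULL, weights = NULL, degree = 3L) {
  control <- as.matrix(control)
  if (ncol(control) != 3L) stop("control must be an n x 3 matrix", call. = FALSE)
  storage.mode(control) <- "double"
  n <- nrow(control)
  degree <- as.integer(degree)
  if (is.null(knots)) knots <- open_uniform_knots(n, degree)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length must match control points", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (length(knots) != n + degree + 1L) {
    stop("knot vector length must be n_ctrl + degree + 1 (got ",
         length(knots), ", expected ", n + degree + 1L, ")", call. = FALSE)
  }
  if (is.unsorted(knots)) stop("knots must be nondecreasing", call. = FALSE)
  structure(list(degree = degree, control = control,
                 weights = as.numeric(weights), knots = as.numeric(knots)),
            class = "nurbs_curve")
}

is_rational <- function(g) any(abs(g$weights - 1) > 1e-14)

curve_domain <- function(crv) {
  p <- crv$degree
  c(crv$knots[p + 1L], crv$knots[length(crv$knots) - p])
}

#' @export
print.nurbs_curve <- function(x, ...) {
  dom <- curve_domain(x)
  cat(sprintf("<nurbs_curve> degree %d, %d control points, %d spans, u in [%g, %g]%s\n",
              x$degree, nrow(x$control), n_spans(x$knots), dom[1], dom[2],
              if (is_rational(x)) ", rational" else ""))
  invisible(x)
}

# Homogeneous control points (n x 4): (w*x, w*y, w*z, w).
homog <- function(crv) {
  cbind(crv$control * crv$weights, crv$weights)
}

curve_from_homog <- function(Pw, knots, degree) {
  w <- Pw[, 4L]
  nurbs_curve(Pw[, 1:3, drop = FALSE] / w, knots = knots, weights = w,
              degree = degree)
}

#' Evaluate a NURBS curve
#'
#' @param curve A `nurbs_curve`.
#' @param u Parameter value(s) within the knot range.
#' @return Length(u) x 3 matrix of points (mm).
#' @export
eval_curve <- function(curve, u) {
  dom <- curve_domain(curve)
  u <- as.numeric(u)
  if (any(u < dom[1] - 1e-12 | u > dom[2] + 1e-12)) {
    stop("parameter out of knot range [", dom[1], ", ", dom[2], "]",
         call. = FALSE)
  }
  u <- pmin(pmax(u, dom[1]), dom[2])
  p <- curve$degree
  U <- curve$knots
  n <- nrow(curve$control)
  Pw <- homog(curve)
  out <- matrix(0, length(u), 3L)
  for (k in seq_along(u)) {
    i <- find_span(u[k], p, U, n)
    N <- basis_funs(i, u[k], p, U)
    Cw <- drop(N %*% Pw[(i - p):i, , drop = FALSE])
    out[k, ] <- Cw[1:3] / Cw[4L]
  }
  out
}

#' Curve derivatives
#'
#' Point and derivatives up to order `n_der` at each parameter, using the
#' rational quotient rule where weights differ from 1.
#'
#' @param curve A `nurbs_curve`.
#' @param u Parameter value(s).
#' @param n_der Highest derivative order (<= 2 used internally).
#' @return List of `n_der + 1` matrices (point, first, second, ... derivative).
#' @export
curve_derivs <- function(curve, u, n_der = 1L) {
  dom <- curve_domain(curve)
  u <- pmin(pmax(as.numeric(u), dom[1]), dom[2])
  p <- curve$degree
  U <- curve$knots
  n <- nrow(curve$control)
  Pw <- homog(curve)
  out <- lapply(0:n_der, function(k) matrix(0, length(u), 3L))
  for (k in seq_along(u)) {
    i <- find_span(u[k], p, U, n)
    D <- ders_basis_funs(i, u[k], p, n_der, U)
    Aw <- D %*% Pw[(i - p):i, , drop = FALSE]       # (n_der+1) x 4
    Cd <- matrix(0, n_der + 1L, 3L)
    for (d in 0:n_der) {
      v <- Aw[d + 1L, 1:3]
      if (d > 0L) {
        for (j in 1:d) {
          v <- v - choose(d, j) * Aw[j + 1L, 4L] * Cd[d - j + 1L, ]
        }
      }
      Cd[d + 1L, ] <- v / Aw[1L, 4L]
    }
    for (d in 0:n_der) out[[d + 1L]][k, ] <- Cd[d + 1L, ]
  }
  out
}

#' Count cubic elements (non-degenerate knot spans)
#'
#' For surfaces the per-direction counts and their product are returned.
#'
#' @param g A `nurbs_curve` or `nurbs_surface`.
#' @return Integer span count (curve) or named vector `c(u, v, total)`.
#' @export
element_count <- function(g) {
  if (inherits(g, "nurbs_curve")) return(n_spans(g$knots))
  if (inherits(g, "nurbs_surface")) {
    eu <- n_spans(g$knots_u)
    ev <- n_spans(g$knots_v)
    return(c(u = eu, v = ev, total = eu * ev))
  }
  stop("element_count expects a nurbs_curve or nurbs_surface", call. = FALSE)
}

#' Arc length of a NURBS curve
#'
#' Adaptive per-span Gauss--Legendre quadrature of the speed, refined until
#' the relative change falls below `rel_tol`.
#'
#' @param curve A `nurbs_curve`.
#' @param rel_tol Relative tolerance (default 1e-10).
#' @return Length in mm.
#' @export
curve_length <- function(curve, rel_tol = 1e-10) {
  gl <- pracma::gaussLegendre(16, 0, 1)
  seg_len <- function(a, b) {
    uu <- a + (b - a) * gl$x
    sp <- curve_derivs(curve, uu, 1L)[[2L]]
    (b - a) * sum(gl$w * sqrt(rowSums(sp^2)))
  }
  adapt <- function(a, b, whole, depth) {
    m <- (a + b) / 2
    l1 <- seg_len(a, m)
    l2 <- seg_len(m, b)
    if (depth > 12L || abs(l1 + l2 - whole) <= rel_tol * abs(whole) + 1e-14) {
      return(l1 + l2)
    }
    adapt(a, m, l1, depth + 1L) + adapt(m, b, l2, depth + 1L)
  }
  br <- knot_breaks(curve$knots)
  total <- 0
  for (s in seq_len(length(br) - 1L)) {
    a <- br[s]; b <- br[s + 1L]
    total <- total + adapt(a, b, seg_len(a, b), 0L)
  }
  total
}

# Parameter at a given arc length from the start: cumulative Gauss--Legendre
# table over a fine grid, then Newton refinement with the exact speed.
param_at_length <- function(curve, s, n_seg = 256L) {
  dom <- curve_domain(curve)
  gl <- pracma::gaussLegendre(5, 0, 1)
  br <- seq(dom[1], dom[2], length.out = n_seg + 1L)
  h <- diff(br)
  nodes <- as.vector(outer(gl$x, h) + rep(br[-length(br)], each = 5L))
  speed <- sqrt(rowSums(curve_derivs(curve, nodes, 1L)[[2L]]^2))
  seg <- h * colSums(matrix(gl$w * matrix(speed, 5L), 5L))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (s <= 0) return(dom[1])
  if (s >= total) return(dom[2])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  u <- br[i] + (s - cum[i]) / seg[i] * h[i]
  quad_to <- function(a, b) {
    uu <- a + (b - a) * gl$x
    sp <- sqrt(rowSums(curve_derivs(curve, uu, 1L)[[2L]]^2))
    (b - a) * sum(gl$w * sp)
  }
  for (it in 1:6) {
    F <- cum[i] + quad_to(br[i], u) - s
    dF <- sqrt(sum(curve_derivs(curve, u, 1L)[[2L]]^2))
    step <- F / dF
    u <- min(max(u - step, dom[1]), dom[2])
    if (abs(step) < 1e-13) break
  }
  u
}
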