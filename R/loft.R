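# Skinning (lofting) an ordered family of section curves into a surface.

# Interpolation scheme shared by loft() and the Gordon tensor term: the
# stacking direction always uses these knots so the correction surface
# cancels exactly along the network curves.
stack_scheme <- function(params, degree) {
  list(degree = degree, knots = averaged_knots(params, degree))
}

# Solve the stacking interpolation for a matrix of values (rows = sections).
stack_interp <- function(values, params, scheme) {
  q <- scheme$degree
  U <- scheme$knots
  K <- length(params)
  A <- matrix(0, K, K)
  for (k in seq_len(K)) {
    i <- find_span(params[k], q, U, K)
    A[k, (i - q):i] <- basis_funs(i, params[k], q, U)
  }
  solve(A, values)
}

#' Loft a surface through an ordered set of curves
#'
#' The curves are made knot-compatible by degree elevation plus knot-vector
#' union (never re-approximation), then interpolated in the stacking (v)
#' direction. Each input curve is reproduced exactly as the iso-curve at its
#' stacking parameter (stored in `attr(, "v_params")`).
#'
#' @param curves List of at least two `nurbs_curve`s.
#' @param params Optional stacking parameters in \[0, 1\]; default averaged
#'   chord lengths across control-point columns.
#' @param degree Stacking degree; default `min(3, length(curves) - 1)`.
#' @return A `nurbs_surface` with the sections as iso-v curves.
#' @export
loft <- function(curves, params = NULL, degree = NULL) {
  K <- length(curves)
  if (K < 2L) stop("loft needs at least 2 curves", call. = FALSE)
  curves <- make_curves_knot_compatible(curves)
  nu <- nrow(curves[[1L]]$control)
  if (is.null(degree)) degree <- min(3L, K - 1L)
  if (is.null(params)) {
    # average chord-length parameters across control columns
    acc <- numeric(K - 1L)
    for (i in seq_len(nu)) {
      col <- t(vapply(curves, function(cv) cv$control[i, ], numeric(3L)))
      acc <- acc + sqrt(rowSums(diff(col)^2))
    }
    if (sum(acc) < 1e-12) {
      warning("loft of (nearly) identical curves: degenerate zero-area surface")
      params <- seq(0, 1, length.out = K)
    } else {
      params <- c(0, cumsum(acc)) / sum(acc)
      # guard monotonicity for columns that coincide
      if (any(diff(params) <= 0)) params <- seq(0, 1, length.out = K)
    }
  }
  scheme <- stack_scheme(params, degree)
  Hw <- lapply(curves, homog)               # homogeneous skinning
  net <- array(0, c(nu, K, 3L))
  W <- matrix(0, nu, K)
  for (i in seq_len(nu)) {
    vals <- t(vapply(Hw, function(h) h[i, ], numeric(4L)))
    sol <- stack_interp(vals, params, scheme)
    if (any(sol[, 4L] <= 0)) {
      stop("lofting produced non-positive weights; sections are incompatible",
           call. = FALSE)
    }
    net[i, , ] <- sol[, 1:3] / sol[, 4L]
    W[i, ] <- sol[, 4L]
  }
  srf <- nurbs_surface(net, knots_u = curves[[1L]]$knots, knots_v = scheme$knots,
                       weights = W, degree_u = curves[[1L]]$degree,
                       degree_v = degree)
  attr(srf, "v_params") <- params
  srf
}

# Bring surfaces to identical degrees and knot vectors in both directions.
make_surfaces_compatible <- function(srfs) {
  pu <- max(vapply(srfs, function(s) s$degree_u, integer(1L)))
  pv <- max(vapply(srfs, function(s) s$degree_v, integer(1L)))
  srfs <- lapply(srfs, elevate_surface_degree, to_u = pu, to_v = pv)
  for (dir in c("u", "v")) {
    key <- paste0("knots_", dir)
    un <- knot_union(lapply(srfs, function(s) s[[key]]))
    srfs <- lapply(srfs, function(s) {
      ins <- numeric(0)
      for (k in seq_along(un$breaks)) {
        if (k %in% c(1L, length(un$breaks))) next
        b <- un$breaks[k]
        have <- sum(abs(s[[key]] - b) < 1e-11)
        if (have < un$mult[k]) ins <- c(ins, rep(b, un$mult[k] - have))
      }
      if (length(ins)) refine_surface_knots(s, ins, dir) else s
    })
  }
  srfs
}
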