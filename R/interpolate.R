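# Global curve interpolation with chord-length parameterization and
# averaged knots; optional end-derivative constraints.

chord_params <- function(points) {
  d <- sqrt(rowSums(diff(points)^2))
  if (any(d < 1e-12)) {
    stop("coincident consecutive interpolation points", call. = FALSE)
  }
  c(0, cumsum(d)) / sum(d)
}

averaged_knots <- function(t, degree) {
  n <- length(t) - 1L                      # 0-based last point index
  p <- degree
  interior <- numeric(0)
  if (n - p >= 1L) {
    interior <- vapply(1:(n - p), function(j) mean(t[(j + 1L):(j + p)]),
                       numeric(1L))
  }
  c(rep(0, p + 1L), interior, rep(1, p + 1L))
}

# Interpolation at prescribed parameters; the workhorse behind
# interpolate_curve and the Gordon resampler.
interpolate_at_params <- function(points, t, degree = 3L, tangents = NULL) {
  points <- as.matrix(points)
  p <- as.integer(degree)
  n <- nrow(points) - 1L
  if (is.null(tangents)) {
    if (n + 1L < p + 1L) {
      stop("need at least degree + 1 points (got ", n + 1L, ")", call. = FALSE)
    }
    U <- averaged_knots(t, p)
    nun <- n + 1L
  } else {
    if (p != 3L) stop("end tangents are supported for cubic curves", call. = FALSE)
    if (n + 1L < 2L) stop("need at least 2 points with tangents", call. = FALSE)
    interior <- if (n >= 2L) t[2:n] else numeric(0)
    U <- c(rep(0, p + 1L), interior, rep(1, p + 1L))
    nun <- n + 3L
  }
  A <- matrix(0, nun, nun)
  rhs <- matrix(0, nun, 3L)
  row <- 1L
  for (k in seq_len(n + 1L)) {
    i <- find_span(t[k], p, U, nun)
    A[row, (i - p):i] <- basis_funs(i, t[k], p, U)
    rhs[row, ] <- points[k, ]
    row <- row + 1L
  }
  if (!is.null(tangents)) {
    for (end in 1:2) {
      tt <- if (end == 1L) t[1L] else t[n + 1L]
      i <- find_span(tt, p, U, nun)
      A[row, (i - p):i] <- ders_basis_funs(i, tt, p, 1L, U)[2L, ]
      rhs[row, ] <- if (end == 1L) tangents[[1L]] else tangents[[2L]]
      row <- row + 1L
    }
  }
  ctrl <- tryCatch(solve(A, rhs), error = function(e) {
    stop("singular interpolation system (", conditionMessage(e), ")",
         call. = FALSE)
  })
  nurbs_curve(ctrl, knots = U, degree = p)
}

#' Globally interpolate points with a NURBS curve
#'
#' Chord-length parameterization with averaged knots. The curve passes
#' through every input point; optional end derivatives are honored exactly
#' (cubic only).
#'
#' @param points Ordered n x 3 matrix of points (mm); no two consecutive
#'   points may coincide.
#' @param degree Curve degree (default 3).
#' @param end_tangents Optional list of two length-3 derivative vectors at
#'   the first and last point (with respect to the chord parameterization).
#' @return A `nurbs_curve` through all points.
#' @export
interpolate_curve <- function(points, degree = 3L, end_tangents = NULL) {
  points <- as.matrix(points)
  t <- chord_params(points)
  interpolate_at_params(points, t, degree = degree, tangents = end_tangents)
}

# Recipe-facing wrapper: fall back to a lower degree when there are fewer
# than 4 points, then elevate so every network curve ends up cubic.
interp_cubic <- function(points, end_tangents = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!is.null(end_tangents) || n >= 4L) {
    crv <- interpolate_curve(points, degree = 3L, end_tangents = end_tangents)
  } else if (n >= 2L) {
    crv <- elevate_curve_degree(interpolate_curve(points, degree = n - 1L), 3L)
  } else {
    stop("need at least 2 points to build a curve", call. = FALSE)
  }
  crv
}

# Greville abscissae (averaged knot sites), used by round-trip tests.
greville <- function(crv) {
  p <- crv$degree
  n <- nrow(crv$control)
  vapply(seq_len(n), function(i) mean(crv$knots[(i + 1L):(i + p)]), numeric(1L))
}
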