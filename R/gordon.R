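# Gordon surfaces over bidirectional curve networks: loft of u-curves plus
# loft of v-curves minus the tensor interpolation of the intersection grid.

#' Build a bidirectional curve network
#'
#' Every u-curve must intersect every v-curve exactly once within `tol`.
#' Intersection parameters, points and residuals are stored on the returned
#' object; missing intersections raise an error listing the offending pairs.
#'
#' @param u_curves,v_curves Lists of `nurbs_curve`s.
#' @param tol Network tolerance in mm (default 1e-6).
#' @return Object of class `curve_network`.
#' @export
curve_network <- function(u_curves, v_curves, tol = 1e-6) {
  nu <- length(u_curves)
  nv <- length(v_curves)
  if (nu < 2L || nv < 2L) {
    stop("a curve network needs at least 2 curves per direction", call. = FALSE)
  }
  u_par <- matrix(NA_real_, nu, nv)
  v_par <- matrix(NA_real_, nu, nv)
  pts <- array(NA_real_, c(nu, nv, 3L))
  res <- matrix(NA_real_, nu, nv)
  bad <- character(0)
  for (i in seq_len(nu)) {
    for (j in seq_len(nv)) {
      hit <- tryCatch(intersect_curves(u_curves[[i]], v_curves[[j]], tol = tol),
                      thvforge_no_intersection = function(e) e)
      if (inherits(hit, "condition")) {
        bad <- c(bad, sprintf("u-curve %d / v-curve %d (closest %.3g mm)",
                              i, j, hit$residual))
      } else {
        u_par[i, j] <- hit$u
        v_par[i, j] <- hit$v
        pts[i, j, ] <- hit$point
        res[i, j] <- hit$residual
      }
    }
  }
  if (length(bad)) {
    stop("incompatible curve network; missing intersections:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  structure(list(u_curves = u_curves, v_curves = v_curves,
                 u_params = u_par, v_params = v_par,
                 points = pts, residuals = res, tol = tol),
            class = "curve_network")
}

#' @export
print.curve_network <- function(x, ...) {
  cat(sprintf("<curve_network> %d u-curves x %d v-curves, max residual %.3g mm\n",
              length(x$u_curves), length(x$v_curves), max(x$residuals)))
  invisible(x)
}

# Replace a rational curve by a non-rational cubic interpolant on the same
# parameterization (adaptive sampling to `tol`); used so Gordon constituent
# surfaces can be combined control-point-wise.
approx_nonrational <- function(crv, tol = 1e-9) {
  if (!is_rational(crv) && crv$degree == 3L) return(crv)
  dom <- curve_domain(crv)
  n <- 60L
  repeat {
    sigma <- seq(dom[1], dom[2], length.out = n)
    new_crv <- interpolate_at_params(eval_curve(crv, sigma),
                                     (sigma - dom[1]) / (dom[2] - dom[1]),
                                     degree = 3L)
    probe <- (sigma[-1L] + sigma[-n]) / 2
    err <- max(sqrt(rowSums((eval_curve(new_crv,
                                        (probe - dom[1]) / (dom[2] - dom[1])) -
                             eval_curve(crv, probe))^2)))
    if (err <= tol || n >= 960L) break
    n <- n * 2L
  }
  new_crv
}

# Reparameterize a curve so that it passes through its grid points at the
# common parameters `s`: the curve is split at its own intersection
# parameters, each piece's knot span is rescaled onto [s_i, s_{i+1}], and
# the pieces are concatenated. Geometry is preserved exactly (splitting and
# affine knot maps are exact); only the parameter speed is piecewise
# rescaled. Rational inputs are first approximated by non-rational cubics.
reparameterize_to <- function(crv, s, own_params, tol = 1e-9) {
  crv <- approx_nonrational(crv, tol)
  dom <- curve_domain(crv)
  span <- own_params[length(own_params)] - own_params[1L]
  if (span <= 1e-12) stop("degenerate intersection parameter range", call. = FALSE)
  identity_map <- max(abs(own_params - (own_params[1L] + s * span))) < 1e-12
  if (identity_map && abs(dom[1]) < 1e-12 && abs(dom[2] - 1) < 1e-12 &&
      abs(own_params[1L]) < 1e-12 &&
      abs(own_params[length(own_params)] - 1) < 1e-12) {
    return(crv)
  }
  q <- (own_params - dom[1]) / (dom[2] - dom[1])
  # trim outside the extreme intersections
  if (q[1L] > 1e-9) {
    crv <- split_curve(crv, q[1L])[[2L]]
    q <- (q - q[1L]) / (1 - q[1L])
  }
  nq <- length(q)
  if (q[nq] < 1 - 1e-9) {
    crv <- split_curve(crv, q[nq])[[1L]]
    q <- q / q[nq]
  }
  q[1L] <- 0; q[nq] <- 1
  pieces <- list()
  rest <- crv
  for (i in seq_len(nq - 2L) + 1L) {
    sp <- split_curve(rest, q[i])
    pieces[[length(pieces) + 1L]] <- sp[[1L]]
    rest <- sp[[2L]]
    q <- (q - q[i]) / (1 - q[i])
  }
  pieces[[length(pieces) + 1L]] <- rest
  p <- crv$degree
  ctrl <- NULL
  wts <- NULL
  knots <- NULL
  for (i in seq_along(pieces)) {
    pc <- pieces[[i]]
    k <- s[i] + pc$knots * (s[i + 1L] - s[i])
    if (is.null(ctrl)) {
      ctrl <- pc$control
      wts <- pc$weights
      knots <- k[seq_len(length(k) - 1L)]
    } else {
      ctrl <- rbind(ctrl, pc$control[-1L, , drop = FALSE])
      wts <- c(wts, pc$weights[-1L])
      knots <- c(knots, k[(p + 2L):(length(k) - 1L)])
    }
  }
  knots <- c(knots, 1)                    # restore full end multiplicity
  nurbs_curve(ctrl, knots = knots, weights = wts, degree = p)
}

#' Construct a Gordon surface from a curve network
#'
#' Classic Gordon construction: the loft of the u-curves plus the loft of
#' the v-curves minus the tensor-product interpolation of the intersection
#' grid, on a shared parameterization. Curves whose intersections do not
#' already fall at common parameters are reparameterized by a monotone
#' spline map and resampled to `resample_tol` before assembly; rational
#' curves are likewise replaced by non-rational cubic interpolants so the
#' three constituent surfaces can be combined control-point-wise.
#'
#' @param net A `curve_network`.
#' @param resample_tol Geometric tolerance of the internal resampling (mm).
#' @return A `nurbs_surface` interpolating every network curve; attributes
#'   `s_params` / `t_params` hold the iso-parameters of the v- and u-curves.
#' @export
gordon_surface <- function(net, resample_tol = 1e-9) {
  nu <- length(net$u_curves)
  nv <- length(net$v_curves)
  s <- colMeans(net$u_params)            # common u-positions of the v-curves
  t <- rowMeans(net$v_params)            # common v-positions of the u-curves
  if (any(diff(s) <= 0) || any(diff(t) <= 0)) {
    stop("network intersections are not consistently ordered", call. = FALSE)
  }
  s_n <- (s - s[1L]) / (s[nv] - s[1L])
  t_n <- (t - t[1L]) / (t[nu] - t[1L])
  uc <- lapply(seq_len(nu), function(i) {
    reparameterize_to(net$u_curves[[i]], s_n, net$u_params[i, ], resample_tol)
  })
  vc <- lapply(seq_len(nv), function(j) {
    reparameterize_to(net$v_curves[[j]], t_n, net$v_params[, j], resample_tol)
  })
  q_u <- min(3L, nv - 1L)                # stacking degree along u (v-curves)
  q_v <- min(3L, nu - 1L)                # stacking degree along v (u-curves)
  S1 <- loft(uc, params = t_n, degree = q_v)
  S2 <- surface_transpose(loft(vc, params = s_n, degree = q_u))
  # tensor interpolation of the grid with the same two stacking schemes
  su <- stack_scheme(s_n, q_u)
  sv <- stack_scheme(t_n, q_v)
  mid <- array(0, c(nv, nu, 3L))         # interpolate rows over s first
  for (i in seq_len(nu)) {
    mid[, i, ] <- stack_interp(matrix(net$points[i, , ], nv, 3L), s_n, su)
  }
  ctrl <- array(0, c(nv, nu, 3L))
  for (l in seq_len(nv)) {
    ctrl[l, , ] <- stack_interp(matrix(mid[l, , ], nu, 3L), t_n, sv)
  }
  TT <- nurbs_surface(ctrl, knots_u = su$knots, knots_v = sv$knots,
                      degree_u = q_u, degree_v = q_v)
  cc <- make_surfaces_compatible(list(S1, S2, TT))
  if (any(vapply(cc, is_rational_surface, logical(1L)))) {
    stop("internal error: rational surfaces in Gordon combination", call. = FALSE)
  }
  G <- cc[[1L]]
  G$control <- cc[[1L]]$control + cc[[2L]]$control - cc[[3L]]$control
  attr(G, "s_params") <- s_n
  attr(G, "t_params") <- t_n
  attr(G, "u_curves") <- uc
  attr(G, "v_curves") <- vc
  G
}

is_rational_surface <- function(s) any(abs(s$weights - 1) > 1e-12)

# Largest distance from dense samples of each network curve to the surface
# iso-curve where it should be interpolated; the backbone of the network QC.
network_interpolation_residual <- function(srf, n_samples = 80L) {
  s_n <- attr(srf, "s_params")
  t_n <- attr(srf, "t_params")
  uc <- attr(srf, "u_curves")
  vc <- attr(srf, "v_curves")
  if (is.null(uc)) stop("surface carries no network attributes", call. = FALSE)
  worst <- 0
  xs <- seq(0, 1, length.out = n_samples)
  for (i in seq_along(uc)) {
    d <- eval_surface(srf, xs, t_n[i]) - eval_curve(uc[[i]], xs)
    worst <- max(worst, sqrt(max(rowSums(d^2))))
  }
  for (j in seq_along(vc)) {
    d <- eval_surface(srf, s_n[j], xs) - eval_curve(vc[[j]], xs)
    worst <- max(worst, sqrt(max(rowSums(d^2))))
  }
  worst
}
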