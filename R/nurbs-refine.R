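# Knot insertion, uniform h-refinement, splitting and (internal) degree
# elevation. All operations are exact on the geometry: refined/split/elevated
# objects evaluate to the same points as their inputs.

# Knot refinement (insert the sorted vector x) in homogeneous coordinates.
refine_curve_knots <- function(crv, x) {
  x <- sort(as.numeric(x))
  if (!length(x)) return(crv)
  p <- crv$degree
  U <- crv$knots
  Pw <- homog(crv)
  n <- nrow(Pw) - 1L                    # 0-based last control index
  m <- n + p + 1L                       # 0-based last knot index
  r <- length(x) - 1L
  a <- find_span(x[1L], p, U, n + 1L) - 1L
  b <- find_span(x[r + 1L], p, U, n + 1L)
  Ubar <- numeric(m + r + 2L)
  Qw <- matrix(0, n + r + 2L, 4L)
  for (j in 0:(a - p)) Qw[j + 1L, ] <- Pw[j + 1L, ]
  for (j in (b - 1L):n) Qw[j + r + 2L, ] <- Pw[j + 1L, ]
  for (j in 0:a) Ubar[j + 1L] <- U[j + 1L]
  for (j in (b + p):m) Ubar[j + r + 2L] <- U[j + 1L]
  i <- b + p - 1L
  k <- b + p + r
  for (j in r:0) {
    while (x[j + 1L] <= U[i + 1L] && i > a) {
      Qw[k - p, ] <- Pw[i - p, ]
      Ubar[k + 1L] <- U[i + 1L]
      k <- k - 1L
      i <- i - 1L
    }
    Qw[k - p, ] <- Qw[k - p + 1L, ]
    for (l in 1:p) {
      ind <- k - p + l
      alfa <- Ubar[k + l + 1L] - x[j + 1L]
      if (alfa == 0) {
        Qw[ind, ] <- Qw[ind + 1L, ]
      } else {
        alfa <- alfa / (Ubar[k + l + 1L] - U[i - p + l + 1L])
        Qw[ind, ] <- alfa * Qw[ind, ] + (1 - alfa) * Qw[ind + 1L, ]
      }
    }
    Ubar[k + 1L] <- x[j + 1L]
    k <- k - 1L
  }
  curve_from_homog(Qw, Ubar, p)
}

refine_surface_knots <- function(srf, x, direction = c("u", "v")) {
  direction <- match.arg(direction)
  if (direction == "v") {
    return(surface_transpose(refine_surface_knots(surface_transpose(srf), x, "u")))
  }
  if (!length(x)) return(srf)
  nv <- dim(srf$control)[2L]
  cols <- vector("list", nv)
  for (j in seq_len(nv)) {
    cv <- nurbs_curve(srf$control[, j, ], knots = srf$knots_u,
                      weights = srf$weights[, j], degree = srf$degree_u)
    cols[[j]] <- refine_curve_knots(cv, x)
  }
  nu2 <- nrow(cols[[1L]]$control)
  ctrl <- array(0, c(nu2, nv, 3L))
  W <- matrix(0, nu2, nv)
  for (j in seq_len(nv)) {
    ctrl[, j, ] <- cols[[j]]$control
    W[, j] <- cols[[j]]$weights
  }
  nurbs_surface(ctrl, knots_u = cols[[1L]]$knots, knots_v = srf$knots_v,
                weights = W, degree_u = srf$degree_u, degree_v = srf$degree_v)
}

#' Uniform h-refinement
#'
#' Splits every non-degenerate knot span at its midpoint, `levels` times.
#' Geometry is unchanged; the span count doubles per level (per direction for
#' surfaces).
#'
#' @param g A `nurbs_curve` or `nurbs_surface`.
#' @param levels Non-negative integer refinement levels.
#' @return Refined object of the same class.
#' @export
h_refine_uniform <- function(g, levels) {
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 0L) {
    stop("levels must be a non-negative integer", call. = FALSE)
  }
  if (levels == 0L) return(g)
  for (lev in seq_len(levels)) {
    if (inherits(g, "nurbs_curve")) {
      br <- knot_breaks(g$knots)
      g <- refine_curve_knots(g, (br[-1L] + br[-length(br)]) / 2)
    } else if (inherits(g, "nurbs_surface")) {
      bu <- knot_breaks(g$knots_u)
      bv <- knot_breaks(g$knots_v)
      g <- refine_surface_knots(g, (bu[-1L] + bu[-length(bu)]) / 2, "u")
      g <- refine_surface_knots(g, (bv[-1L] + bv[-length(bv)]) / 2, "v")
    } else {
      stop("h_refine_uniform expects a nurbs_curve or nurbs_surface",
           call. = FALSE)
    }
  }
  g
}

#' Split a curve at an interior parameter
#'
#' @param curve A `nurbs_curve`.
#' @param u Strictly interior parameter.
#' @return List of two clamped `nurbs_curve`s, each reparameterized to
#'   \[0, 1\], whose union reproduces the original geometry.
#' @export
split_curve <- function(curve, u) {
  dom <- curve_domain(curve)
  if (u <= dom[1] + 1e-12 || u >= dom[2] - 1e-12) {
    stop("split parameter must be strictly interior to [", dom[1], ", ",
         dom[2], "]", call. = FALSE)
  }
  p <- curve$degree
  s <- sum(abs(curve$knots - u) < 1e-13)
  if (s < p) curve <- refine_curve_knots(curve, rep(u, p - s))
  U <- curve$knots
  a <- which(abs(U - u) < 1e-13)[1L]     # first of the p coincident knots
  P <- curve$control
  w <- curve$weights
  k_left <- c(U[1:(a - 1L)], rep(u, p + 1L))
  k_right <- c(rep(u, p + 1L), U[(a + p):length(U)])
  renorm <- function(K) (K - K[1L]) / (K[length(K)] - K[1L])
  left <- nurbs_curve(P[1:(a - 1L), , drop = FALSE], knots = renorm(k_left),
                      weights = w[1:(a - 1L)], degree = p)
  right <- nurbs_curve(P[(a - 1L):nrow(P), , drop = FALSE],
                       knots = renorm(k_right),
                       weights = w[(a - 1L):nrow(P)], degree = p)
  list(left, right)
}

# --- internal degree elevation (Bezier decomposition) -----------------------

# Insert knots so every interior breakpoint has multiplicity p.
decompose_bezier <- function(crv) {
  p <- crv$degree
  br <- knot_breaks(crv$knots)
  ins <- numeric(0)
  for (b in br[-c(1L, length(br))]) {
    mult <- sum(abs(crv$knots - b) < 1e-13)
    if (mult < p) ins <- c(ins, rep(b, p - mult))
  }
  refine_curve_knots(crv, ins)
}

# Raise the degree by one (exact, homogeneous coordinates); interior
# breakpoints end up with multiplicity p + 1 (C0 representation).
elevate_once <- function(crv) {
  crv <- decompose_bezier(crv)
  p <- crv$degree
  q <- p + 1L
  Pw <- homog(crv)
  br <- knot_breaks(crv$knots)
  nseg <- length(br) - 1L
  out <- NULL
  for (s in seq_len(nseg)) {
    idx <- ((s - 1L) * p + 1L):((s - 1L) * p + p + 1L)
    B <- Pw[idx, , drop = FALSE]
    Q <- matrix(0, q + 1L, 4L)
    for (i in 0:q) {
      a <- i / q
      lo <- if (i > 0L) B[i, ] else 0
      hi <- if (i <= p) B[i + 1L, ] else 0
      Q[i + 1L, ] <- a * lo + (1 - a) * hi
    }
    out <- if (is.null(out)) Q else rbind(out, Q[-1L, , drop = FALSE])
  }
  knots <- c(rep(br[1L], q + 1L),
             rep(br[-c(1L, length(br))], each = q),
             rep(br[length(br)], q + 1L))
  curve_from_homog(out, knots, q)
}

elevate_curve_degree <- function(crv, to) {
  while (crv$degree < to) crv <- elevate_once(crv)
  crv
}

elevate_surface_degree <- function(srf, to_u, to_v) {
  while (srf$degree_u < to_u) {
    nv <- dim(srf$control)[2L]
    cols <- lapply(seq_len(nv), function(j) {
      elevate_once(nurbs_curve(srf$control[, j, ], knots = srf$knots_u,
                               weights = srf$weights[, j],
                               degree = srf$degree_u))
    })
    nu2 <- nrow(cols[[1L]]$control)
    ctrl <- array(0, c(nu2, nv, 3L))
    W <- matrix(0, nu2, nv)
    for (j in seq_len(nv)) {
      ctrl[, j, ] <- cols[[j]]$control
      W[, j] <- cols[[j]]$weights
    }
    srf <- nurbs_surface(ctrl, knots_u = cols[[1L]]$knots,
                         knots_v = srf$knots_v, weights = W,
                         degree_u = srf$degree_u + 1L,
                         degree_v = srf$degree_v)
  }
  if (srf$degree_v < to_v) {
    srf <- surface_transpose(elevate_surface_degree(surface_transpose(srf),
                                                    to_v, srf$degree_u))
  }
  srf
}

# Merge knot vectors: refine each curve to the union (with multiplicities).
knot_union <- function(knot_list, tol = 1e-12) {
  all_breaks <- sort(unique(round(unlist(lapply(knot_list, knot_breaks)) / tol) * tol))
  mult <- function(U, b) sum(abs(U - b) < 10 * tol)
  target <- vapply(all_breaks, function(b) {
    max(vapply(knot_list, mult, integer(1L) + 0L, b = b))
  }, numeric(1L))
  list(breaks = all_breaks, mult = target)
}

make_curves_knot_compatible <- function(curves) {
  degs <- vapply(curves, function(cv) cv$degree, integer(1L))
  p <- max(degs)
  curves <- lapply(curves, elevate_curve_degree, to = p)
  un <- knot_union(lapply(curves, function(cv) cv$knots))
  lapply(curves, function(cv) {
    ins <- numeric(0)
    for (k in seq_along(un$breaks)) {
      b <- un$breaks[k]
      have <- sum(abs(cv$knots - b) < 1e-11)
      need <- un$mult[k]
      if (k %in% c(1L, length(un$breaks))) next    # clamped ends already full
      if (have < need) ins <- c(ins, rep(b, need - have))
    }
    if (length(ins)) refine_curve_knots(cv, ins) else cv
  })
}
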