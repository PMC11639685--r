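# Exact rational circular arcs, curve joining, and point-to-curve projection.

#' Exact circular arc through three points
#'
#' Builds the rational quadratic Bezier arc through `p1`, `p2`, `p3`
#' (circumcircle construction, sweep < 180 degrees required), then elevates
#' it to degree 3 so it can join cubic curve networks. The representation is
#' exact: every point lies on the circumcircle to machine precision.
#'
#' @param p1,p2,p3 Length-3 points (mm); `p2` selects the arc side.
#' @return List with `curve` (rational cubic `nurbs_curve`), `center`,
#'   `radius`, `normal`.
#' @export
circle_arc_3pt <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  a <- p2 - p1
  b <- p3 - p1
  nrm <- c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
  n2 <- sum(nrm^2)
  if (sqrt(n2) < 1e-10 * max(sqrt(sum(a^2)), sqrt(sum(b^2)))^2) {
    stop("arc points are (nearly) collinear", call. = FALSE)
  }
  # circumcenter: O = p1 + (|b|^2 (n x a) + |a|^2 (b x n)) / (2 |n|^2)
  cross <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                            x[3] * y[1] - x[1] * y[3],
                            x[1] * y[2] - x[2] * y[1])
  O <- p1 + (sum(b^2) * cross(nrm, a) + sum(a^2) * cross(b, nrm)) / (2 * n2)
  R <- sqrt(sum((p1 - O)^2))
  u1 <- (p1 - O) / R
  u3 <- (p3 - O) / R
  cth <- max(-1, min(1, sum(u1 * u3)))
  theta <- acos(cth)                      # sweep from p1 to p3
  # ensure the arc passes on the p2 side (sweep through p2 must be interior)
  if (theta > pi - 1e-9) stop("arc sweep must be < 180 degrees", call. = FALSE)
  mid_dir <- (u1 + u3)
  mid_dir <- mid_dir / sqrt(sum(mid_dir^2))
  if (sum((O + R * mid_dir - p2) * (O + R * mid_dir - p2)) >
      sum((O - R * mid_dir - p2) * (O - R * mid_dir - p2))) {
    stop("middle point is not on the minor arc between the endpoints",
         call. = FALSE)
  }
  w1 <- cos(theta / 2)
  apex <- O + (R / w1) * mid_dir
  quad <- nurbs_curve(rbind(p1, apex, p3),
                      knots = c(0, 0, 0, 1, 1, 1),
                      weights = c(1, w1, 1), degree = 2L)
  cubic <- elevate_curve_degree(quad, 3L)
  list(curve = cubic, center = O, radius = R, normal = nrm / sqrt(n2))
}

# C0-join two curves sharing an endpoint (end of a == start of b).
join_curves <- function(a, b, tol = 1e-6) {
  pa <- a$control[nrow(a$control), ]
  pb <- b$control[1L, ]
  gap <- sqrt(sum((pa - pb)^2))
  if (gap > tol) {
    stop(sprintf("cannot join curves: endpoint gap %.3g mm exceeds %g mm",
                 gap, tol), call. = FALSE)
  }
  if (a$degree != b$degree) {
    p <- max(a$degree, b$degree)
    a <- elevate_curve_degree(a, p)
    b <- elevate_curve_degree(b, p)
  }
  p <- a$degree
  la <- curve_length(a, rel_tol = 1e-8)
  lb <- curve_length(b, rel_tol = 1e-8)
  sbreak <- la / (la + lb)
  ka <- (a$knots - a$knots[1L]) / (a$knots[length(a$knots)] - a$knots[1L]) * sbreak
  kb <- sbreak + (b$knots - b$knots[1L]) /
    (b$knots[length(b$knots)] - b$knots[1L]) * (1 - sbreak)
  knots <- c(ka[seq_len(length(ka) - 1L)], kb[(p + 2L):length(kb)])
  ctrl <- rbind(a$control, b$control[-1L, , drop = FALSE])
  wts <- c(a$weights, b$weights[-1L])
  out <- nurbs_curve(ctrl, knots = knots, weights = wts, degree = p)
  attr(out, "join_param") <- sbreak
  out
}

# Closest distance from point(s) to a curve (grid seed + 1D damped Newton).
project_point_to_curve <- function(crv, pts, grid_n = 128L) {
  pts <- if (is.matrix(pts)) pts else matrix(pts, 1L)
  dom <- curve_domain(crv)
  us <- seq(dom[1], dom[2], length.out = grid_n)
  S <- eval_curve(crv, us)
  out_u <- numeric(nrow(pts))
  out_d <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    q <- pts[k, ]
    d2 <- rowSums(sweep(S, 2L, q, "-")^2)
    u <- us[which.min(d2)]
    f <- min(d2)
    for (it in seq_len(60L)) {
      dd <- curve_derivs(crv, u, 2L)
      r <- dd[[1L]][1L, ] - q
      g <- 2 * sum(r * dd[[2L]][1L, ])
      h <- 2 * (sum(dd[[2L]][1L, ]^2) + sum(r * dd[[3L]][1L, ]))
      step <- if (is.finite(h) && abs(h) > 1e-30) -g / h else -g
      lam <- 1
      moved <- FALSE
      for (ls in seq_len(25L)) {
        u_new <- min(max(u + lam * step, dom[1]), dom[2])
        d <- drop(eval_curve(crv, u_new)) - q
        f_new <- sum(d * d)
        if (f_new < f - 1e-30) {
          u <- u_new; f <- f_new; moved <- TRUE
          break
        }
        lam <- lam / 2
      }
      if (!moved || lam * abs(step) < 1e-15) break
    }
    out_u[k] <- u
    out_d[k] <- sqrt(f)
  }
  list(u = out_u, distance = out_d)
}
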