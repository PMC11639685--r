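# Curve-curve closest-point / intersection search: coarse parameter grid
# seeding followed by damped Newton iteration on the squared distance.

#' Intersect (or find the closest approach of) two curves
#'
#' Minimizes the squared distance between the curves over their parameter
#' rectangle, starting from the best cell of a coarse sampling grid. Success
#' requires the residual distance to fall below `tol`.
#'
#' @param a,b `nurbs_curve` objects.
#' @param tol Acceptance tolerance in mm (default 1e-6).
#' @param grid_n Sampling grid resolution per curve (default 64).
#' @return List with `u`, `v` (parameters on `a` and `b`), `point`
#'   (midpoint of the two footpoints, mm) and `residual` (closest distance,
#'   mm). Throws a condition of class `thvforge_no_intersection` when the
#'   curves do not approach within `tol`.
#' @export
intersect_curves <- function(a, b, tol = 1e-6, grid_n = 64L) {
  dom_a <- curve_domain(a)
  dom_b <- curve_domain(b)
  us <- seq(dom_a[1], dom_a[2], length.out = grid_n)
  vs <- seq(dom_b[1], dom_b[2], length.out = grid_n)
  Pa <- eval_curve(a, us)
  Pb <- eval_curve(b, vs)
  # pairwise squared distances via the expansion |a|^2 + |b|^2 - 2 a.b
  D2 <- outer(rowSums(Pa^2), rowSums(Pb^2), "+") - 2 * Pa %*% t(Pb)
  idx <- arrayInd(which.min(D2), dim(D2))
  u <- us[idx[1L]]
  v <- vs[idx[2L]]
  clamp <- function(x, dom) min(max(x, dom[1]), dom[2])
  f_of <- function(u, v) {
    d <- eval_curve(a, u) - eval_curve(b, v)
    sum(d * d)
  }
  f <- f_of(u, v)
  for (iter in seq_len(100L)) {
    da <- curve_derivs(a, u, 2L)
    db <- curve_derivs(b, v, 2L)
    r <- da[[1L]][1L, ] - db[[1L]][1L, ]
    a1 <- da[[2L]][1L, ]; a2 <- da[[3L]][1L, ]
    b1 <- db[[2L]][1L, ]; b2 <- db[[3L]][1L, ]
    g <- 2 * c(sum(r * a1), -sum(r * b1))
    H <- 2 * matrix(c(sum(a1 * a1) + sum(r * a2), -sum(a1 * b1),
                      -sum(a1 * b1), sum(b1 * b1) - sum(r * b2)), 2L, 2L)
    step <- tryCatch(-solve(H, g), error = function(e) -g)
    if (!all(is.finite(step))) step <- -g
    lambda <- 1
    improved <- FALSE
    for (ls in seq_len(30L)) {
      u_new <- clamp(u + lambda * step[1L], dom_a)
      v_new <- clamp(v + lambda * step[2L], dom_b)
      f_new <- f_of(u_new, v_new)
      if (f_new < f - 1e-30) {
        u <- u_new; v <- v_new; f <- f_new
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved || lambda * max(abs(step)) < 1e-15) break
  }
  residual <- sqrt(f)
  if (residual > tol) {
    cond <- structure(
      class = c("thvforge_no_intersection", "error", "condition"),
      list(message = sprintf(
             "curves do not approach within tol = %g (closest %g mm)",
             tol, residual),
           call = sys.call(-1L), residual = residual))
    stop(cond)
  }
  pa <- drop(eval_curve(a, u))
  pb <- drop(eval_curve(b, v))
  list(u = u, v = v, point = (pa + pb) / 2, residual = residual)
}
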