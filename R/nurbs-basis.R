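# B-spline basis machinery: knot vectors, span lookup, basis functions and
# their derivatives. Everything here is 1-based; `i` always denotes the span
# index returned by find_span(), i.e. knots[i] <= u < knots[i + 1].

#' Open (clamped) uniform knot vector
#'
#' Builds the clamped knot vector with `n_ctrl - degree` uniformly spaced
#' non-degenerate spans on \[0, 1\]. End knots carry multiplicity
#' `degree + 1`.
#'
#' @param n_ctrl Number of control points (>= degree + 1).
#' @param degree Polynomial degree (3 for all valve curves).
#' @return Numeric knot vector of length `n_ctrl + degree + 1`.
#' @export
#' @examples
#' open_uniform_knots(4, 3)   # single Bezier segment
#' open_uniform_knots(5, 3)   # interior knot at 0.5
open_uniform_knots <- function(n_ctrl, degree) {
  n_ctrl <- as.integer(n_ctrl)
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1", call. = FALSE)
  if (n_ctrl < degree + 1L) {
    stop("n_ctrl must be at least degree + 1 (got ", n_ctrl, " for degree ",
         degree, ")", call. = FALSE)
  }
  n_span <- n_ctrl - degree
  c(rep(0, degree + 1L),
    if (n_span > 1L) seq_len(n_span - 1L) / n_span,
    rep(1, degree + 1L))
}

# Unique breakpoints of the non-degenerate spans.
knot_breaks <- function(U, tol = 1e-12) {
  br <- U[c(TRUE, diff(U) > tol)]
  br
}

# Number of non-degenerate knot spans.
n_spans <- function(U, tol = 1e-12) {
  length(knot_breaks(U, tol)) - 1L
}

find_span <- function(u, p, U, n) {
  if (u >= U[n + 1L]) return(n)
  if (u <= U[p + 1L]) return(p + 1L)
  lo <- p + 1L
  hi <- n + 1L
  mid <- (lo + hi) %/% 2L
  while (u < U[mid] || u >= U[mid + 1L]) {
    if (u < U[mid]) hi <- mid else lo <- mid
    mid <- (lo + hi) %/% 2L
  }
  mid
}

# Nonzero basis functions N_{i-p},...,N_i at u (Cox-de Boor recursion).
basis_funs <- function(i, u, p, U) {
  N <- numeric(p + 1L)
  N[1L] <- 1
  if (p == 0L) return(N)
  left <- numeric(p)
  right <- numeric(p)
  for (j in 1:p) {
    left[j] <- u - U[i + 1L - j]
    right[j] <- U[i + j] - u
    saved <- 0
    for (r in 1:j) {
      temp <- N[r] / (right[r] + left[j - r + 1L])
      N[r] <- saved + right[r] * temp
      saved <- left[j - r + 1L] * temp
    }
    N[j + 1L] <- saved
  }
  N
}

# Basis functions and derivatives up to order n_der; returns an
# (n_der + 1) x (p + 1) matrix, row k+1 = k-th derivative of the p+1
# nonzero functions.
ders_basis_funs <- function(i, u, p, n_der, U) {
  ndu <- matrix(0, p + 1L, p + 1L)
  ndu[1L, 1L] <- 1
  left <- numeric(p + 1L)
  right <- numeric(p + 1L)
  if (p > 0L) {
    for (j in 1:p) {
      left[j + 1L] <- u - U[i + 1L - j]
      right[j + 1L] <- U[i + j] - u
      saved <- 0
      for (r in 0:(j - 1L)) {
        ndu[j + 1L, r + 1L] <- right[r + 2L] + left[j - r + 1L]
        temp <- ndu[r + 1L, j] / ndu[j + 1L, r + 1L]
        ndu[r + 1L, j + 1L] <- saved + right[r + 2L] * temp
        saved <- left[j - r + 1L] * temp
      }
      ndu[j + 1L, j + 1L] <- saved
    }
  }
  ders <- matrix(0, n_der + 1L, p + 1L)
  ders[1L, ] <- ndu[, p + 1L]
  if (n_der == 0L || p == 0L) return(ders)
  a <- matrix(0, 2L, p + 1L)
  for (r in 0:p) {
    s1 <- 1L
    s2 <- 2L
    a[1L, 1L] <- 1
    for (k in 1:min(n_der, p)) {
      d <- 0
      rk <- r - k
      pk <- p - k
      if (r >= k) {
        a[s2, 1L] <- a[s1, 1L] / ndu[pk + 2L, rk + 1L]
        d <- a[s2, 1L] * ndu[rk + 1L, pk + 1L]
      }
      j1 <- if (rk >= -1L) 1L else -rk
      j2 <- if (r - 1L <= pk) k - 1L else p - r
      if (j2 >= j1) {
        for (j in j1:j2) {
          a[s2, j + 1L] <- (a[s1, j + 1L] - a[s1, j]) / ndu[pk + 2L, rk + j + 1L]
          d <- d + a[s2, j + 1L] * ndu[rk + j + 1L, pk + 1L]
        }
      }
      if (r <= pk) {
        a[s2, k + 1L] <- -a[s1, k] / ndu[pk + 2L, r + 1L]
        d <- d + a[s2, k + 1L] * ndu[r + 1L, pk + 1L]
      }
      ders[k + 1L, r + 1L] <- d
      tmp <- s1; s1 <- s2; s2 <- tmp
    }
  }
  fac <- p
  for (k in 1:min(n_der, p)) {
    ders[k + 1L, ] <- ders[k + 1L, ] * fac
    fac <- fac * (p - k)
  }
  ders
}
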