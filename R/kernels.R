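# Pointwise mechanical kernels: beam cross-section frames (azimuthal
# reference construction and twist-free frame propagation), the Lee-Sacks
# hyperelastic energy with analytic invariant derivatives, penalty-coupling
# parameter formulas, and the nonlocal contact and static-friction kernels.
# Everything here is an evaluator with explicit unit contracts (mm, kPa);
# quadrature and assembly belong to the downstream solver.

#' Azimuthal unit vector
#'
#' @param phi_c Azimuth in degrees.
#' @return `(-sin(phi_c), cos(phi_c), 0)`.
#' @export
phi_hat <- function(phi_c) {
  a <- deg2rad(phi_c)
  c(-sin(a), cos(a), 0)
}

#' Beam cross-section frame at a curve parameter
#'
#' `v1` is the unit tangent; `v2 = v1 x phi_hat` and `v3 = v1 x v2`
#' (normalized), where the azimuth is taken from the evaluation point. The
#' rectangular wire section extends along `v2` (width) and `v3` (height).
#'
#' @param curve Stent centerline (`nurbs_curve`).
#' @param u Parameter value(s).
#' @return List of matrices `v1`, `v2`, `v3` (one row per parameter).
#' @export
section_frame <- function(curve, u) {
  d <- curve_derivs(curve, u, 1L)
  P <- d[[1L]]
  Tg <- d[[2L]]
  m <- nrow(P)
  v1 <- v2 <- v3 <- matrix(0, m, 3L)
  for (k in seq_len(m)) {
    t1 <- Tg[k, ]
    nt <- sqrt(sum(t1^2))
    if (nt < 1e-14) stop("degenerate frame: zero tangent", call. = FALSE)
    t1 <- t1 / nt
    ph <- phi_hat(atan2(P[k, 2L], P[k, 1L]) * 180 / pi)
    c2 <- c(t1[2L] * ph[3L] - t1[3L] * ph[2L],
            t1[3L] * ph[1L] - t1[1L] * ph[3L],
            t1[1L] * ph[2L] - t1[2L] * ph[1L])
    n2 <- sqrt(sum(c2^2))
    if (n2 < 1e-10) {
      stop("degenerate frame: tangent parallel to the azimuthal direction",
           call. = FALSE)
    }
    c2 <- c2 / n2
    c3 <- c(t1[2L] * c2[3L] - t1[3L] * c2[2L],
            t1[3L] * c2[1L] - t1[1L] * c2[3L],
            t1[1L] * c2[2L] - t1[2L] * c2[1L])
    v1[k, ] <- t1; v2[k, ] <- c2; v3[k, ] <- c3
  }
  list(v1 = v1, v2 = v2, v3 = v3)
}

#' Minimal rotation mapping one unit vector onto another
#'
#' Euler--Rodrigues rotation about `a x b` by the angle between `a` and
#' `b`; the identity when they coincide. Antiparallel inputs have no
#' minimal rotation and raise an error.
#'
#' @param a,b Unit 3-vectors.
#' @return 3 x 3 rotation matrix `L` with `L %*% a = b`.
#' @export
mapping_operator <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    stop("undefined rotation: vectors are antiparallel", call. = FALSE)
  }
  v <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3L) + K + K %*% K / (1 + c_)
}

#' Rotation about an axis
#'
#' @param axis Unit 3-vector.
#' @param theta Angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
axis_rotation <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg2rad(theta)
  K <- matrix(c(0, axis[3L], -axis[2L], -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Propagate twist-free frames along a curve
#'
#' The first triad maps the global reference frame onto the initial
#' tangent; subsequent stations apply the minimal rotation between
#' consecutive tangents (discrete parallel transport, avoiding spurious
#' twist where the centerline turns), then the per-station rotation
#' `theta0` about the local tangent.
#'
#' @param curve A `nurbs_curve`.
#' @param stations Increasing parameter values (>= 1).
#' @param theta0 Rotational offset in degrees (scalar or per station).
#' @param reference Global reference triad as a 3 x 3 matrix whose columns
#'   are (A1, A2, A3); default A1 = z.
#' @return Object of class `frame_field`: list with `stations`, `a1`, `a2`,
#'   `a3` (station-row matrices) and `theta`.
#' @export
propagate_frames <- function(curve, stations, theta0 = 0,
                             reference = cbind(c(0, 0, 1), c(1, 0, 0),
                                               c(0, 1, 0))) {
  ns <- length(stations)
  if (ns < 1L) stop("need at least one station", call. = FALSE)
  theta0 <- rep_len(theta0, ns)
  Tg <- curve_derivs(curve, stations, 1L)[[2L]]
  a1 <- a2 <- a3 <- matrix(0, ns, 3L)
  A1 <- reference[, 1L]
  prev_t <- NULL
  prev2 <- NULL
  prev3 <- NULL
  for (i in seq_len(ns)) {
    t1 <- Tg[i, ]
    nt <- sqrt(sum(t1^2))
    if (nt < 1e-14) {
      stop("propagation error: zero tangent at station ", i, call. = FALSE)
    }
    t1 <- t1 / nt
    if (i == 1L) {
      L <- mapping_operator(A1, t1)
      a2p <- drop(L %*% reference[, 2L])
      a3p <- drop(L %*% reference[, 3L])
    } else {
      if (sum(prev_t * t1) < -1 + 1e-12) {
        stop("propagation error: antiparallel tangents at station ", i,
             call. = FALSE)
      }
      L <- mapping_operator(prev_t, t1)
      a2p <- drop(L %*% prev2)
      a3p <- drop(L %*% prev3)
    }
    prev_t <- t1
    prev2 <- a2p
    prev3 <- a3p
    R <- axis_rotation(t1, theta0[i])
    a1[i, ] <- t1
    a2[i, ] <- drop(R %*% a2p)
    a3[i, ] <- drop(R %*% a3p)
  }
  structure(list(stations = stations, a1 = a1, a2 = a2, a3 = a3,
                 theta = theta0), class = "frame_field")
}

#' Lee--Sacks strain energy density and invariant derivatives
#'
#' `psi = c0/2 (I1 - 3) + c1/2 (w exp(c2 (I1-3)^2) +
#' (1-w) exp(c3 (I4-1)^2) - 1)` in kPa. `w = 1` recovers the isotropic
#' (skirt) model with no I4 dependence. Invariants beyond the configured
#' caps trigger a warning (the numerical-stability bound concept); values
#' are never silently clamped.
#'
#' @param I1 First invariant of the right Cauchy--Green tensor.
#' @param I4 Fiber-direction invariant.
#' @param params List with `c0`, `c1` (kPa), `c2`, `c3`, `w`.
#' @param caps Invariant warning bounds, default `c(I1 = 12, I4 = 4)`.
#' @return List with `psi` (kPa), `dpsi_dI1`, `dpsi_dI4`.
#' @export
lee_sacks_energy <- function(I1, I4 = 1, params, caps = c(I1 = 12, I4 = 4)) {
  if (any(I1 > caps[["I1"]]) || any(I4 > caps[["I4"]])) {
    warning(sprintf(
      "invariants exceed the stability caps (I1 <= %g, I4 <= %g)",
      caps[["I1"]], caps[["I4"]]))
  }
  c0 <- params$c0; c1 <- params$c1; c2 <- params$c2
  w <- params$w
  c3 <- if (is.null(params$c3)) 0 else params$c3
  e1 <- exp(c2 * (I1 - 3)^2)
  e4 <- exp(c3 * (I4 - 1)^2)
  psi <- c0 / 2 * (I1 - 3) + c1 / 2 * (w * e1 + (1 - w) * e4 - 1)
  list(psi = psi,
       dpsi_dI1 = c0 / 2 + c1 * w * c2 * (I1 - 3) * e1,
       dpsi_dI4 = c1 * (1 - w) * c3 * (I4 - 1) * e4)
}

#' Effective shell stiffness from the neo-Hookean shear term
#'
#' `E = 2 c0 (1 + nu)`; with the incompressible `nu = 0.5` this is `3 c0`.
#'
#' @param c0 Neo-Hookean coefficient (kPa; equals the shear modulus).
#' @param nu Poisson ratio.
#' @return Effective stiffness in kPa.
#' @export
effective_shell_stiffness <- function(c0, nu = 0.5) {
  if (c0 <= 0) stop("c0 must be positive", call. = FALSE)
  2 * c0 * (1 + nu)
}

#' Shell-shell penalty parameters
#'
#' Displacement and rotation penalties for a coupled shell interface:
#' `alpha_d = alpha E H / (h_I (1 - nu^2))` and
#' `alpha_r = alpha E H^3 / (12 h_I (1 - nu^2))`, so
#' `alpha_r / alpha_d = H^2 / 12` exactly.
#'
#' @param E Effective stiffness (kPa).
#' @param H Shell thickness (mm).
#' @param h_I Mean local element length along the penalty curve (mm).
#' @param nu Poisson ratio (|nu| < 1).
#' @param alpha Dimensionless penalty coefficient.
#' @return List with `alpha_d` and `alpha_r`.
#' @export
penalty_ss <- function(E, H, h_I, nu, alpha) {
  if (abs(nu) >= 1) stop("division error: |nu| must be < 1", call. = FALSE)
  ad <- alpha * E * H / (h_I * (1 - nu^2))
  list(alpha_d = ad, alpha_r = ad * H^2 / 12)
}

#' Shell-beam displacement penalty parameter
#'
#' The minimum of the shell and beam stiffness scales:
#' `alpha_d = alpha min(E_sh H / (h_sh (1 - nu_sh^2)),
#' E_be sqrt(A) / (h_be (1 - nu_be^2)))`.
#'
#' @param E_sh,H,h_sh,nu_sh Shell stiffness (kPa), thickness, local element
#'   length (mm), Poisson ratio.
#' @param E_be,A,h_be,nu_be Beam modulus (kPa), cross-section area (mm^2),
#'   local element length (mm), Poisson ratio.
#' @param alpha Dimensionless penalty coefficient.
#' @return List with `alpha_d` and `branch` (`"shell"` or `"beam"`).
#' @export
penalty_sb <- function(E_sh, H, h_sh, nu_sh, E_be, A, h_be, nu_be, alpha) {
  shell <- E_sh * H / (h_sh * (1 - nu_sh^2))
  beam <- E_be * sqrt(A) / (h_be * (1 - nu_be^2))
  list(alpha_d = alpha * min(shell, beam),
       branch = if (shell <= beam) "shell" else "beam")
}

#' Nonlocal linear contact kernel
#'
#' `phi_c'(r) = -max(k_c (r_max - r), 0)`: zero beyond the cutoff, linear
#' ramp inside, never positive.
#'
#' @param r Distance(s), mm (>= 0).
#' @param params List with `k_c` and `r_max`.
#' @return Signed kernel magnitude(s).
#' @export
contact_kernel <- function(r, params) {
  -pmax(params$k_c * (params$r_max - r), 0)
}

#' Static friction force kernel
#'
#' Pointwise friction estimate between a beam point and a wall point:
#' the tangential-slip excess since deployment scaled by the contact kernel
#' and the friction penalty, directed along the current tangential gap.
#' Inactive outside the contact cutoff; the zero-tangential-gap limit is
#' the zero vector (flagged via attribute `degenerate`).
#'
#' @param x_be,x_so Current beam / wall points (mm).
#' @param x_be_d,x_so_d The same points in the deployed configuration.
#' @param n,n_d Outward wall unit normals, current and deployed.
#' @param params List with `k_c`, `r_max`, `alpha_f`.
#' @return Force 3-vector (perpendicular to `n`).
#' @export
friction_force <- function(x_be, x_so, x_be_d, x_so_d, n, n_d, params) {
  r <- x_be - x_so
  rd <- x_be_d - x_so_d
  rn <- sqrt(sum(r^2))
  if (rn >= params$r_max) return(c(0, 0, 0))
  rt <- r - sum(r * n) * n
  rdt <- rd - sum(rd * n_d) * n_d
  nrt <- sqrt(sum(rt^2))
  if (nrt < 1e-14) {
    out <- c(0, 0, 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  params$alpha_f * abs(contact_kernel(rn, params)) *
    (nrt - sqrt(sum(rdt^2))) * rt / nrt
}
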