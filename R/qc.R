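# Geometric quality control: symmetry deviations, constraint collinearity,
# bounding dimensions, a geometric orifice-area proxy, and a combined
# machine-readable report.

# Exact max nearest-neighbor distance from each row of A to the set B,
# chunked to bound memory; the argmin is found via the quadratic expansion
# and the distance recomputed exactly (the expansion alone loses ~1e-7 mm
# to cancellation at valve scale).
nn_max_distance <- function(A, B, chunk = 512L) {
  worst <- 0
  b2 <- rowSums(B^2)
  for (i0 in seq(1L, nrow(A), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(A))
    Ac <- A[idx, , drop = FALSE]
    D2 <- outer(rowSums(Ac^2), b2, "+") - 2 * Ac %*% t(B)
    j <- max.col(-D2, ties.method = "first")
    d <- sqrt(rowSums((Ac - B[j, , drop = FALSE])^2))
    worst <- max(worst, max(d))
  }
  worst
}

#' Radial (n-fold) symmetry deviation of an assembly
#'
#' Rotates every control point by `360 / n_fold` degrees and reports the
#' largest distance to the nearest original control point.
#'
#' @param assembly A `valve_assembly`.
#' @param n_fold Symmetry order (>= 2; `1` returns 0 by definition).
#' @return Deviation in mm.
#' @export
check_radial_symmetry <- function(assembly, n_fold = 3L) {
  if (n_fold < 2L) return(0)
  P <- assembly_control_points(assembly)
  nn_max_distance(rotate_z(P, 360 / n_fold), P)
}

#' Mirror symmetry deviation of a component
#'
#' @param component A `nurbs_curve`, `nurbs_surface`, point matrix, or list
#'   thereof.
#' @param plane_phi Azimuth of the mirror plane in degrees.
#' @return Deviation in mm (nearest-neighbor correspondence).
#' @export
check_mirror_symmetry <- function(component, plane_phi = 60) {
  P <- collect_points(component)
  nn_max_distance(reflect(P, plane_phi), P)
}

collect_points <- function(g) {
  if (is.matrix(g)) return(g)
  if (inherits(g, "nurbs_curve")) return(g$control)
  if (inherits(g, "nurbs_surface")) return(matrix(g$control, ncol = 3L))
  if (is.list(g)) return(do.call(rbind, lapply(g, collect_points)))
  stop("cannot collect points from class ", paste(class(g), collapse = "/"),
       call. = FALSE)
}

#' Worst constraint-group collinearity residual
#'
#' Distance of each interior connection's middle control point to the line
#' through its outer two; groups without a full triple are skipped.
#'
#' @param cmap A `constraint_map`.
#' @return Max residual in mm.
#' @export
check_collinearity <- function(cmap) {
  res <- vapply(cmap, function(g) {
    if (g$n_pairs == 3L) g$collinearity else 0
  }, numeric(1L))
  if (length(res)) max(res) else 0
}

#' Bounding dimensions of an assembly
#'
#' @param assembly A `valve_assembly`.
#' @return Named vector `c(height, max_diameter)` in mm over all control
#'   points.
#' @export
bounding_dims <- function(assembly) {
  P <- assembly_control_points(assembly)
  r <- sqrt(P[, 1L]^2 + P[, 2L]^2)
  c(height = max(P[, 3L]) - min(P[, 3L]), max_diameter = 2 * max(r))
}

#' Base (inflow) diameter of a valve profile
#'
#' Twice the radius of the lowest baseline profile point -- the sizing
#' diameter of the device at its inflow rim.
#'
#' @param profile Profile element of a [valve_config] (or the config).
#' @return Diameter in mm.
#' @export
base_diameter <- function(profile) {
  if (inherits(profile, "valve_config")) profile <- profile$profile
  2 * profile$points$r[which.min(profile$points$z)]
}

#' Geometric orifice area
#'
#' Projects the three leaflet free edges onto the z-plane, orders them into
#' a closed loop, and evaluates the shoelace area. This is a geometry-only
#' proxy for the opening enclosed by the free edges in top view (it is not a
#' hemodynamic opening area).
#'
#' @param free_edges Either a `valve_assembly` or a list of free-edge
#'   `nurbs_curve`s.
#' @param n_samples Samples per edge (default 512).
#' @return Area in mm^2 (absolute-value convention; a warning is issued if
#'   the projected loop is not star-shaped about its centroid).
#' @export
geometric_orifice_area <- function(free_edges, n_samples = 512L) {
  if (inherits(free_edges, "valve_assembly")) {
    free_edges <- lapply(free_edges$leaflet_curves,
                         function(cs) cs$free_edge)
  }
  loop <- do.call(rbind, lapply(free_edges, function(cv) {
    eval_curve(cv, seq(0, 1, length.out = n_samples))[, 1:2, drop = FALSE]
  }))
  ctr <- colMeans(loop)
  ang <- atan2(loop[, 2L] - ctr[2L], loop[, 1L] - ctr[1L])
  dang <- diff(ang)
  dang <- (dang + pi) %% (2 * pi) - pi
  if (abs(abs(sum(dang)) - 2 * pi) > 0.1) {
    warning("projected free-edge loop does not wind once around its ",
            "centroid (likely self-intersecting); reporting absolute ",
            "shoelace area")
  }
  x <- loop[, 1L]; y <- loop[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

#' Geometric QC report for an assembly
#'
#' @param assembly A `valve_assembly`.
#' @param tol Named tolerances: `radial`, `mirror`, `collinearity`,
#'   `network` (mm).
#' @return Object of class `qc_report` with all residuals, dimensions,
#'   element counts, and an overall `pass` flag.
#' @export
qc_report <- function(assembly,
                      tol = c(radial = 1e-8, mirror = 1e-8,
                              collinearity = 1e-12, network = 1e-8)) {
  radial <- check_radial_symmetry(assembly, 3L)
  mirror <- if (!is.null(assembly$components)) {
    check_mirror_symmetry(assembly$components$leaflet$surface, 60)
  } else NA_real_
  collin <- check_collinearity(assembly$stent$constraints)
  network <- max(vapply(c(assembly$skirt[1L], assembly$leaflets[1L]),
                        function(s) {
                          if (is.null(attr(s, "u_curves"))) return(NA_real_)
                          network_interpolation_residual(s)
                        }, numeric(1L)), na.rm = TRUE)
  dims <- bounding_dims(assembly)
  area <- if (!is.null(assembly$leaflet_curves)) {
    geometric_orifice_area(assembly)
  } else NA_real_
  checks <- c(radial = radial <= tol[["radial"]],
              mirror = is.na(mirror) || mirror <= tol[["mirror"]],
              collinearity = collin <= tol[["collinearity"]],
              network = is.na(network) || network <= tol[["network"]])
  structure(list(
    radial_symmetry = radial, mirror_symmetry = mirror,
    collinearity = collin, network_residual = network,
    height = dims[["height"]], max_diameter = dims[["max_diameter"]],
    orifice_area = area,
    elements = element_report(assembly),
    tolerances = tol, checks = checks, pass = all(checks)),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  radial symmetry   %.3g mm\n", x$radial_symmetry))
  cat(sprintf("  mirror symmetry   %.3g mm\n", x$mirror_symmetry))
  cat(sprintf("  collinearity      %.3g mm\n", x$collinearity))
  cat(sprintf("  network residual  %.3g mm\n", x$network_residual))
  cat(sprintf("  height            %.2f mm\n", x$height))
  cat(sprintf("  max diameter      %.2f mm\n", x$max_diameter))
  cat(sprintf("  orifice area      %.1f mm^2\n", x$orifice_area))
  cat(sprintf("  pass              %s\n", x$pass))
  invisible(x)
}
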