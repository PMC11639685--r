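# Stent wireframe: baseline + support control points, the single cubic stent
# curve, its mirror, the rotational pattern, and the crossing-constraint map.
#
# Support-point rules: interior connection points get two supports offset
# purely axially (same r, phi) by interior_fraction times the z-gap to the
# adjacent cross-section -- this guarantees the three collinear control
# points at every wire crossing AND exact support overlap between the two
# crossing wires after mirror + rotation. End (apex) points get one support
# on the chord to their single neighbor, whose axial offset is end_fraction
# times the z-gap.

#' Baseline stent points in Cartesian coordinates
#'
#' @param profile The `profile` element of a [valve_config].
#' @return n x 3 matrix (mm), bottom to top.
#' @export
baseline_points <- function(profile) {
  pts <- profile$points
  unname(cyl_to_cart(pts$r, pts$phi, pts$z))
}

#' Support points for the stent curve
#'
#' @param profile Profile element of a config.
#' @param spec List with `end_fraction` (default 0.25) and
#'   `interior_fraction` (default 0.125).
#' @return List of support points, each with `anchor_index`, `side`
#'   (`"above"`/`"below"`) and `position` (mm).
#' @export
support_points <- function(profile,
                           spec = list(end_fraction = 0.25,
                                       interior_fraction = 0.125)) {
  P <- baseline_points(profile)
  z <- profile$points$z
  n <- nrow(P)
  if (n < 2L) stop("profile needs at least 2 baseline points", call. = FALSE)
  if (any(diff(z) <= 1e-12)) {
    stop("degenerate profile: zero vertical gap between cross-sections",
         call. = FALSE)
  }
  fe <- spec$end_fraction
  fi <- spec$interior_fraction
  out <- list()
  add <- function(i, side, pos) {
    out[[length(out) + 1L]] <<- list(anchor_index = i, side = side,
                                     position = as.numeric(pos))
  }
  add(1L, "above", P[1L, ] + fe * (P[2L, ] - P[1L, ]))
  if (n > 2L) {
    for (i in 2:(n - 1L)) {
      add(i, "below", P[i, ] - c(0, 0, fi * (z[i] - z[i - 1L])))
      add(i, "above", P[i, ] + c(0, 0, fi * (z[i + 1L] - z[i])))
    }
  }
  add(n, "below", P[n, ] + fe * (P[n - 1L, ] - P[n, ]))
  out
}

#' Build the single cubic stent curve
#'
#' Control polygon ordered bottom to top as P1, S1+, S2-, P2, S2+, ...,
#' Sn-, Pn with an open uniform cubic knot vector. For the built-in valves
#' this yields 31 control points / 28 spans (THV-A) and 22 / 19 (THV-B).
#'
#' @inheritParams support_points
#' @return A cubic `nurbs_curve`.
#' @export
build_stent_curve <- function(profile,
                              spec = list(end_fraction = 0.25,
                                          interior_fraction = 0.125)) {
  P <- baseline_points(profile)
  sup <- support_points(profile, spec)
  n <- nrow(P)
  get_sup <- function(i, side) {
    for (s in sup) if (s$anchor_index == i && s$side == side) return(s$position)
    stop("internal: missing support", call. = FALSE)
  }
  poly <- P[1L, , drop = FALSE]
  poly <- rbind(poly, get_sup(1L, "above"))
  if (n > 2L) {
    for (i in 2:(n - 1L)) {
      poly <- rbind(poly, get_sup(i, "below"), P[i, ], get_sup(i, "above"))
    }
  }
  poly <- rbind(poly, get_sup(n, "below"), P[n, ])
  nurbs_curve(poly)
}

#' Mirror the stent curve across the phi = 0 plane
#'
#' @param curve The stent `nurbs_curve`.
#' @return Mirrored curve (shares both end baseline points with the input).
#' @export
mirror_curve <- function(curve) reflect(curve, 0)

#' Rotational pattern of the stent curve pair
#'
#' Rotates the (curve, mirror) pair about z in increments of twice the
#' maximum profile azimuth until the circumference is covered exactly once.
#'
#' @param pair List of two `nurbs_curve`s.
#' @param phi_max Maximum profile azimuth in degrees.
#' @return List of `2 * 360 / (2 phi_max)` curves.
#' @export
pattern_curves <- function(pair, phi_max) {
  incr <- 2 * phi_max
  k <- 360 / incr
  if (abs(k - round(k)) > 1e-9) {
    stop("tiling error: 360 is not divisible by 2 * phi_max = ", incr,
         call. = FALSE)
  }
  k <- as.integer(round(k))
  out <- vector("list", 2L * k)
  for (m in seq_len(k)) {
    ang <- (m - 1L) * incr
    out[[2L * m - 1L]] <- rotate_z(pair[[1L]], ang)
    out[[2L * m]] <- rotate_z(pair[[2L]], ang)
  }
  out
}

#' Crossing-constraint map of a patterned stent
#'
#' Groups control points that coincide in the undeformed configuration
#' (these are treated as a single point by downstream solvers so moments
#' transfer through the connection). Interior connections group two curves
#' times three collinear control points; apexes group the shared baseline
#' point only.
#'
#' @param curves List of patterned stent curves.
#' @param tol Coincidence tolerance in mm (default 1e-6); grouping keys are
#'   rounded at 1e-7 mm.
#' @param profile,phi_max Optional; when given, every interior ring is
#'   checked for its expected crossings and a constraint error names any
#'   missing location.
#' @return Object of class `constraint_map`: list of groups with `location`,
#'   `members` (curve, index pairs), `n_pairs`, and `collinearity` residual.
#' @export
crossing_constraints <- function(curves, tol = 1e-6, profile = NULL,
                                 phi_max = NULL) {
  key_round <- 1e-7
  tab <- new.env(parent = emptyenv())
  for (ci in seq_along(curves)) {
    P <- curves[[ci]]$control
    for (pi in seq_len(nrow(P))) {
      key <- paste(round(P[pi, ] / key_round) * key_round, collapse = "|")
      rec <- if (is.null(tab[[key]])) list() else tab[[key]]
      rec[[length(rec) + 1L]] <- c(curve = ci, index = pi, P[pi, ])
      tab[[key]] <- rec
    }
  }
  # coincident-location clusters (each is one control-point pair or more)
  clusters <- list()
  for (key in ls(tab)) {
    rec <- tab[[key]]
    if (length(rec) < 2L) next
    pts <- t(vapply(rec, function(r) r[3:5], numeric(3L)))
    spread <- max(sqrt(rowSums(sweep(pts, 2L, colMeans(pts))^2)))
    if (spread > tol) next
    clusters[[length(clusters) + 1L]] <- list(
      location = colMeans(pts),
      members = t(vapply(rec, function(r) r[1:2], numeric(2L))))
  }
  # merge clusters belonging to one connection: same curve set, control-point
  # indices adjacent on every shared curve (the S-, P, S+ triple)
  nc <- length(clusters)
  parent <- seq_len(nc)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  curve_set <- lapply(clusters, function(cl) sort(unique(cl$members[, 1L])))
  idx_of <- function(cl, ci) cl$members[cl$members[, 1L] == ci, 2L][1L]
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (j <= i) next
      if (!identical(curve_set[[i]], curve_set[[j]])) next
      adj <- all(vapply(curve_set[[i]], function(ci) {
        abs(idx_of(clusters[[i]], ci) - idx_of(clusters[[j]], ci)) == 1
      }, logical(1L)))
      if (adj) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(nc), find, integer(1L))
  groups <- list()
  for (r in unique(roots)) {
    cls <- clusters[roots == r]
    members <- do.call(rbind, lapply(cls, function(cl) cl$members))
    ord <- order(vapply(cls, function(cl) cl$location[3L], numeric(1L)))
    cls <- cls[ord]
    mid <- cls[[ceiling(length(cls) / 2)]]$location   # baseline point
    colres <- 0
    if (length(cls) == 3L) {
      a <- cls[[1L]]$location; b <- cls[[3L]]$location; c0 <- cls[[2L]]$location
      ab <- b - a
      h <- c0 - a - sum((c0 - a) * ab) / sum(ab * ab) * ab
      colres <- sqrt(sum(h * h))
    }
    groups[[length(groups) + 1L]] <- list(
      location = mid,
      members = members,
      n_pairs = length(cls),
      n_curves = length(unique(members[, 1L])),
      collinearity = colres)
  }
  if (!is.null(profile) && !is.null(phi_max)) {
    npts <- nrow(profile$points)
    stations <- as.integer(round(360 / (2 * phi_max)))
    for (i in 2:(npts - 1L)) {
      row <- profile$points[i, ]
      for (m in seq_len(stations) - 1L) {
        loc <- drop(cyl_to_cart(row$r, row$phi + m * 2 * phi_max, row$z))
        found <- any(vapply(groups, function(g) {
          sqrt(sum((g$location - loc)^2)) < 10 * tol && g$n_curves == 2L
        }, logical(1L)))
        if (!found) {
          stop(sprintf(
            "constraint error: expected crossing missing at (%.3f, %.3f, %.3f)",
            loc[1L], loc[2L], loc[3L]), call. = FALSE)
        }
      }
    }
  }
  structure(groups, class = "constraint_map")
}

#' @export
print.constraint_map <- function(x, ...) {
  np <- vapply(x, function(g) g$n_pairs, numeric(1L))
  cat(sprintf("<constraint_map> %d groups (%d interior with 3 pairs, %d apex)\n",
              length(x), sum(np == 3), sum(np == 1)))
  invisible(x)
}
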