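# Soft goods: skirt (Gordon surface over rotated vertical profiles and
# zigzag/ring horizontal edges), commissural attachments (loft of a central
# curve and its rotated/reflected copies), and leaflets (Gordon surface over
# vertical edges, free edge, attachment edge, central interior curve and
# interior horizontal curves).
#
# The one-third of the geometry between phi = 0 and phi = 120 degrees is
# built here and is mirror-symmetric across the phi = 60 plane; the full
# valve is assembled by rotation in assemble_valve().

unit60 <- function(radial, vertical) {
  a <- deg2rad(60)
  c(radial * cos(a), radial * sin(a), vertical)
}

#' Skirt vertical curve pair
#'
#' Interpolates the resolved recipe points (baseline, inverted-phi and
#' support stent points rotated into the phi = 0 plane) into the first
#' vertical curve; the second of the pair is its rotation by `phi_max`.
#'
#' @param recipe Recipe list (see the fixture YAML files).
#' @param profile Profile element of a [valve_config].
#' @param support_cache Optional [support_points()] result.
#' @return List of two cubic `nurbs_curve`s.
#' @export
skirt_vertical_curves <- function(recipe, profile, support_cache = NULL) {
  pts <- resolve_recipe(recipe, profile, support_cache)
  v0 <- interp_cubic(pts)
  list(v0, rotate_z(v0, profile$phi_max))
}

#' Rotate the vertical pair over one-third of the valve
#'
#' Stations at every multiple of `phi_max` covering \[0, `span`\] degrees.
#'
#' @param pair List of two curves from [skirt_vertical_curves()].
#' @param phi_max Azimuthal increment in degrees.
#' @param span Azimuthal extent in degrees (default 120).
#' @return List of `span / phi_max + 1` curves.
#' @export
skirt_rotate_set <- function(pair, phi_max, span = 120) {
  k <- span / phi_max
  if (abs(k - round(k)) > 1e-9) {
    stop("span must be a multiple of phi_max", call. = FALSE)
  }
  k <- as.integer(round(k))
  lapply(0:k, function(m) {
    base <- pair[[(m %% 2L) + 1L]]
    rotate_z(base, (m - m %% 2L) * phi_max)
  })
}

#' Skirt horizontal (top and bottom) edge curves
#'
#' @param skirt_cfg The `skirt` element of a config (fields `top`, `bottom`,
#'   each a recipe; optional `top_tangents` / `bottom_tangents` as lists of
#'   two end-derivative vectors).
#' @inheritParams skirt_vertical_curves
#' @return List with elements `top` and `bottom` (cubic `nurbs_curve`s).
#' @export
skirt_horizontal_curves <- function(skirt_cfg, profile, support_cache = NULL) {
  mk <- function(recipe, tangents) {
    pts <- resolve_recipe(recipe, profile, support_cache)
    interp_cubic(pts, end_tangents = tangents)
  }
  list(top = mk(skirt_cfg$top, skirt_cfg$top_tangents),
       bottom = mk(skirt_cfg$bottom, skirt_cfg$bottom_tangents))
}

# Trim a vertical between the bottom and top horizontal curves.
trim_vertical <- function(vert, bottom, top, tol) {
  hb <- intersect_curves(bottom, vert, tol = tol)
  if (hb$v > 1e-9) vert <- split_curve(vert, hb$v)[[2L]]
  ht <- intersect_curves(top, vert, tol = tol)
  if (ht$v < 1 - 1e-9) vert <- split_curve(vert, ht$v)[[1L]]
  vert
}

#' Build one-third of the skirt as a Gordon surface
#'
#' Vertical profile curves are rotated to every station, trimmed between
#' the bottom and top horizontal edges, and combined with them into a
#' bidirectional network.
#'
#' @param cfg A `valve_config`.
#' @param network_tol Network tolerance in mm.
#' @return List with `surface` (the Gordon `nurbs_surface`), the trimmed
#'   `verticals`, and the `top`/`bottom` edge curves.
#' @export
build_skirt <- function(cfg, network_tol = 1e-6) {
  prof <- cfg$profile
  sup <- support_points(prof, cfg$support)
  pair <- skirt_vertical_curves(cfg$skirt$vertical, prof, sup)
  verts <- skirt_rotate_set(pair, prof$phi_max)
  hor <- skirt_horizontal_curves(cfg$skirt, prof, sup)
  trimmed <- lapply(verts, trim_vertical, bottom = hor$bottom, top = hor$top,
                    tol = network_tol)
  net <- curve_network(list(hor$bottom, hor$top), trimmed, tol = network_tol)
  G <- gordon_surface(net)
  list(surface = G, verticals = trimmed, top = hor$top, bottom = hor$bottom)
}

# Section of the baseline stent curve sharing its endpoints with `central`.
stent_segment_for <- function(cfg, central) {
  sc <- build_stent_curve(cfg$profile, cfg$support)
  ends <- rbind(central$control[1L, ],
                central$control[nrow(central$control), ])
  pr <- project_point_to_curve(sc, ends)
  u1 <- min(pr$u); u2 <- max(pr$u)
  seg <- split_curve(sc, u1)[[2L]]
  split_curve(seg, (u2 - u1) / (1 - u1))[[1L]]
}

#' Build a commissural attachment
#'
#' The central curve at phi = 0 is interpolated from its recipe; the two
#' edges are the configured source curve rotated by `phi_max / 6` about z
#' and reflected across phi = 0; the surface is the loft of
#' (edge-, central, edge+).
#'
#' @param cfg A `valve_config`.
#' @return Object of class `commissure_set` with `central_curve`,
#'   `edge_plus`, `edge_minus`, `surface`, `rotation_deg`.
#' @export
commissure_build <- function(cfg) {
  prof <- cfg$profile
  sup <- support_points(prof, cfg$support)
  pts <- resolve_recipe(cfg$commissure$central, prof, sup)
  central <- interp_cubic(pts)
  src <- cfg$commissure$edge_source
  base <- switch(src,
    central_curve = central,
    stent_segment = stent_segment_for(cfg, central),
    stop("config error: unknown commissure edge source '", src, "'",
         call. = FALSE))
  ang <- prof$phi_max / 6
  edge_plus <- rotate_z(base, ang)
  edge_minus <- reflect(edge_plus, 0)
  surface <- loft(list(edge_minus, central, edge_plus), params = c(0, 0.5, 1))
  structure(list(central_curve = central, edge_plus = edge_plus,
                 edge_minus = edge_minus, surface = surface,
                 rotation_deg = ang), class = "commissure_set")
}

#' @export
print.commissure_set <- function(x, ...) {
  cat(sprintf("<commissure_set> edge rotation %g deg, central z in [%g, %g] mm\n",
              x$rotation_deg, x$central_curve$control[1L, 3L],
              x$central_curve$control[nrow(x$central_curve$control), 3L]))
  invisible(x)
}

#' Upper vertical leaflet edge
#'
#' Extracts the commissure central curve (optionally a sub-span) and
#' translates it by `t` mm along the unit normal of the phi = 0 plane
#' (+y, toward the leaflet interior).
#'
#' @param commissure A `commissure_set`.
#' @param t Translation distance in mm (>= 0).
#' @param span Optional parameter span `c(f0, f1)` of the central curve to
#'   extract (default the whole curve).
#' @return A cubic `nurbs_curve` running bottom to top.
#' @export
leaflet_upper_edge <- function(commissure, t, span = c(0, 1)) {
  if (t < 0) stop("translation must be non-negative", call. = FALSE)
  crv <- commissure$central_curve
  span <- as.numeric(span)
  if (span[1L] < 0 || span[2L] > 1 || span[1L] >= span[2L]) {
    stop("split fractions must satisfy 0 <= f0 < f1 <= 1", call. = FALSE)
  }
  if (span[1L] > 1e-12) crv <- split_curve(crv, span[1L])[[2L]]
  if (span[2L] < 1 - 1e-12) {
    crv <- split_curve(crv, (span[2L] - span[1L]) / (1 - span[1L]))[[1L]]
  }
  translate(crv, c(0, t, 0))
}

#' Composite vertical leaflet edges
#'
#' Joins the lower edge (interpolated through the resolved recipe points,
#' listed junction-first) to the upper edge at their common endpoint, then
#' reflects the composite across phi = 60 to obtain the right edge.
#'
#' @param upper Upper edge curve from [leaflet_upper_edge()].
#' @param lower_pts Matrix of resolved lower-edge points, first row equal to
#'   the upper edge's bottom endpoint, subsequent rows descending.
#' @return List with `left` and `right` composite curves (bottom to top).
#' @export
leaflet_vertical_edges <- function(upper, lower_pts) {
  lower_pts <- as.matrix(lower_pts)
  if (nrow(lower_pts) < 2L) {
    stop("join error: lower edge recipe needs at least 2 points", call. = FALSE)
  }
  lower <- interp_cubic(lower_pts[nrow(lower_pts):1L, , drop = FALSE])
  left <- join_curves(lower, upper)
  list(left = left, right = reflect(left, 60))
}

#' Leaflet free edge
#'
#' Linear points are evaluated on the line joining the top corner of the
#' vertical edge to a near-axis point (at the height of the bottom of the
#' upper edge section for `center_low`, of its top for `center_flat`),
#' mirrored across phi = 60, and interpolated together with the central
#' point (an on-axis point at the commissure-top height offset radially
#' along the phi = 60 plane and vertically).
#'
#' @param style List with `mode` (`"center_low"`/`"center_flat"`),
#'   `side_fractions`, `near_axis_vertical_offset`, `center_radial_offset`,
#'   `center_vertical_offset`.
#' @param context List with `corner` (top of the left vertical edge),
#'   `z_low`, `z_top`.
#' @return A cubic `nurbs_curve` (left corner to right corner); attributes
#'   `side_points` (left side) and `center`.
#' @export
free_edge <- function(style, context) {
  fr <- as.numeric(style$side_fractions)
  if (!length(fr)) stop("config error: side_fractions must not be empty",
                        call. = FALSE)
  if (any(fr <= 0 | fr >= 1) || any(diff(fr) <= 0)) {
    stop("config error: side_fractions must be strictly increasing in (0,1)",
         call. = FALSE)
  }
  mode <- match.arg(style$mode, c("center_low", "center_flat"))
  z_na <- (if (mode == "center_low") context$z_low else context$z_top) +
    style$near_axis_vertical_offset
  corner <- as.numeric(context$corner)
  na_pt <- c(0, 0, z_na)
  side <- t(vapply(fr, function(f) corner + f * (na_pt - corner), numeric(3L)))
  center <- c(0, 0, context$z_top) +
    unit60(style$center_radial_offset, style$center_vertical_offset)
  nside <- nrow(side)
  pts <- rbind(corner, side, center,
               reflect(side[nside:1L, , drop = FALSE], 60),
               reflect(matrix(corner, 1L), 60))
  crv <- interp_cubic(pts)
  attr(crv, "side_points") <- side
  attr(crv, "center") <- center
  crv
}

#' Lower leaflet attachment edge
#'
#' The recipe lists the left half ending with the central point on the
#' phi = 60 plane; the right half is generated by reflection and the full
#' point set interpolated.
#'
#' @param left_pts Resolved left-half points (center last).
#' @return A cubic `nurbs_curve` left to right; attribute `center`.
#' @export
attachment_edge <- function(left_pts) {
  left_pts <- as.matrix(left_pts)
  n <- nrow(left_pts)
  if (n < 2L) stop("attachment recipe needs at least 2 points", call. = FALSE)
  center <- left_pts[n, ]
  d60 <- abs(cart_to_cyl(center)[2L] - 60)
  if (d60 > 1e-6) {
    warning(sprintf(
      "attachment center is %.2g deg off the phi = 60 symmetry plane", d60))
  }
  pts <- rbind(left_pts,
               reflect(left_pts[(n - 1L):1L, , drop = FALSE], 60))
  crv <- interp_cubic(pts)
  attr(crv, "center") <- center
  crv
}

#' Central interior (belly) curve of a leaflet
#'
#' Three-point interpolation in the phi = 60 plane: attachment-edge center,
#' belly point, free-edge center (bottom to top).
#'
#' @param attach_center,belly,free_center Length-3 points on the phi = 60
#'   plane.
#' @return A cubic `nurbs_curve`.
#' @export
central_interior_curve <- function(attach_center, belly, free_center) {
  interp_cubic(rbind(attach_center, belly, free_center))
}

#' Interior horizontal leaflet curve
#'
#' Endpoints offset down the vertical edges (arc length `d` from the top),
#' central point offset down the central interior curve by the same arc
#' length, and the free-edge side points offset by `-d` in z; all mirrored
#' across phi = 60 and interpolated.
#'
#' @param left Left composite edge (bottom to top).
#' @param central Central interior curve (bottom to top).
#' @param fe Free edge curve carrying its `side_points` attribute.
#' @param d Offset arc length in mm (> 0).
#' @return A cubic `nurbs_curve` (left to right).
#' @export
interior_horizontal_curve <- function(left, central, fe, d) {
  if (d <= 0) stop("offset length must be positive", call. = FALSE)
  pt_at_from_end <- function(crv, dd) {
    s <- curve_length(crv) - dd
    drop(eval_curve(crv, param_at_length(crv, s)))
  }
  pt_l <- pt_at_from_end(left, d)
  pt_c <- pt_at_from_end(central, d)
  side <- attr(fe, "side_points")
  side_off <- sweep(side, 2L, c(0, 0, d), "-")
  nside <- nrow(side_off)
  pts <- rbind(pt_l, side_off, pt_c,
               reflect(side_off[nside:1L, , drop = FALSE], 60),
               reflect(matrix(pt_l, 1L), 60))
  interp_cubic(pts)
}

# Planar arc through the belly point and the two edge points at its height.
leaflet_arc <- function(left, belly) {
  zb <- belly[3L]
  f <- function(u) drop(eval_curve(left, u))[3L] - zb
  lo <- f(0); hi <- f(1)
  if (lo * hi > 0) {
    stop("arc error: belly height is outside the vertical edge range",
         call. = FALSE)
  }
  u <- stats::uniroot(f, c(0, 1), tol = 1e-12)$root
  pt_l <- drop(eval_curve(left, u))
  pt_r <- drop(reflect(pt_l, 60))
  circle_arc_3pt(pt_l, belly, pt_r)$curve
}

#' Build one leaflet as a Gordon surface
#'
#' Runs the full construction: commissure, translated upper edge, composite
#' vertical edges, free edge, attachment edge, central interior curve,
#' interior horizontal curve (and the optional planar arc), then the Gordon
#' surface over the network.
#'
#' @param cfg A `valve_config`.
#' @param network_tol Network tolerance in mm.
#' @return List with `surface`, the named `curves` of the network, and the
#'   `commissure` used.
#' @export
build_leaflet <- function(cfg, network_tol = 1e-6) {
  comm <- commissure_build(cfg)
  lf <- cfg$leaflet
  prof <- cfg$profile
  sup <- support_points(prof, cfg$support)
  upper <- leaflet_upper_edge(comm, lf$upper_translation,
                              if (is.null(lf$upper_span)) c(0, 1)
                              else as.numeric(lf$upper_span))
  ctx <- list(upper_edge_bottom = upper$control[1L, ],
              upper_edge_top = upper$control[nrow(upper$control), ])
  lower_pts <- resolve_recipe(lf$lower_edge, prof, sup, ctx)
  edges <- leaflet_vertical_edges(upper, lower_pts)
  fctx <- list(corner = ctx$upper_edge_top,
               z_low = ctx$upper_edge_bottom[3L],
               z_top = ctx$upper_edge_top[3L])
  fe <- free_edge(lf$free_edge, fctx)
  att_pts <- resolve_recipe(lf$attachment, prof, sup, ctx)
  att <- attachment_edge(att_pts)
  belly <- c(0, 0, fctx$z_top) +
    unit60(lf$belly$radial_offset, lf$belly$vertical_offset)
  cic <- central_interior_curve(attr(att, "center"), belly, attr(fe, "center"))
  d <- lf$interior_factor * curve_length(upper)
  ih <- interior_horizontal_curve(edges$left, cic, fe, d)
  arc <- if (isTRUE(lf$use_arc)) leaflet_arc(edges$left, belly) else NULL
  u_curves <- c(list(att), if (!is.null(arc)) list(arc), list(ih, fe))
  net <- curve_network(u_curves, list(edges$left, cic, edges$right),
                       tol = network_tol)
  G <- gordon_surface(net)
  curves <- list(left = edges$left, right = edges$right, free_edge = fe,
                 attachment = att, central_interior = cic,
                 interior_horizontal = ih)
  if (!is.null(arc)) curves$arc <- arc
  list(surface = G, curves = curves, commissure = comm)
}
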