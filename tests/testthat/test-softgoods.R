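# Soft goods: skirt curve network and Gordon surface, commissural
# attachments, and the leaflet construction steps.

test_that("skirt vertical recipes interpolate their resolved points", {
  b <- fixture_config("b")
  sup <- support_points(b$profile, b$support)
  pair <- skirt_vertical_curves(b$skirt$vertical, b$profile, sup)
  # the THV-B vertical resolves 8 points, all rotated into phi = 0
  pts <- thvforge:::resolve_recipe(b$skirt$vertical, b$profile, sup)
  expect_equal(nrow(pts), 8)
  expect_lt(max(abs(pts[, 2])), 1e-12)
  tpar <- thvforge:::chord_params(pts)
  expect_lt(max(abs(eval_curve(pair[[1]], tpar) - pts)), 1e-10)
  # the partner is the rotation by phi_max
  expect_lt(max(abs(pair[[2]]$control - rotate_z(pair[[1]], 15)$control)),
            1e-14)
  expect_error(thvforge:::resolve_recipe(list(), b$profile), "empty recipe")
})

test_that("rotation stations cover one-third of the valve", {
  a <- fixture_config("a"); b <- fixture_config("b")
  pa <- skirt_vertical_curves(a$skirt$vertical, a$profile,
                              support_points(a$profile, a$support))
  pb <- skirt_vertical_curves(b$skirt$vertical, b$profile,
                              support_points(b$profile, b$support))
  sa <- skirt_rotate_set(pa, 12)
  sb <- skirt_rotate_set(pb, 15)
  expect_length(sa, 11)                        # 120 / 12 + 1
  expect_length(sb, 9)                         # 120 / 15 + 1
  expect_equal(curve_length(sa[[5]]), curve_length(sa[[1]]),
               tolerance = 1e-9)
})

test_that("skirt horizontal recipes resolve the documented example point", {
  a <- fixture_config("a")
  sup <- support_points(a$profile, a$support)
  pts <- thvforge:::resolve_recipe(a$skirt$bottom, a$profile, sup)
  # R_24(P1) appears at station 3: 13.15 (cos 24, sin 24), z = 0
  expect_equal(pts[3, ], c(12.013122768, 5.348586856, 0), tolerance = 1e-8)
  hor <- skirt_horizontal_curves(a$skirt, a$profile, sup)
  expect_lt(max(abs(eval_curve(hor$bottom,
                               thvforge:::chord_params(pts)) - pts)), 1e-10)
})

test_that("tangent-constrained horizontal fits honor the end derivative", {
  a <- fixture_config("a")
  sup <- support_points(a$profile, a$support)
  cfg <- a$skirt
  D <- list(c(0, 10, 0), c(-10, 0, 0))
  cfg$bottom_tangents <- D
  hor <- skirt_horizontal_curves(cfg, a$profile, sup)
  d <- curve_derivs(hor$bottom, c(0, 1), 1L)
  expect_equal(d[[2]][1, ], D[[1]], tolerance = 1e-8)
  expect_equal(d[[2]][2, ], D[[2]], tolerance = 1e-8)
})

test_that("vertical splitting between horizontals reproduces the kept span", {
  # synthetic case with an interior bottom intersection
  vert <- straight_curve(c(10, 0, -3), c(10, 0, 10), n = 5)
  bottom <- straight_curve(c(9, -1, 0), c(11, 1, 0))
  top <- straight_curve(c(9, -1, 10), c(11, 1, 10))
  tr <- thvforge:::trim_vertical(vert, bottom, top, tol = 1e-6)
  expect_equal(drop(eval_curve(tr, 0)), c(10, 0, 0), tolerance = 1e-7)
  expect_equal(drop(eval_curve(tr, 1)), c(10, 0, 10), tolerance = 1e-9)
})

test_that("skirt Gordon surfaces interpolate their networks", {
  for (which in c("a", "b")) {
    sk <- fixture_assembly(which)$components$skirt_third
    expect_lt(thvforge:::network_interpolation_residual(sk$surface), 1e-8)
    expect_lt(check_mirror_symmetry(sk$surface, 60), 1e-9)
  }
  # THV-B skirt z-extent stays within the profile table
  skb <- fixture_assembly("b")$components$skirt_third
  ctrl <- matrix(skb$surface$control, ncol = 3)
  expect_gte(min(ctrl[, 3]), -1e-9)
  expect_lte(max(ctrl[, 3]), 20.05 + 1e-9)
})

test_that("analytic cylinder network reproduces the cylinder", {
  R <- 13
  verts <- lapply(seq(0, 120, by = 30), function(a) {
    ar <- a * pi / 180
    straight_curve(c(R * cos(ar), R * sin(ar), 0),
                   c(R * cos(ar), R * sin(ar), 15))
  })
  horiz <- lapply(c(0, 15), function(z) {
    p <- function(a) c(R * cos(a * pi / 180), R * sin(a * pi / 180), z)
    circle_arc_3pt(p(0), p(60), p(120))$curve
  })
  G <- gordon_surface(curve_network(horiz, verts))
  pts <- eval_surface(G, runif(150), runif(150))
  expect_lt(max(abs(sqrt(pts[, 1]^2 + pts[, 2]^2) - R)), 1e-6)
})

test_that("commissure edges sit at phi_max / 6 and the loft hits the center", {
  ca <- fixture_leaflet("a")$commissure
  cb <- fixture_leaflet("b")$commissure
  expect_equal(ca$rotation_deg, 2)             # 12 / 6
  expect_equal(cb$rotation_deg, 2.5)           # 15 / 6
  # edges are mirror images across phi = 0
  expect_lt(max(abs(reflect(ca$edge_plus, 0)$control -
                    ca$edge_minus$control)), 1e-12)
  # surface mid-v iso-curve equals the central curve
  uu <- seq(0, 1, length.out = 40)
  d <- eval_surface(ca$surface, uu, 0.5) - eval_curve(ca$central_curve, uu)
  expect_lt(max(abs(d)), 1e-8)
})

test_that("upper leaflet edge translation is the phi = 0 plane normal", {
  comm <- fixture_leaflet("a")$commissure
  e0 <- leaflet_upper_edge(comm, 0)
  expect_lt(max(abs(e0$control - comm$central_curve$control)), 1e-14)
  e1 <- leaflet_upper_edge(comm, 0.12)
  expect_equal(e1$control[, 2] - comm$central_curve$control[, 2],
               rep(0.12, nrow(e1$control)))
  expect_equal(e1$control[, c(1, 3)], comm$central_curve$control[, c(1, 3)])
  expect_equal(curve_length(e1), curve_length(comm$central_curve),
               tolerance = 1e-9)
  expect_error(leaflet_upper_edge(comm, 0.1, span = c(0.5, 0.2)),
               "split fractions")
  # partial extraction reproduces the sub-span geometry
  e_half <- leaflet_upper_edge(comm, 0, span = c(0, 0.5))
  d <- eval_curve(e_half, seq(0, 1, length.out = 50)) -
    eval_curve(comm$central_curve, seq(0, 0.5, length.out = 50))
  expect_lt(max(abs(d)), 1e-11)
})

test_that("vertical edges join and reflect across phi = 60", {
  lf <- fixture_leaflet("a")
  left <- lf$curves$left
  right <- lf$curves$right
  expect_lt(max(abs(reflect(left, 60)$control - right$control)), 1e-12)
  # azimuths of mirrored control points sum to 120
  cl <- thvforge:::cart_to_cyl(left$control)
  cr <- thvforge:::cart_to_cyl(right$control)
  expect_equal(cl[, "phi"] + cr[, "phi"], rep(120, nrow(cl)),
               tolerance = 1e-10)
  # single-point lower recipe cannot be joined
  comm <- lf$commissure
  up <- leaflet_upper_edge(comm, 0.12)
  expect_error(leaflet_vertical_edges(up, up$control[1, , drop = FALSE]),
               "join error")
  # a gap at the junction is reported with its distance
  bad <- rbind(up$control[1, ] + c(0.5, 0, 0), c(12, 2, 9), c(12.5, 4, 5))
  expect_error(leaflet_vertical_edges(up, bad), "gap")
})

test_that("free edge styles place the center as configured", {
  lfa <- fixture_leaflet("a")
  lfb <- fixture_leaflet("b")
  fa <- lfa$curves$free_edge
  fb <- lfb$curves$free_edge
  # center-low: center strictly below the corners (THV-A)
  corners_a <- eval_curve(fa, c(0, 1))[, 3]
  center_a <- attr(fa, "center")[3]
  expect_true(all(center_a < corners_a - 1))
  # center-flat: corners and center at one height (THV-B)
  pts_b <- eval_curve(fb, c(0, 0.5, 1))[, 3]
  expect_equal(pts_b, rep(20.05, 3), tolerance = 1e-9)
  # mirror symmetry of the whole free edge
  expect_lt(check_mirror_symmetry(fa, 60), 1e-9)
  style <- fixture_config("a")$leaflet$free_edge
  style$side_fractions <- numeric(0)
  expect_error(free_edge(style, list(corner = c(15, 0, 32), z_low = 23.5,
                                     z_top = 32.5)), "side_fractions")
})

test_that("attachment edge is symmetric and meets the vertical edges", {
  for (which in c("a", "b")) {
    lf <- fixture_leaflet(which)
    att <- lf$curves$attachment
    expect_lt(check_mirror_symmetry(att, 60), 1e-9)
    gap_l <- sqrt(sum((att$control[1, ] - lf$curves$left$control[1, ])^2))
    gap_r <- sqrt(sum((att$control[nrow(att$control), ] -
                       lf$curves$right$control[1, ])^2))
    expect_lt(gap_l, 1e-6)
    expect_lt(gap_r, 1e-6)
  }
  expect_error(attachment_edge(matrix(c(1, 2, 3), 1)), "at least 2")
})

test_that("central interior curve lies in the phi = 60 plane", {
  lf <- fixture_leaflet("a")
  cic <- lf$curves$central_interior
  pts <- eval_curve(cic, seq(0, 1, length.out = 60))
  n60 <- c(-sin(pi / 3), cos(pi / 3), 0)
  expect_lt(max(abs(pts %*% n60)), 1e-9)
  # zero belly offsets give the straight chord between the edge centers
  a <- attr(lf$curves$attachment, "center")
  f <- attr(lf$curves$free_edge, "center")
  straight <- central_interior_curve(a, (a + f) / 2, f)
  mid <- drop(eval_curve(straight, 0.5))
  chord <- a + 0.5 * (f - a)
  expect_lt(sqrt(sum((mid - chord)^2)), 1e-9)
})

test_that("interior horizontal offsets are measured by arc length", {
  lf <- fixture_leaflet("a")
  comm <- lf$commissure
  upper_len <- curve_length(leaflet_upper_edge(comm, 0.12))
  ih <- lf$curves$interior_horizontal
  # endpoint sits on the left edge at arc length L from its top
  left <- lf$curves$left
  pr <- thvforge:::project_point_to_curve(left, ih$control[1, ])
  expect_lt(pr$distance, 1e-8)
  s_here <- curve_length(split_curve(left, pr$u)[[1]])
  expect_equal(curve_length(left) - s_here, upper_len, tolerance = 1e-6)
})

test_that("planar arcs recover their circumcircle", {
  th <- c(0.3, 1.1, 2.0)
  pts <- cbind(4 + 2 * cos(th), -1 + 2 * sin(th), 5)
  arc <- circle_arc_3pt(pts[1, ], pts[2, ], pts[3, ])
  expect_equal(arc$center, c(4, -1, 5), tolerance = 1e-9)
  expect_equal(arc$radius, 2, tolerance = 1e-10)
  expect_error(circle_arc_3pt(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
  # the fixture leaflet arc passes through the belly point at its height
  lf <- fixture_leaflet("a")
  belly_z <- 32.5 - 20.5
  arc_z <- eval_curve(lf$curves$arc, seq(0, 1, 0.05))[, 3]
  expect_lt(max(abs(arc_z - belly_z)), 1e-9)
})

test_that("leaflet Gordon surfaces interpolate their networks", {
  for (which in c("a", "b")) {
    lf <- fixture_leaflet(which)
    expect_lt(thvforge:::network_interpolation_residual(lf$surface), 1e-8)
    expect_lt(check_mirror_symmetry(lf$surface, 60), 1e-8)
  }
  # soft goods stay within the stent envelope + 1 mm
  for (which in c("a", "b")) {
    asm <- fixture_assembly(which)
    r_stent <- max(fixture_config(which)$profile$points$r)
    S <- eval_surface(asm$leaflets[[1]],
                      rep(seq(0, 1, length.out = 40), each = 40),
                      rep(seq(0, 1, length.out = 40), times = 40))
    expect_lt(max(sqrt(S[, 1]^2 + S[, 2]^2)), r_stent + 1)
  }
})
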