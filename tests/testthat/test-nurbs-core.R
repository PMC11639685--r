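# NURBS primitives: knot vectors, evaluation, interpolation, refinement,
# rigid transforms, splitting, intersection, lofting and Gordon surfaces.

test_that("open uniform knot vectors are clamped with uniform spans", {
  expect_identical(open_uniform_knots(4, 3), c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(open_uniform_knots(5, 3), c(0, 0, 0, 0, 0.5, 1, 1, 1, 1))
  kv <- open_uniform_knots(31, 3)
  expect_equal(thvforge:::n_spans(kv), 28)
  expect_error(open_uniform_knots(3, 3), "degree \\+ 1")
})

test_that("curve evaluation interpolates clamped endpoints and lines", {
  set.seed(11)
  P <- cbind(sort(runif(6)), rnorm(6), rnorm(6))
  cv <- nurbs_curve(P)
  expect_equal(drop(eval_curve(cv, 0)), P[1, ], tolerance = 1e-14)
  expect_equal(drop(eval_curve(cv, 1)), P[6, ], tolerance = 1e-14)
  expect_error(eval_curve(cv, 1.5), "out of knot range")
  # affine invariance: straight control polygon stays on its line
  ln <- straight_curve(c(0, 0, 0), c(2, 4, 6), n = 7)
  pts <- eval_curve(ln, runif(40))
  dir <- c(2, 4, 6) / sqrt(sum(c(2, 4, 6)^2))
  off <- pts - (pts %*% dir) %*% t(dir)
  expect_lt(max(abs(off)), 1e-13)
})

test_that("rational quarter arc stays on its circle", {
  arc <- quarter_arc(2.5)
  pts <- eval_curve(arc, seq(0, 1, length.out = 200))
  expect_lt(max(abs(sqrt(rowSums(pts^2)) - 2.5)), 1e-12)
  expect_equal(curve_length(arc), 2.5 * pi / 2, tolerance = 1e-8)
})

test_that("global interpolation reproduces its data and known geometry", {
  # collinear points give a straight curve of chord length
  P <- cbind(seq(0, 3, length.out = 5), 0, 0)
  cv <- interpolate_curve(P)
  expect_equal(curve_length(cv), 3, tolerance = 1e-9)
  expect_lt(max(abs(eval_curve(cv, seq(0, 1, 0.05))[, 2:3])), 1e-12)
  # round trip: interpolation is a projector -- resampling an interpolated
  # cubic at its own parameters reproduces the same geometry
  set.seed(3)
  Q <- cbind(sort(runif(9)), rnorm(9), rnorm(9))
  base <- interpolate_curve(Q)
  tpar <- thvforge:::chord_params(Q)
  fit <- interpolate_curve(eval_curve(base, tpar))
  uu <- seq(0, 1, length.out = 300)
  expect_lt(max(abs(eval_curve(fit, uu) - eval_curve(base, uu))), 1e-9)
  # residual at every input point
  expect_lt(max(abs(eval_curve(base, tpar) - Q)), 1e-10)
  expect_error(interpolate_curve(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "coincident")
})

test_that("two points plus tangents give the Hermite cubic", {
  D0 <- c(3, 0, 0); D1 <- c(0, 3, 0)
  cv <- interpolate_curve(rbind(c(0, 0, 0), c(1, 1, 0)),
                          end_tangents = list(D0, D1))
  d <- curve_derivs(cv, c(0, 1), 1L)
  expect_equal(d[[2]][1, ], D0, tolerance = 1e-10)
  expect_equal(d[[2]][2, ], D1, tolerance = 1e-10)
  expect_equal(drop(eval_curve(cv, 1)), c(1, 1, 0), tolerance = 1e-12)
})

test_that("h-refinement preserves geometry and multiplies span counts", {
  set.seed(7)
  cv <- interpolate_curve(cbind(sort(runif(8)), rnorm(8), rnorm(8)))
  expect_identical(h_refine_uniform(cv, 0), cv)
  r2 <- h_refine_uniform(cv, 2)
  expect_equal(element_count(r2), 4 * element_count(cv))
  uu <- runif(200)
  expect_lt(max(abs(eval_curve(r2, uu) - eval_curve(cv, uu))), 1e-12)
  expect_error(h_refine_uniform(cv, -1), "non-negative")
  # surfaces refine per direction
  srf <- loft(list(straight_curve(c(0, 0, 0), c(1, 0, 0)),
                   straight_curve(c(0, 1, 0), c(1, 1, 0))))
  rs <- h_refine_uniform(srf, 1)
  expect_equal(unname(element_count(rs)[["total"]]),
               4 * unname(element_count(srf)[["total"]]))
})

test_that("rigid transforms are exact group operations", {
  set.seed(5)
  cv <- interpolate_curve(cbind(sort(runif(6)), rnorm(6), rnorm(6)))
  uu <- runif(30)
  # full turn, composition, equivariance
  expect_lt(max(abs(rotate_z(cv, 360)$control - cv$control)), 1e-12)
  expect_equal(drop(rotate_z(c(13.15, 0, 0), 90)), c(0, 13.15, 0),
               tolerance = 1e-12)
  ab <- rotate_z(rotate_z(cv, 17), 25)
  expect_lt(max(abs(ab$control - rotate_z(cv, 42)$control)), 1e-12)
  expect_lt(max(abs(eval_curve(rotate_z(cv, 33), uu) -
                    rotate_z(eval_curve(cv, uu), 33))), 1e-12)
  # reflection: involution, azimuth mirror, fixed points
  expect_lt(max(abs(reflect(reflect(cv, 20), 20)$control - cv$control)),
            1e-12)
  p <- drop(thvforge:::cyl_to_cart(5, 12, 2))
  expect_equal(unname(thvforge:::cart_to_cyl(reflect(p, 0))[1, ]),
               c(5, -12, 2), tolerance = 1e-12)
  on_plane <- drop(thvforge:::cyl_to_cart(3, 45, 1))
  expect_equal(unname(drop(reflect(on_plane, 45))), unname(on_plane),
               tolerance = 1e-13)
  # translation: identity, inverse, length invariance
  expect_equal(translate(cv, c(0, 0, 0))$control, cv$control)
  expect_lt(max(abs(translate(translate(cv, c(1, -2, 3)),
                              -c(1, -2, 3))$control - cv$control)), 1e-14)
  expect_equal(curve_length(translate(cv, c(4, 5, 6))), curve_length(cv),
               tolerance = 1e-10)
  expect_equal(curve_length(rotate_z(cv, 77)), curve_length(cv),
               tolerance = 1e-10)
})

test_that("splitting reproduces the original geometry piecewise", {
  sg <- straight_curve(c(0, 0, 0), c(2, 0, 0))
  halves <- split_curve(sg, 0.5)
  expect_equal(curve_length(halves[[1]]), 1, tolerance = 1e-10)
  expect_equal(curve_length(halves[[2]]), 1, tolerance = 1e-10)
  set.seed(9)
  cv <- interpolate_curve(cbind(sort(runif(7)), rnorm(7), rnorm(7)))
  sp <- split_curve(cv, 0.3)
  g1 <- eval_curve(sp[[1]], seq(0, 1, length.out = 101))
  g2 <- eval_curve(sp[[2]], seq(0, 1, length.out = 101))
  expect_lt(max(abs(g1 - eval_curve(cv, seq(0, 0.3, length.out = 101)))),
            1e-11)
  expect_lt(max(abs(g2 - eval_curve(cv, seq(0.3, 1, length.out = 101)))),
            1e-11)
  # a split quarter arc keeps its circle and sums its sweep
  arc <- quarter_arc(1)
  pa <- split_curve(arc, 0.4)
  expect_equal(curve_length(pa[[1]]) + curve_length(pa[[2]]), pi / 2,
               tolerance = 1e-8)
  expect_error(split_curve(cv, 0), "interior")
  expect_error(split_curve(cv, 1), "interior")
})

test_that("curve intersection finds crossings and signals misses", {
  a <- straight_curve(c(-1, 0, 0), c(1, 0, 0))
  b <- straight_curve(c(0, -1, 0), c(0, 1, 0))
  hit <- intersect_curves(a, b)
  expect_lt(hit$residual, 1e-12)
  expect_lt(max(abs(hit$point)), 1e-12)
  # coplanar arcs with a known crossing
  a1 <- quarter_arc(2)
  a2 <- translate(quarter_arc(2), c(0.5, -0.5, 0))
  h2 <- intersect_curves(a1, a2, tol = 1e-6)
  expect_lt(h2$residual, 1e-8)
  expect_error(
    intersect_curves(straight_curve(c(0, 0, 0), c(1, 0, 0)),
                     straight_curve(c(0, 1, 0), c(1, 1, 0))),
    class = "thvforge_no_intersection")
})

test_that("lofting interpolates every section as an iso-curve", {
  s <- loft(list(straight_curve(c(0, 0, 0), c(1, 0, 0)),
                 straight_curve(c(0, 1, 0), c(1, 1, 0))))
  pts <- eval_surface(s, runif(60), runif(60))
  expect_lt(max(abs(pts[, 3])), 1e-13)
  arcs <- lapply(c(1, 1.5, 2), function(r) quarter_arc(r))
  sl <- loft(arcs)
  vp <- attr(sl, "v_params")
  for (k in seq_along(arcs)) {
    d <- eval_surface(sl, seq(0, 1, 0.02), vp[k]) -
      eval_curve(arcs[[k]], seq(0, 1, 0.02))
    expect_lt(max(abs(d)), 1e-10)
  }
  expect_warning(loft(list(straight_curve(c(0, 0, 0), c(1, 0, 0)),
                           straight_curve(c(0, 0, 0), c(1, 0, 0)))),
                 "degenerate")
  expect_error(loft(list(quarter_arc(1))), "at least 2")
})

test_that("gordon surface recovers a known bicubic patch", {
  ctrl <- array(0, c(4, 4, 3))
  for (i in 1:4) for (j in 1:4) ctrl[i, j, ] <- c(i, j, sin(i) * cos(j))
  patch <- nurbs_surface(ctrl)
  ucv <- lapply(c(0, 0.4, 1), function(v) thvforge:::iso_curve(patch, v, "v"))
  vcv <- lapply(c(0, 0.3, 0.7, 1),
                function(u) thvforge:::iso_curve(patch, u, "u"))
  G <- gordon_surface(curve_network(ucv, vcv))
  expect_lt(thvforge:::network_interpolation_residual(G), 1e-10)
  set.seed(2)
  uu <- runif(80); vv <- runif(80)
  expect_lt(max(abs(eval_surface(G, uu, vv) - eval_surface(patch, uu, vv))),
            1e-10)
})

test_that("gordon surface handles incompatible stations and cylinders", {
  R <- 10
  ang <- c(0, 30, 45, 90) * pi / 180
  verts <- lapply(ang, function(a) {
    straight_curve(c(R * cos(a), R * sin(a), 0), c(R * cos(a), R * sin(a), 20))
  })
  horiz <- lapply(c(0, 7, 20), function(z) {
    circle_arc_3pt(c(R, 0, z), c(R / sqrt(2), R / sqrt(2), z),
                   c(0, R, z))$curve
  })
  G <- gordon_surface(curve_network(horiz, verts))
  p <- eval_surface(G, runif(200), runif(200))
  expect_lt(max(abs(sqrt(p[, 1]^2 + p[, 2]^2) - R)), 1e-6)
  # a missing intersection names the offending pair
  bad <- c(verts[1:3], list(straight_curve(c(30, 30, 0), c(30, 30, 20))))
  expect_error(curve_network(horiz, bad), "missing intersections")
})

test_that("curve length matches closed forms", {
  expect_equal(curve_length(straight_curve(c(0, 0, 0), c(0, 0, 2))), 2,
               tolerance = 1e-12)
  expect_equal(curve_length(quarter_arc(1)), pi / 2, tolerance = 1e-8)
})

test_that("element counts follow knot spans", {
  bez <- nurbs_curve(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(3, 1, 0)))
  expect_equal(element_count(bez), 1)
  expect_equal(element_count(h_refine_uniform(bez, 2)), 4)
})
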