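# Mechanical kernels: section frames, frame propagation, Lee-Sacks energy,
# penalty parameters, contact and friction.

test_that("azimuthal unit vector matches its defining components", {
  expect_equal(phi_hat(0), c(0, 1, 0))
  expect_equal(phi_hat(90), c(-1, 0, 0), tolerance = 1e-15)
  for (a in runif(10, -360, 360)) {
    expect_equal(sqrt(sum(phi_hat(a)^2)), 1, tolerance = 1e-14)
  }
})

test_that("section frames follow v2 = v1 x phi_hat, v3 = v1 x v2", {
  # vertical tangent at phi = 0: v2 = (-1, 0, 0), v3 = (0, -1, 0)
  vert <- straight_curve(c(5, 0, 0), c(5, 0, 10))
  fr <- section_frame(vert, 0.5)
  expect_equal(fr$v1[1, ], c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$v2[1, ], c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$v3[1, ], c(0, -1, 0), tolerance = 1e-12)
  # azimuthal tangent is degenerate
  ring <- quarter_arc(5)
  expect_error(section_frame(ring, 0.3), "degenerate frame")
})

test_that("frames are orthonormal along both fixture stent curves", {
  for (which in c("a", "b")) {
    sc <- build_stent_curve(fixture_config(which)$profile)
    fr <- section_frame(sc, seq(0.001, 0.999, length.out = 400))
    for (pair in list(c("v1", "v2"), c("v1", "v3"), c("v2", "v3"))) {
      dots <- rowSums(fr[[pair[1]]] * fr[[pair[2]]])
      expect_lt(max(abs(dots)), 1e-10)
    }
    for (nm in c("v1", "v2", "v3")) {
      expect_lt(max(abs(sqrt(rowSums(fr[[nm]]^2)) - 1)), 1e-12)
    }
    # right-handed: v1 x v2 = v3
    cr <- cbind(fr$v1[, 2] * fr$v2[, 3] - fr$v1[, 3] * fr$v2[, 2],
                fr$v1[, 3] * fr$v2[, 1] - fr$v1[, 1] * fr$v2[, 3],
                fr$v1[, 1] * fr$v2[, 2] - fr$v1[, 2] * fr$v2[, 1])
    expect_lt(max(abs(cr - fr$v3)), 1e-10)
  }
})

test_that("the mapping operator is the minimal rotation", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0); e3 <- c(0, 0, 1)
  expect_equal(mapping_operator(e1, e1), diag(3))
  R90 <- mapping_operator(e1, e2)
  expect_equal(drop(R90 %*% e1), e2, tolerance = 1e-14)
  expect_equal(drop(R90 %*% e3), e3, tolerance = 1e-14)  # axis fixed
  set.seed(21)
  for (k in 1:25) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    b <- rnorm(3); b <- b / sqrt(sum(b^2))
    L <- mapping_operator(a, b)
    expect_lt(sqrt(sum((drop(L %*% a) - b)^2)), 1e-12)
    expect_lt(max(abs(t(L) %*% L - diag(3))), 1e-12)
  }
  expect_error(mapping_operator(e1, -e1), "antiparallel")
})

test_that("frame propagation parallel-transports without twist", {
  # straight curve: constant frame equal to the seed
  sg <- straight_curve(c(0, 0, 0), c(0, 0, 9))
  ff <- propagate_frames(sg, seq(0, 1, length.out = 20))
  expect_lt(max(abs(sweep(ff$a2, 2, ff$a2[1, ]))), 1e-13)
  expect_lt(max(abs(sweep(ff$a3, 2, ff$a3[1, ]))), 1e-13)
  # planar 90-degree arc: end frame = seed rotated 90 degrees about the
  # arc axis (exact for planar curves: every step shares the binormal)
  arc <- circle_arc_3pt(c(2, 0, 0), c(2 / sqrt(2), 0, 2 / sqrt(2)),
                        c(0, 0, 2))$curve
  fa <- propagate_frames(arc, seq(0, 1, length.out = 15))
  R <- axis_rotation(c(0, -1, 0), 90)
  expect_equal(drop(R %*% fa$a2[1, ]), fa$a2[15, ], tolerance = 1e-9)
  expect_equal(drop(R %*% fa$a3[1, ]), fa$a3[15, ], tolerance = 1e-9)
  # theta = 180 flips the section vectors
  fflip <- propagate_frames(sg, c(0, 1), theta0 = 180)
  expect_equal(fflip$a2[2, ], -ff$a2[1, ], tolerance = 1e-12)
  expect_equal(fflip$a3[2, ], -ff$a3[1, ], tolerance = 1e-12)
})

test_that("Lee-Sacks energy matches the reference state and a frozen value", {
  lp <- fixture_config("a")$materials$leaflet
  expect_equal(lee_sacks_energy(3, 1, lp)$psi, 0)
  # independent scalar evaluation at I1 = 3.1, I4 = 1
  expect_equal(lee_sacks_energy(3.1, 1, lp)$psi, 46.73378052964625,
               tolerance = 1e-12)
  # the isotropic skirt model has no I4 dependence
  sp <- fixture_config("a")$materials$skirt
  e <- lee_sacks_energy(3.2, 1.5, sp)
  expect_equal(e$dpsi_dI4, 0)
  expect_equal(lee_sacks_energy(3.2, 1.0, sp)$psi, e$psi)
  expect_warning(lee_sacks_energy(13, 1, lp), "caps")
})

test_that("Lee-Sacks analytic derivatives match finite differences", {
  lp <- fixture_config("a")$materials$leaflet
  h <- 1e-6
  for (I1 in c(3.02, 3.1, 3.25)) {
    for (I4 in c(1.0, 1.05, 1.2)) {
      an <- lee_sacks_energy(I1, I4, lp)
      fd1 <- (lee_sacks_energy(I1 + h, I4, lp)$psi -
              lee_sacks_energy(I1 - h, I4, lp)$psi) / (2 * h)
      fd4 <- (lee_sacks_energy(I1, I4 + h, lp)$psi -
              lee_sacks_energy(I1, I4 - h, lp)$psi) / (2 * h)
      expect_equal(an$dpsi_dI1, fd1, tolerance = 1e-6)
      if (abs(fd4) > 1e-8) expect_equal(an$dpsi_dI4, fd4, tolerance = 1e-6)
    }
  }
})

test_that("effective shell stiffness is 2 c0 (1 + nu)", {
  expect_equal(effective_shell_stiffness(117.1375, 0.5), 351.4125)
  expect_equal(effective_shell_stiffness(10, 0), 20)
  expect_gt(effective_shell_stiffness(11, 0.3),
            effective_shell_stiffness(10, 0.3))
})

test_that("shell-shell penalties keep the H^2 / 12 ratio exactly", {
  p <- penalty_ss(1, 1, 1, 0, 1000)
  expect_equal(p$alpha_d, 1000)
  expect_equal(p$alpha_r, 1000 / 12)
  set.seed(4)
  for (k in 1:20) {
    E <- runif(1, 1, 1e5); H <- runif(1, 0.1, 2); hI <- runif(1, 0.05, 5)
    nu <- runif(1, 0, 0.49); al <- 10^runif(1, 1, 5)
    pp <- penalty_ss(E, H, hI, nu, al)
    expect_equal(pp$alpha_r / pp$alpha_d, H^2 / 12, tolerance = 1e-12)
    # homogeneous of degree 1 in E
    expect_equal(penalty_ss(2 * E, H, hI, nu, al)$alpha_d, 2 * pp$alpha_d,
                 tolerance = 1e-12)
  }
  p5 <- penalty_ss(1, 1, 1, 0.5, 1)
  expect_equal(p5$alpha_d, 1 / 0.75)
  expect_error(penalty_ss(1, 1, 1, 1, 1), "division error")
})

test_that("shell-beam penalty selects the softer branch", {
  eq <- penalty_sb(10, 1, 1, 0, 10, 1, 1, 0, 1)
  expect_equal(eq$alpha_d, 10)
  soft <- penalty_sb(1, 1, 1, 0, 1e6, 1, 1, 0, 1)
  expect_equal(soft$branch, "shell")
  expect_equal(soft$alpha_d, 1)
  # published-magnitude inputs: shell branch wins by >= 4 orders
  E_sh <- effective_shell_stiffness(117.1375, 0.5)
  res <- penalty_sb(E_sh, 0.33, 1, 0.5, 5.8e7, 0.54 * 0.21, 1, 0.33, 1e4)
  expect_equal(res$branch, "shell")
  shell_scale <- E_sh * 0.33 / (1 * (1 - 0.25))
  beam_scale <- 5.8e7 * sqrt(0.1134) / (1 * (1 - 0.33^2))
  expect_gt(beam_scale / shell_scale, 1e4)
  expect_equal(res$alpha_d, 1e4 * shell_scale, tolerance = 1e-12)
})

test_that("contact kernel is a non-positive truncated linear ramp", {
  p <- list(k_c = 2, r_max = 1)
  expect_equal(contact_kernel(0.4, p), -1.2)
  expect_equal(contact_kernel(1, p), 0)
  expect_equal(contact_kernel(1.7, p), 0)
  r <- seq(0, 1.5, length.out = 200)
  k <- contact_kernel(r, p)
  expect_true(all(k <= 0))
  expect_true(all(diff(k) >= -1e-12))          # non-decreasing toward cutoff
  inside <- r < 1
  expect_equal(k[inside], -2 * (1 - r[inside]), tolerance = 1e-12)
})

test_that("friction force vanishes without slip and stays tangential", {
  p <- list(k_c = 10, r_max = 0.5, alpha_f = 1e11)
  n <- c(0, 0, 1)
  # no tangential slip since deployment: zero force
  f0 <- friction_force(c(0.1, 0, 0.1), c(0, 0, 0), c(0.1, 0, 0.1),
                       c(0, 0, 0), n, n, p)
  expect_equal(f0, c(0, 0, 0))
  # beyond the cutoff the kernel is inactive
  f1 <- friction_force(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                       n, n, p)
  expect_equal(f1, c(0, 0, 0))
  # active contact: force perpendicular to the wall normal
  f2 <- friction_force(c(0.2, 0.1, 0.1), c(0, 0, 0), c(0.05, 0, 0.1),
                       c(0, 0, 0), n, n, p)
  expect_gt(sqrt(sum(f2^2)), 0)
  expect_lt(abs(sum(f2 * n)), 1e-12)
})
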