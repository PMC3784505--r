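p_ref <- sim_params()
morph_ref <- build_morphology(p_ref)

test_that("morphology matches the anatomical layout", {
  m <- morph_ref
  left <- m[m$side == "left", ]
  right <- m[m$side == "right", ]
  expect_equal(nrow(left), 7)
  expect_equal(nrow(right), 7)
  expect_equal(left$length[1], 44)
  expect_equal(left$length[7], 8)
  expect_equal(left$curvature[1], -0.01)
  expect_equal(left$curvature[7], 0.08)
  expect_true(all(diff(left$length) < 0))
  # right side is the mirror image of the left
  expect_equal(right$base_x, left$base_x)
  expect_equal(right$base_y, -left$base_y)
  expect_equal(right$length, left$length)
  # bases lie on the pad-arc ellipse
  ell <- ((left$base_x + 30) / 30)^2 + (left$base_y / 12)^2
  expect_equal(ell, rep(1, 7), tolerance = 1e-10)
})

test_that("whisker arcs have the closed-form chord and rotate rigidly", {
  m <- morph_ref[1, ]
  # zero curvature: straight segment of the whisker's length
  straight <- arc_polyline(m, 120, curvature = 0, step = 1)
  expect_equal(sqrt(sum((straight[nrow(straight), ] - straight[1, ])^2)),
               m$length)
  expect_lt(max(sqrt(rowSums(diff(straight)^2))), 1 + 1e-9)
  # chord of a circular arc: (2/k) sin(kL/2), cross-checked by integration
  for (k in c(0.03, -0.01, 0.08)) {
    arc <- arc_polyline(m, 100, curvature = k, step = 0.5)
    chord <- sqrt(sum((arc[nrow(arc), ] - arc[1, ])^2))
    expect_equal(chord, abs(2 / k * sin(k * m$length / 2)), tolerance = 1e-9)
    num <- integrate_arc(c(m$base_x, m$base_y), "left", 100, k, m$length)
    expect_lt(max(abs(arc[nrow(arc), ] - num[nrow(num), ])), 1e-3)
  }
  # one degree of protraction rotates the polyline about the base
  a0 <- arc_polyline(m, 90, step = 1)
  a1 <- arc_polyline(m, 91, step = 1)
  rot <- -pi / 180 # left side: increasing protraction is clockwise
  b <- a0[1, ]
  rotated <- cbind(b[1] + cos(rot) * (a0[, 1] - b[1]) - sin(rot) * (a0[, 2] - b[2]),
                   b[2] + sin(rot) * (a0[, 1] - b[1]) + cos(rot) * (a0[, 2] - b[2]))
  expect_equal(a1, rotated, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("neck drag preserves the fovea-neck separation", {
  pose <- head_pose(c(0, 0), c(-50, 0))
  expect_equal(step_neck(pose, c(100, 0), 50)$neck, c(50, 0))
  same <- step_neck(pose, pose$fovea, 50)
  expect_equal(same$fovea, pose$fovea)
  expect_equal(same$neck, pose$neck)
  set.seed(1)
  for (i in 1:20) {
    nf <- runif(2, -100, 100)
    out <- step_neck(pose, nf, 50)
    expect_equal(sqrt(sum((out$fovea - out$neck)^2)), 50, tolerance = 1e-9)
    pose <- out
  }
  expect_error(step_neck(head_pose(c(0, 0), c(-50, 0)), c(-50, 0), 50),
               class = "vibrisim_pose_error")
})

test_that("frame transforms invert each other", {
  pose <- head_pose(c(13, -7), c(-20, 22))
  tf <- frame_transform(pose)
  expect_equal(as.numeric(tf$head_from_world(pose$fovea)), c(0, 0),
               tolerance = 1e-12)
  expect_equal(as.numeric(tf$head_from_world(pose$neck)),
               c(-sqrt(sum((pose$fovea - pose$neck)^2)), 0),
               tolerance = 1e-9)
  set.seed(2)
  pts <- matrix(runif(40, -200, 200), ncol = 2)
  expect_lt(max(abs(tf$world_from_head(tf$head_from_world(pts)) - pts)), 1e-9)
})

test_that("bending leaves free whiskers unperturbed and clears obstacles", {
  pose <- head_pose(c(0, 0), c(-50, 0))
  far_wall <- obstacle(500, 0, 20, 400)
  free <- resolve_bending(morph_ref, morph_ref$theta_nom, pose, far_wall, p_ref)
  expect_equal(free$kappa_p, morph_ref$curvature)
  expect_true(all(free$contact_signal == 0))
  expect_true(all(is.na(free$contact_x)))

  wall <- obstacle(25, 0, 20, 400)
  bent <- resolve_bending(morph_ref, rep(175, 14), pose, wall, p_ref)
  touching <- which(bent$contact)
  expect_gt(length(touching), 0)
  expect_true(all(bent$contact_signal[touching] > 0))
  expect_true(all(bent$contact_signal >= 0 & bent$contact_signal <= 1))
  # contact_signal = 0 iff no deviation iff no contact point
  expect_equal(bent$contact_signal > 0, bent$delta > 0)
  expect_equal(bent$contact_signal > 0, !is.na(bent$contact_x))
  # perturbed arcs clear the wall to within solver tolerance
  tf <- frame_transform(pose)
  for (i in touching) {
    pts <- arc_polyline(morph_ref[i, ], 175, bent$kappa_p[i], step = 1)
    expect_lt(max_depth_all(tf$world_from_head(pts), wall), 0.01)
  }
})

test_that("the bisection solver matches a dense brute-force curvature scan", {
  pose <- head_pose(c(0, 0), c(-50, 0))
  wall <- obstacle(25, 8, 20, 300, angle = 5)
  for (i in c(1, 2, 3)) {
    m <- morph_ref[i, ]
    bent <- resolve_bending(m, 170, pose, wall, p_ref)
    expect_true(bent$contact)
    oracle <- brute_bend(m, 170, pose, wall)
    expect_equal(bent$delta, oracle$delta, tolerance = 0.01)
  }
})

test_that("bending is mirror symmetric", {
  pose <- head_pose(c(0, 3), c(-50, 1))
  pose_m <- head_pose(c(0, -3), c(-50, -1))
  wall <- obstacle(28, 15, 24, 300, angle = 12)
  wall_m <- mirror_obstacles(wall)
  left <- morph_ref[morph_ref$side == "left", ]
  right <- morph_ref[morph_ref$side == "right", ]
  a <- resolve_bending(left, rep(160, 7), pose, wall, p_ref)
  b <- resolve_bending(right, rep(160, 7), pose_m, wall_m, p_ref)
  expect_equal(a$kappa_p, b$kappa_p, tolerance = 1e-6)
  expect_equal(a$contact_signal, b$contact_signal, tolerance = 1e-6)
  expect_equal(a$contact_x, b$contact_x, tolerance = 1e-6)
  expect_equal(a$contact_y, -b$contact_y, tolerance = 1e-6)
})

test_that("measured shaft angle follows the two-thirds chord", {
  m <- morph_ref[2, ]
  # straight whisker: measured equals base angle
  expect_equal(measured_angle(120, 0, m$length), 120)
  # curved whisker: offset is fixed, independent of protraction
  offs <- vapply(c(80, 110, 150), function(th) {
    pts <- arc_polyline(m, th, step = m$length / 300)
    i23 <- round(2 / 3 * (nrow(pts) - 1)) + 1
    v <- pts[i23, ] - pts[1, ]
    atan2(v[2], -v[1]) * 180 / pi - th
  }, numeric(1))
  expect_lt(diff(range(offs)), 1e-6)
  expect_equal(measured_angle(0, m$curvature, m$length), offs[1],
               tolerance = 0.05)
  # bending caudally drops the measured angle below the unbent value
  expect_lt(measured_angle(150, m$curvature - 0.05, m$length),
            measured_angle(150, m$curvature, m$length))
})
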