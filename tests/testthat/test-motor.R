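p_ref <- sim_params()
grid <- field_grid(p_ref)
morph <- build_morphology(p_ref)

test_that("oscillator drive matches the duty cycle and ticks at 8 Hz", {
  t <- seq(0, 1, by = p_ref$sample_dt)
  osc <- oscillator_step(t, p_ref)
  phase <- t / p_ref$oscillator_period %% 1
  phase <- phase - floor(phase)
  expect_true(all(osc$q[phase < 0.299] == 0))
  expect_true(all(osc$q[phase > 0.301 & phase < 0.999] == 1))
  expect_equal(sum(osc$tick[-1]), 8) # 8 new cycles within one second
  expect_error(sim_params(duty_cycle = 1), class = "vibrisim_param_error")
})

test_that("foveation targets the salience peak with deterministic ties", {
  pose <- head_pose(c(100, 50), c(60, 20))
  S <- empty_field(grid)
  expect_equal(foveation_target(S, grid, pose), pose$fovea)
  S[25, 40] <- 0.7
  tf <- frame_transform(pose)
  expect_equal(foveation_target(S, grid, pose),
               as.numeric(tf$world_from_head(c(grid$x[25], grid$y[40]))))
  # two exactly equal peaks: the nearer to the fovea wins
  S2 <- empty_field(grid)
  S2[12, 30] <- 0.5   # x = 3, y = -1  (close ahead)
  S2[40, 55] <- 0.5   # x = 59, y = 49 (far corner)
  expect_equal(foveation_target(S2, grid, pose),
               as.numeric(tf$world_from_head(c(grid$x[12], grid$y[30]))))
})

test_that("minimum jerk hits its endpoints and the 15/8 peak speed", {
  plan <- min_jerk_plan(c(0, 0), c(80, -40), t0 = 1, duration = 0.175)
  expect_equal(min_jerk(plan, 1), c(0, 0))
  expect_equal(min_jerk(plan, 1 + 0.175), c(80, -40))
  expect_equal(min_jerk(plan, 1 + 0.175 / 2), c(40, -20))
  expect_equal(min_jerk(plan, 0.5), c(0, 0))     # clamped before start
  expect_equal(min_jerk(plan, 2), c(80, -40))    # clamped after end
  ts <- seq(1, 1.175, length.out = 20001)
  pos <- t(vapply(ts, function(t) min_jerk(plan, t), numeric(2)))
  speed <- sqrt(rowSums(diff(pos)^2)) / diff(ts)[1]
  d <- sqrt(sum(c(80, -40)^2))
  expect_equal(max(speed), 1.875 * d / 0.175, tolerance = 1e-4)
})

test_that("geometric angle table is consistent with the arc geometry", {
  gt <- build_geom_table(morph, grid)
  m1 <- morph[1, ]
  cellx <- rep(grid$x, times = grid$ny)
  celly <- rep(grid$y, each = grid$nx)
  r <- sqrt((cellx - m1$base_x)^2 + (celly - m1$base_y)^2)
  tip <- abs(2 / m1$curvature * sin(m1$curvature * m1$length / 2))
  expect_true(all(gt$status[r > tip, 1] == "far"))
  # a straight whisker reaches a cell on bearing psi at exactly theta = psi
  ms <- morph[1, ]
  ms$curvature <- 0
  gts <- build_geom_table(ms, grid)
  e <- which(gts$status == "ok")[100]
  ex <- cellx[e] - ms$base_x
  ey <- celly[e] - ms$base_y
  expect_equal(gts$theta_geom[e, 1], atan2(ey, -ex) * 180 / pi,
               tolerance = 1e-9)
  # curved whiskers: the arc at theta_geom passes within 1 mm of the cell
  set.seed(7)
  ok <- which(gt$status[, 1] == "ok")
  for (e in sample(ok, 25)) {
    pts <- arc_polyline(m1, gt$theta_geom[e, 1], step = 0.2)
    d <- min(sqrt((pts[, 1] - cellx[e])^2 + (pts[, 2] - celly[e])^2))
    expect_lt(d, 1)
  }
})

test_that("proposals clip to the protraction range and reach when too far", {
  expect_equal(proposed_angle(100, "ok", p_ref), 100)
  expect_equal(proposed_angle(20, "ok", p_ref), 30)
  expect_equal(proposed_angle(190, "ok", p_ref), 175)
  expect_equal(proposed_angle(NA_real_, "far", p_ref), 175)
  expect_equal(proposed_angle(NA_real_, "occluded", p_ref), 175)
  expect_true(is.na(proposed_angle(NA_real_, "near", p_ref)))
})

test_that("arbitration is a caudally biased weighted mean", {
  m1 <- morph[4, ] # mid-array: caudal-proposal cells lie on-grid
  tables <- vibrisim:::proposal_tables(m1, grid, p_ref)
  # a single active cell returns exactly its proposal
  gt <- build_geom_table(m1, grid)
  ok_cells <- which(gt$status == "ok" & !is.na(gt$theta_geom))
  e <- ok_cells[round(length(ok_cells) / 2)]
  S <- empty_field(grid)
  S[e] <- 0.8
  th <- arbitrated_angle(S, m1, grid, p_ref, tables)
  expect_equal(th, tables$P[e, 1], tolerance = 1e-9)
  # empty map falls back to the nominal angle
  expect_equal(arbitrated_angle(empty_field(grid), m1, grid, p_ref, tables),
               m1$theta_nom)
  # equal activity at a caudal and a rostral proposal: the caudal bias
  # pulls the mean below the midpoint
  ec <- which(abs(tables$P[, 1] - 60) < 5 & tables$W2[, 1] > 0)[1]
  er <- which(abs(tables$P[, 1] - 160) < 5 & tables$W2[, 1] > 0)[1]
  expect_false(anyNA(c(ec, er)))
  S2 <- empty_field(grid)
  S2[ec] <- 0.5
  S2[er] <- 0.5
  th2 <- arbitrated_angle(S2, m1, grid, p_ref, tables)
  expect_lt(th2, mean(tables$P[c(ec, er), 1]))
  # brute-force double-loop oracle agreement on random fields
  set.seed(8)
  for (i in 1:3) {
    Sr <- matrix(pmax(0, runif(grid$nx * grid$ny, -0.5, 0.5)),
                 grid$nx, grid$ny)
    expect_equal(arbitrated_angle(Sr, m1, grid, p_ref, tables),
                 brute_theta_hat(Sr, m1, grid, p_ref), tolerance = 1e-9)
  }
})

test_that("contrast and modulation behave at their limits", {
  expect_equal(map_contrast(matrix(0.4, 10, 10)), 0)
  expect_equal(map_contrast(matrix(0, 10, 10)), 0)
  one <- empty_field(grid)
  one[1, 1] <- 1
  expect_equal(map_contrast(one), 1, tolerance = 1e-3)
  expect_equal(max_protraction(120, 0.7, 110, sim_params(modulation_strength = 0)),
               110)
  expect_equal(max_protraction(120, 0, 110, p_ref), 110)
  expect_equal(max_protraction(150, 1, 110, p_ref), 130)
  # convexity: theta_max stays inside [theta_min, theta_max]
  set.seed(9)
  th <- runif(100, 30, 175)
  C <- runif(100)
  out <- max_protraction(th, C, 110, p_ref)
  expect_true(all(out >= 30 & out <= 175))
})

test_that("whisking dynamics follow a first-order lag", {
  amp <- per_whisker(p_ref$amplitude_range, 7)
  expect_equal(amp[1], 30)
  expect_equal(amp[7], 45)
  # fixed point at the target
  expect_equal(whisk_step(120, 120, 30, 1, p_ref), 120)
  # step response: the gap shrinks like the Euler map of exp(-t/tau)
  theta <- 70
  nstep <- round(p_ref$whisk_tau / p_ref$sample_dt)
  for (i in seq_len(nstep)) theta <- whisk_step(theta, 120, 30, 1, p_ref)
  euler <- 70 + (120 - 70) * (1 - (1 - p_ref$sample_dt / p_ref$whisk_tau)^nstep)
  expect_equal(theta, euler, tolerance = 1e-9)
  expect_equal((120 - theta) / 50, exp(-1), tolerance = 0.15)
})

test_that("a lone reachable target is touched at maximum protraction", {
  # minimal-impingement, maximal-contact property: with full modulation and
  # contrast, the whisker commanded to theta_max passes through the target
  p1 <- sim_params(modulation_strength = 1)
  m1 <- morph[1, ]
  tables <- vibrisim:::proposal_tables(m1, grid, p1)
  gt <- build_geom_table(m1, grid)
  set.seed(10)
  ok <- which(gt$status == "ok" & gt$theta_geom > 40 & gt$theta_geom < 165)
  cellx <- rep(grid$x, times = grid$ny)
  celly <- rep(grid$y, each = grid$nx)
  for (e in sample(ok, 10)) {
    S <- empty_field(grid)
    S[e] <- 1
    th_hat <- arbitrated_angle(S, m1, grid, p1, tables)
    th_max <- max_protraction(th_hat, 1, m1$theta_nom, p1)
    pts <- arc_polyline(m1, th_max, step = 0.2)
    d <- min(sqrt((pts[, 1] - cellx[e])^2 + (pts[, 2] - celly[e])^2))
    expect_lt(d, 2)
  }
})

test_that("moving a lone target caudally never protracts further", {
  m1 <- morph[4, ] # mid-array whisker: its radial fan stays on-grid
  tables <- vibrisim:::proposal_tables(m1, grid, p_ref)
  r0 <- 18
  psis <- seq(150, 60, by = -10) # bearing from base, rostral to caudal
  th <- vapply(psis, function(psi) {
    # place the cell at fixed radius from the base on the given bearing
    x <- m1$base_x - r0 * cos(psi * pi / 180)
    y <- m1$base_y + r0 * sin(psi * pi / 180)
    S <- empty_field(grid)
    S[which.min(abs(grid$x - x)),
      which.min(abs(grid$y - y))] <- 1
    arbitrated_angle(S, m1, grid, p_ref, tables)
  }, numeric(1))
  expect_true(all(diff(th) <= 1e-9))
})
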