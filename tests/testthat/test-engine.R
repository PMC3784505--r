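p_ref <- sim_params()

test_that("sampling grid and determinism contracts hold", {
  log <- run_simulation(p_ref, duration = 1, seed = 1)
  expect_equal(nrow(log), 126)
  expect_equal(diff(log$t), rep(p_ref$sample_dt, 125), tolerance = 1e-12)
  expect_equal(sum(grepl("^theta_base_", names(log))), 14)
  log2 <- run_simulation(p_ref, duration = 1, seed = 1)
  expect_identical(as.data.frame(log), as.data.frame(log2))
  log3 <- run_simulation(p_ref, duration = 1, seed = 2)
  expect_false(isTRUE(all.equal(log$fovea_x, log3$fovea_x)))
})

test_that("logs are finite everywhere", {
  log <- run_simulation(p_ref, obstacles = arena_obstacles(), duration = 5,
                        seed = 3, init_pose = arena_start_pose())
  num <- as.matrix(log[vapply(log, is.numeric, logical(1))])
  num <- num[, !grepl("^contact_[xy]_", colnames(num))] # NA when no contact
  expect_true(all(is.finite(num)))
})

test_that("a quiescent model whisks periodically in place at nominal angles", {
  pq <- sim_params(noise_gain = 0, other_gain = 0)
  log <- run_simulation(pq, duration = 4, seed = 1)
  # head never moves
  expect_lt(max(abs(log$fovea_x)) + max(abs(log$fovea_y)), 1e-6)
  # whisker 1 oscillates between theta_nom and theta_nom - amplitude
  th <- log$theta_base_l1[log$t > 1]
  expect_lt(max(th), 75 + 1)
  expect_gt(min(th), 75 - 30 - 1)
  expect_gt(max(th) - min(th), 15)
  # tactile salience stays identically zero without contacts or noise
  expect_lt(max(attr(log, "fields")$S_tactile), 1e-6)
  # whisking frequency equals the oscillator rate
  expect_equal(dominant_freq(log$theta_base_l1, 125), 8, tolerance = 0.05)
})

test_that("free exploration orients to random locations", {
  log <- run_simulation(p_ref, duration = 10, seed = 4, log = "summary")
  hops <- sqrt(diff(log$fovea_x[log$tick])^2 + diff(log$fovea_y[log$tick])^2)
  expect_gt(mean(hops > 5), 0.5) # most ticks launch a real movement
  expect_gt(max(abs(log$bearing_deg)), 45)
  # whisk frequency from the commanded angles of any log
  expect_equal(dominant_freq(log$mean_base_l, 125), 8, tolerance = 0.05)
})

test_that("arena exploration engages the tactile channel and follows walls", {
  log <- run_simulation(p_ref, obstacles = arena_obstacles(), duration = 60,
                        seed = 5, init_pose = arena_start_pose(),
                        log = "summary")
  frac <- mean(log$channel[log$tick] == "tactile")
  expect_gt(frac, 0.3)
})

test_that("no perturbed whisker enters an obstacle at any logged sample", {
  walls <- arena_obstacles()
  log <- run_simulation(p_ref, obstacles = walls, duration = 10, seed = 6,
                        init_pose = arena_start_pose())
  morph <- build_morphology(p_ref)
  rows <- which(log$n_contact_l + log$n_contact_r > 0)
  set.seed(11)
  for (i in sample(rows, min(25, length(rows)))) {
    pose <- head_pose(c(log$fovea_x[i], log$fovea_y[i]),
                      c(log$neck_x[i], log$neck_y[i]))
    th <- unlist(log[i, paste0("theta_base_",
                               vibrisim:::whisker_labels(morph))])
    bend <- resolve_bending(morph, th, pose, walls, p_ref)
    tf <- frame_transform(pose)
    # clamped whiskers flag unresolvable deep penetration (e.g. a base
    # carried into a wall by the collisionless snout) and are excluded
    for (j in which(!bend$clamped)) {
      pts <- arc_polyline(morph[j, ], th[j], bend$kappa_p[j], step = 1)
      expect_lt(max_depth_all(tf$world_from_head(pts), walls), 0.01)
    }
  }
})

test_that("a world-fixed contact ridge stays put under remapping", {
  # a contact at a fixed world point is re-deposited every sample while
  # the head shuttles at 100 mm/s; after 1 s the ridge peak must sit
  # within two cells of the true world location
  grid <- field_grid(p_ref)
  pose <- head_pose(c(0, 0), c(-50, 0))
  world <- as.numeric(frame_transform(pose)$world_from_head(c(40, 10)))
  dt <- p_ref$sample_dt
  cur <- empty_field(grid)
  pc <- pose
  for (i in 1:125) {
    v <- if (i <= 62) c(100, 0) else c(-100, 0) # out and back
    pn <- head_pose(pc$fovea + v * dt, pc$neck + v * dt)
    cur <- remap_field(cur, grid, pc, pn)
    ph <- as.numeric(frame_transform(pn)$head_from_world(world))
    cur <- pmax(cur, deposit_blobs(empty_field(grid), grid, ph, 1, 8))
    pc <- pn
  }
  peak <- which(cur == max(cur), arr.ind = TRUE)[1, ]
  pw <- frame_transform(pc)$world_from_head(c(grid$x[peak[1]],
                                              grid$y[peak[2]]))
  expect_lt(sqrt(sum((pw - world)^2)), 2 * grid$res)
})

test_that("a mirrored world with mirrored noise mirrors the whole log", {
  obst <- obstacle(cx = 60, cy = 25, width = 30, height = 120, angle = 10)
  a <- run_simulation(p_ref, obst, duration = 3, seed = 9,
                      init_pose = head_pose(c(0, 5), c(-50, 3)))
  b <- run_simulation(p_ref, mirror_obstacles(obst), duration = 3, seed = 9,
                      init_pose = head_pose(c(0, -5), c(-50, -3)),
                      flip_noise = TRUE)
  expect_equal(a$fovea_x, b$fovea_x, tolerance = 1e-6)
  expect_equal(a$fovea_y, -b$fovea_y, tolerance = 1e-6)
  expect_equal(a$bearing_deg, -b$bearing_deg, tolerance = 1e-6)
  expect_equal(a$channel, b$channel)
  for (i in 1:7) {
    expect_equal(a[[paste0("theta_base_l", i)]],
                 b[[paste0("theta_base_r", i)]], tolerance = 1e-6)
    expect_equal(a[[paste0("contact_r", i)]],
                 b[[paste0("contact_l", i)]], tolerance = 1e-6)
  }
})

test_that("whisk segmentation labels pre and contact whisks", {
  # synthetic contact pattern: contact starting mid-interval marks that
  # whisk as the first contact whisk
  log <- run_simulation(p_ref, duration = 1, seed = 1)
  wk0 <- segment_whisks(log, "left")
  expect_equal(nrow(wk0), 8) # 1 s at 8 Hz
  fake <- log
  for (i in 1:7) fake[[paste0("contact_l", i)]] <- 0
  ticks <- which(fake$tick)
  fake$contact_l1[ticks[4] - 7] <- 0.5              # mid-whisk 3
  fake$contact_l1[(ticks[5] - 3):ticks[5]] <- 0.8   # whisk 4
  fake$contact_l2[ticks[5] - 2] <- 0.2
  wk <- segment_whisks(fake, "left")
  expect_equal(wk$class[1:5], c("other", "pre", "first", "second", "other"))
  expect_equal(wk$n_whiskers[4], 2)
  empty <- segment_whisks(log[0, ], "left")
  expect_equal(nrow(empty), 0)
})
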