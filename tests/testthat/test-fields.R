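p_ref <- sim_params()
grid <- field_grid(p_ref)

test_that("blob deposition peaks, sums and clips as specified", {
  f <- empty_field(grid)
  expect_equal(deposit_blobs(f, grid, matrix(numeric(0), ncol = 2),
                             numeric(0), 8), f)
  # unit blob at a cell centre peaks at exactly 1 after clipping
  centre <- c(grid$x[20], grid$y[30])
  one <- deposit_blobs(f, grid, centre, 1, 8)
  expect_equal(one[20, 30], 1)
  expect_equal(max(one), 1)
  # coincident blobs clip at 1, not 1.2
  two <- deposit_blobs(f, grid, rbind(centre, centre), c(0.6, 0.6), 8)
  expect_equal(two[20, 30], 1)
  # points outside the extent are silently ignored
  out <- deposit_blobs(f, grid, c(500, 0), 1, 8)
  expect_equal(out, f)
})

test_that("remapping preserves world locations and never gains mass", {
  pose <- head_pose(c(10, 5), c(-40, 5))
  f <- empty_field(grid)
  f[20, 30] <- 1
  expect_equal(remap_field(f, grid, pose, pose), f)
  # 10 mm translation: the impulse tracks its world position within a cell
  tf0 <- frame_transform(pose)
  world <- tf0$world_from_head(c(grid$x[20], grid$y[30]))
  pose2 <- head_pose(pose$fovea + c(10, 0), pose$neck + c(10, 0))
  g <- remap_field(f, grid, pose, pose2)
  peak <- which(g == max(g), arr.ind = TRUE)[1, ]
  expected <- frame_transform(pose2)$head_from_world(world)
  expect_lt(abs(grid$x[peak[1]] - expected[1]), grid$res + 1e-9)
  expect_lt(abs(grid$y[peak[2]] - expected[2]), grid$res + 1e-9)
  # repeated small rotations only lose mass (interpolation + boundary)
  blob <- deposit_blobs(empty_field(grid), grid, c(20, 0), 0.8, 12)
  cur <- blob
  pc <- pose
  for (i in 1:10) {
    ang <- i * pi / 180
    pn <- head_pose(pc$fovea, pc$fovea - 50 * c(cos(ang), sin(ang)))
    nxt <- remap_field(cur, grid, pc, pn)
    expect_lte(sum(nxt), sum(cur) + 1e-9)
    cur <- nxt
    pc <- pn
  }
})

test_that("excitation update is a leaky max with clipping", {
  pose <- head_pose(c(0, 0), c(-50, 0))
  E <- deposit_blobs(empty_field(grid), grid, c(10, 10), 0.7, 8)
  # identity warp, no input, no decay: fixed point
  expect_equal(update_excitation(E, empty_field(grid), grid, pose, pose), E)
  # a stronger input wins entry-wise (max semantics)
  blob <- deposit_blobs(empty_field(grid), grid, c(10, 10), 0.9, 8)
  expect_equal(update_excitation(E, blob, grid, pose, pose), blob)
  # with decay the stored state fades toward the input floor
  faded <- update_excitation(E, empty_field(grid), grid, pose, pose,
                             decay = 0.9)
  expect_equal(faded, 0.9 * E)
  # noise perturbs then clips to [0, 1]
  set.seed(3)
  nz <- noise_step(NULL, grid, p_ref)
  noisy <- update_excitation(E, blob, grid, pose, pose, nz, 0.025)
  expect_true(all(noisy >= 0 & noisy <= 1))
})

test_that("coloured noise reaches unit stationary variance", {
  set.seed(4)
  st <- noise_step(NULL, grid, p_ref)
  acc <- 0
  nkeep <- 400
  vals <- numeric(nkeep)
  for (i in seq_len(nkeep)) {
    st <- noise_step(st, grid, p_ref)
    vals[i] <- st[17, 23]
    acc <- acc + stats::var(as.vector(st))
  }
  expect_equal(acc / nkeep, 1, tolerance = 0.1)
  # per-cell increment scale: gain * unit sd
  expect_equal(sd(vals) * p_ref$noise_gain, 0.025, tolerance = 0.2)
})

test_that("the stochastic channel emits one blob per tick, uniformly", {
  expect_equal(other_input(FALSE, grid, p_ref), empty_field(grid))
  set.seed(5)
  f <- other_input(TRUE, grid, p_ref)
  expect_gt(max(f), 0.45)
  expect_lte(max(f), 0.5)
  # a single connected active region
  active <- f > 0.05
  ij <- which(active, arr.ind = TRUE)
  expect_lt(max(dist(ij)), 30)
  # peak locations uniform over the extent (chi-square on 4x4 occupancy)
  set.seed(6)
  counts <- matrix(0, 4, 4)
  for (i in 1:1000) {
    g <- other_input(TRUE, grid, p_ref)
    peak <- which(g == max(g), arr.ind = TRUE)[1, ]
    bx <- min(4, ceiling(peak[1] / (grid$nx / 4)))
    by <- min(4, ceiling(peak[2] / (grid$ny / 4)))
    counts[bx, by] <- counts[bx, by] + 1
  }
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("obstacle inhibition covers interiors and shadows", {
  pose <- head_pose(c(0, 0), c(-50, 0))
  none <- obstacle_inhibition(grid, pose, arena_obstacles()[0, ])
  expect_equal(none, empty_field(grid))
  wall <- obstacle(30, 0, 10, 200)
  H <- obstacle_inhibition(grid, pose, wall)
  ix_in <- which.min(abs(grid$x - 30))
  iy0 <- which.min(abs(grid$y - 0))
  expect_equal(H[ix_in, iy0], 1)          # inside the wall
  ix_behind <- which.min(abs(grid$x - 50))
  expect_equal(H[ix_behind, iy0], 1)      # shadowed behind it
  ix_front <- which.min(abs(grid$x - 10))
  expect_equal(H[ix_front, iy0], 0)       # free space in front
})

test_that("IOR memory expires and sums before the cap", {
  mem <- NULL
  mem <- ior_step(mem, c(0, 0), 0, p_ref)
  mem <- ior_step(mem, c(10, 0), 4.01, p_ref)
  expect_equal(nrow(mem), 1) # the 4.01 s old entry has been forgotten
  expect_equal(mem$x, 10)
  pose <- head_pose(c(0, 0), c(-50, 0))
  expect_equal(ior_field(NULL, grid, pose, p_ref), empty_field(grid))
  # two coincident visits sum to 1.0 before the inhibition cap
  mem2 <- tibble::tibble(x = c(20, 20), y = c(0, 0), t = c(0, 1))
  f <- ior_field(mem2, grid, pose, p_ref)
  ix <- which.min(abs(grid$x - 20))
  iy <- which.min(abs(grid$y - 0))
  expect_equal(f[ix, iy], 1, tolerance = 0.01)
})

test_that("inhibition caps IOR but not obstacles; salience gates excitation", {
  H_ior <- matrix(1, grid$nx, grid$ny)
  H_obs <- empty_field(grid)
  expect_equal(inhibition(H_obs, H_ior, p_ref)[1, 1], 0.66)
  H_obs[3, 3] <- 1
  expect_equal(inhibition(H_obs, H_ior, p_ref)[3, 3], 1)
  expect_equal(inhibition(empty_field(grid), empty_field(grid), p_ref),
               empty_field(grid))
  E <- matrix(0.8, grid$nx, grid$ny)
  expect_equal(salience(E, matrix(1, grid$nx, grid$ny)), 0 * E)
  expect_equal(salience(E, empty_field(grid)), E)
  expect_equal(salience(matrix(0.8, 1, 1), matrix(0.66, 1, 1))[1, 1], 0.272)
})

test_that("channel selection takes the higher peak and holds ties", {
  St <- empty_field(grid)
  So <- empty_field(grid)
  St[5, 5] <- 0.9
  So[6, 6] <- 0.5
  expect_equal(select_channel(St, So), "tactile")
  expect_equal(select_channel(So * 0, So), "other")
  expect_equal(select_channel(St * 0, So * 0, previous = "tactile"),
               "tactile")
})
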