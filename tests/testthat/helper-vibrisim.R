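# Shared fixtures and independent oracles for the test suite.

# numerical arc integration, independent of the closed-form kernels
integrate_arc <- function(base, side, theta_deg, kappa, L, n = 20000) {
  sgn <- if (side == "left") 1 else -1
  phi <- if (sgn > 0) pi - theta_deg * pi / 180 else theta_deg * pi / 180 - pi
  k <- if (sgn > 0) -kappa else kappa
  ds <- L / n
  s <- (seq_len(n) - 0.5) * ds
  ang <- phi + k * s
  cbind(c(base[1], base[1] + cumsum(cos(ang) * ds)),
        c(base[2], base[2] + cumsum(sin(ang) * ds)))
}

# signed interior depth of points in one obstacle row (> 0 strictly inside)
inside_depth <- function(pts, ob) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  a <- ob$angle * pi / 180
  dx <- pts[, 1] - ob$cx
  dy <- pts[, 2] - ob$cy
  qx <- cos(a) * dx + sin(a) * dy
  qy <- -sin(a) * dx + cos(a) * dy
  pmin(ob$width / 2 - abs(qx), ob$height / 2 - abs(qy))
}

max_depth_all <- function(pts, obstacles) {
  if (nrow(obstacles) == 0) return(-Inf)
  max(vapply(seq_len(nrow(obstacles)),
             function(i) max(inside_depth(pts, obstacles[i, ])),
             numeric(1)))
}

# brute-force quasistatic bending: dense scan over caudal curvature offsets
brute_bend <- function(morph_row, theta, pose, obstacles, n = 10000) {
  tf <- frame_transform(pose)
  dks <- seq(0, 0.25, length.out = n)
  pen <- vapply(dks, function(dk) {
    pts <- arc_polyline(morph_row, theta, morph_row$curvature - dk, step = 1)
    max_depth_all(tf$world_from_head(pts), obstacles)
  }, numeric(1))
  ok <- which(pen <= 0)
  dk <- if (length(ok) == 0) 0.25 else dks[ok[1]]
  p0 <- arc_polyline(morph_row, theta, morph_row$curvature, step = 1)
  p1 <- arc_polyline(morph_row, theta, morph_row$curvature - dk, step = 1)
  i5 <- which.min(abs(seq(0, morph_row$length,
                          length.out = nrow(p0)) - 5))
  list(dk = dk, delta = sqrt(sum((p1[i5, ] - p0[i5, ])^2)))
}

# brute-force arbitration: plain double loop over grid cells
brute_theta_hat <- function(S, morph_row, grid, params) {
  gt <- build_geom_table(morph_row, grid)
  P <- proposed_angle(gt$theta_geom, gt$status, params)
  span <- params$theta_max - params$theta_min
  num <- 0
  den <- 0
  for (e in seq_along(S)) {
    if (is.na(P[e, 1])) next
    w <- (params$activity_gain * S[e])^params$activity_exponent *
      params$caudal_bias_base^(-(P[e, 1] - params$theta_min) / span)
    num <- num + w * P[e, 1]
    den <- den + w
  }
  if (den == 0) morph_row$theta_nom else num / den
}

# dominant nonzero frequency of a trace sampled at fs
dominant_freq <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(fft(x))[2:floor(n / 2)]
  fr <- (1:(floor(n / 2) - 1)) * fs / n
  fr[which.max(sp)]
}
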