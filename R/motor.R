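#' Behavioural oscillator
#'
#' The oscillator ticks every `oscillator_period` seconds and emits the
#' whisking drive `q`, which is 0 during the first `1 - duty_cycle` of each
#' cycle (retraction) and 1 during the final `duty_cycle` fraction
#' (protraction), so that its falling edge -- the point of maximum
#' protraction -- coincides with the tick.
#'
#' @param t Sample time(s) (s), vectorised.
#' @param params A [sim_params()] object.
#' @return A tibble with columns `t`, `tick` (logical; `TRUE` when a new
#'   cycle starts at or before this sample, the first sample counts as a
#'   tick) and `q` (0/1 whisking drive).
#' @export
oscillator_step <- function(t, params) {
  Tc <- params$oscillator_period
  cyc <- floor(t / Tc + 1e-9)
  phase <- t / Tc - cyc
  q <- as.integer(phase >= (1 - params$duty_cycle) - 1e-9)
  tick <- c(TRUE, diff(cyc) > 0)
  tibble(t = t, tick = tick, q = q)
}

#' Foveation target from a salience map
#'
#' The world location of the peak salience cell. Exact ties are broken by
#' smallest distance to the current fovea, then by lowest cell index; an
#' all-zero map keeps the fovea in place.
#'
#' @param S Salience field matrix.
#' @param grid A [field_grid()].
#' @param pose Current [head_pose()].
#' @return Length-2 world point.
#' @export
foveation_target <- function(S, grid, pose) {
  mx <- max(S)
  if (mx <= 0) return(pose$fovea)
  idx <- which(S == mx)
  tf <- frame_transform(pose)
  ix <- (idx - 1) %% grid$nx + 1
  iy <- (idx - 1) %/% grid$nx + 1
  pts <- tf$world_from_head(cbind(grid$x[ix], grid$y[iy]))
  d2 <- (pts[, 1] - pose$fovea[1])^2 + (pts[, 2] - pose$fovea[2])^2
  pts[which.min(d2), ]
}

#' Minimum-jerk head trajectory
#'
#' `min_jerk_plan()` pre-computes an open-loop minimum-jerk movement from
#' `start` to `target` (zero velocity and acceleration at both ends);
#' `min_jerk()` evaluates it, clamping outside the time span. A new plan is
#' issued at each oscillator tick from the current fovea position, so a
#' plan longer than the tick interval is interrupted before completion.
#'
#' @param start,target World points (mm).
#' @param t0 Plan start time (s).
#' @param duration Plan duration (s), the foveation period.
#' @return `min_jerk_plan()`: a `foveation_plan` list; `min_jerk()`: a
#'   length-2 world point.
#' @export
min_jerk_plan <- function(start, target, t0, duration) {
  structure(list(start = as.numeric(start), target = as.numeric(target),
                 t0 = t0, duration = duration),
            class = "foveation_plan")
}

#' @rdname min_jerk_plan
#' @param plan A `foveation_plan`.
#' @param t Evaluation time (s).
#' @export
min_jerk <- function(plan, t) {
  tau <- (t - plan$t0) / plan$duration
  tau <- min(1, max(0, tau))
  s <- tau^3 * (10 + tau * (-15 + 6 * tau))
  plan$start + (plan$target - plan$start) * s
}

# --------------------------------------------------------------------------
# Salience-to-protraction transform
# --------------------------------------------------------------------------

#' Geometric protraction angles for every whisker / cell pair
#'
#' For each whisker and each grid cell, the protraction angle at which the
#' unperturbed whisker arc passes through the cell centre. Because the arc
#' rotates rigidly about its base, the angle decomposes into the bearing of
#' the cell from the base minus a fixed chord offset that depends only on
#' the distance: a chord of arc length `s` on a circular arc of curvature
#' `kappa` subtends `kappa * s / 2` at the base. Cells farther from the
#' base than the whisker tip are unreachable ("far"); cells whose geometric
#' angle falls outside the whisker's own half-plane (0 to 180 degrees,
#' i.e. cells the shaft could only meet by sweeping through the head) are
#' occluded ("occluded"); with a monotone radius profile no cell is
#' unreachable "near", but the status is kept for completeness.
#'
#' @param morph Whisker morphology tibble ([build_morphology()]).
#' @param grid A [field_grid()].
#' @return A list with `theta_geom` (cells-by-whiskers matrix of angles in
#'   degrees, `NA` where unreachable) and `status` (same shape; `"ok"`,
#'   `"far"`, `"occluded"`, or `"near"`). Whisker columns follow the row
#'   order of `morph`.
#' @export
build_geom_table <- function(morph, grid) {
  ncell <- grid$nx * grid$ny
  cellx <- rep(grid$x, times = grid$ny)
  celly <- rep(grid$y, each = grid$nx)
  nwh <- nrow(morph)
  theta <- matrix(NA_real_, ncell, nwh)
  status <- matrix("ok", ncell, nwh)
  for (j in seq_len(nwh)) {
    w <- morph[j, ]
    sgn <- if (w$side == "left") 1 else -1
    vx <- cellx - w$base_x
    vy <- sgn * (celly - w$base_y)
    r <- sqrt(vx^2 + vy^2)
    psi <- atan2(vy, -vx) * 180 / pi
    k <- w$curvature
    if (abs(k) < 1e-12) {
      tip <- w$length
      s_star <- r
    } else {
      tip <- abs(2 / k * sin(k * w$length / 2))
      s_star <- (2 / k) * asin(pmin(pmax(k * r / 2, -1), 1))
    }
    far <- r > tip
    th <- psi - (k * s_star / 2) * 180 / pi
    occ <- !far & (th < 0 | th > 180)
    theta[, j] <- th
    theta[far | occ, j] <- NA_real_
    status[far, j] <- "far"
    status[occ, j] <- "occluded"
  }
  list(theta_geom = theta, status = status)
}

#' Proposed maximum protraction angle for one geometric entry
#'
#' Reachable cells propose their geometric angle plus the impingement
#' offset, clipped to the allowed protraction range. Cells the whisker
#' cannot touch -- beyond its tip, or occluded by the head on the
#' contralateral side -- propose `theta_max`, so whiskers reach forward
#' towards objects they cannot contact. Cells unreachable on the near side
#' are excluded from arbitration (weight zero, encoded as `NA`).
#'
#' @param theta_geom Geometric angle(s) (deg), `NA` where unreachable.
#' @param status Matching status (`"ok"`, `"far"`, `"occluded"`,
#'   `"near"`), vectorised.
#' @param params A [sim_params()] object.
#' @return Proposed angle(s) in degrees (`NA` for near-unreachable cells).
#' @export
proposed_angle <- function(theta_geom, status, params) {
  out <- pmin(pmax(theta_geom + params$theta_imp, params$theta_min),
              params$theta_max)
  out[status == "far" | status == "occluded"] <- params$theta_max
  out[status == "near"] <- NA_real_
  out
}

# proposal tables for the engine: P holds the proposed angle per (cell,
# whisker); W2 the caudal-bias weight b^(-(P - theta_min)/(theta_max -
# theta_min)), zero where excluded
proposal_tables <- function(morph, grid, params) {
  gt <- build_geom_table(morph, grid)
  P <- proposed_angle(gt$theta_geom, gt$status, params)
  span <- params$theta_max - params$theta_min
  W2 <- params$caudal_bias_base^(-(P - params$theta_min) / span)
  W2[is.na(P)] <- 0
  P[is.na(P)] <- 0
  list(P = P, W2 = W2)
}

#' Arbitrated protraction angle
#'
#' A weighted mean over grid cells of the proposed angles, with weight
#' `(activity_gain * S_e)^activity_exponent *
#' caudal_bias_base^(-(prop - theta_min)/(theta_max - theta_min))`: active
#' cells count more, and cells proposing more caudal angles count more, so
#' the whisker tends to meet the first active region it would reach during
#' protraction. An all-zero map falls back to the nominal angles.
#'
#' @param S Salience field matrix.
#' @param morph Whisker morphology tibble.
#' @param grid A [field_grid()].
#' @param params A [sim_params()] object.
#' @param tables Optional precomputed [proposal_tables] (recomputed
#'   otherwise).
#' @return Arbitrated angle per whisker (deg), in `morph` row order.
#' @export
arbitrated_angle <- function(S, morph, grid, params, tables = NULL) {
  if (is.null(tables)) tables <- proposal_tables(morph, grid, params)
  theta_hat_cpp(S, tables$W2, tables$P, params$activity_gain,
                params$activity_exponent, morph$theta_nom, grid$res)
}

#' Salience map contrast
#'
#' `C = clip(max(S) - mean(S), 0, 1)`: zero for flat maps, approximately
#' the peak height for sparse maps. Gates how strongly the arbitrated
#' angles move the whiskers away from their nominal posture.
#'
#' @param S Salience field matrix.
#' @return Contrast in \[0, 1\].
#' @export
map_contrast <- function(S) {
  min(1, max(0, max(S) - mean(S)))
}

#' Instantaneous maximum protraction angle
#'
#' `theta_max_i = theta_nom_i + gamma * C * (theta_hat_i - theta_nom_i)`:
#' the whisker moves from its nominal posture towards the arbitrated angle
#' in proportion to the modulation strength and the map contrast.
#'
#' @param theta_hat Arbitrated angle(s) (deg).
#' @param C Map contrast.
#' @param theta_nom Nominal angle(s) (deg).
#' @param params A [sim_params()] object.
#' @return Maximum protraction angle(s) (deg).
#' @export
max_protraction <- function(theta_hat, C, theta_nom, params) {
  theta_nom + params$modulation_strength * C * (theta_hat - theta_nom)
}

#' One whisking step
#'
#' First-order (Euler) lag of the commanded base angle towards the
#' instantaneous target: the maximum protraction angle while the drive is
#' high, or that angle minus the whisk amplitude while it is low.
#'
#' @param theta_base Current base angle(s) (deg).
#' @param theta_max Instantaneous maximum protraction angle(s) (deg).
#' @param amplitude Whisk amplitude(s) (deg).
#' @param q Whisking drive (0 or 1).
#' @param params A [sim_params()] object (`sample_dt`, `whisk_tau`).
#' @return Updated base angle(s) (deg).
#' @export
whisk_step <- function(theta_base, theta_max, amplitude, q, params) {
  target <- if (q > 0) theta_max else theta_max - amplitude
  theta_base + (params$sample_dt / params$whisk_tau) * (target - theta_base)
}
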