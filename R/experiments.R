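#' Zero-phase low-pass filter
#'
#' Forward-backward second-order Butterworth filter, the standard zero-phase
#' smoothing applied to behavioural time series before down-sampling.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz).
#' @return Filtered vector.
#' @export
lowpass_zero_phase <- function(x, fs, cutoff = 2) {
  bf <- signal::butter(2, cutoff / (fs / 2))
  as.numeric(signal::filtfilt(bf, x))
}

unwrap_deg <- function(b) {
  d <- diff(b)
  d <- d - 360 * round(d / 360)
  b[1] + c(0, cumsum(d))
}

turn_rate_deg_ms <- function(bearing_deg, dt) {
  b <- unwrap_deg(bearing_deg)
  n <- length(b)
  r <- numeric(n)
  r[2:(n - 1)] <- (b[3:n] - b[1:(n - 2)]) / (2 * dt)
  r[1] <- (b[2] - b[1]) / dt
  r[n] <- (b[n] - b[n - 1]) / dt
  r / 1000 # deg per ms
}

# indices of the samples nearest each oscillator tick (one per whisk)
tick_indices <- function(log) {
  which(log$tick)
}

#' Head-turning asymmetry experiment
#'
#' Runs the simulation in free space (no obstacles), where foveation is
#' driven only by the stochastic channel, and regresses the left-minus-
#' right asymmetry of the bilateral mean protraction angles on the head
#' turn rate. Turn rate is the central-difference derivative of the
#' (unwrapped) head bearing, zero-phase low-pass filtered at 2 Hz, in
#' degrees per millisecond. A negative slope is head-turning asymmetry:
#' whiskers lead the turn, more caudal on the side the head turns towards.
#'
#' @param params A [sim_params()] object.
#' @param duration Run length (s).
#' @param seed Integer seed.
#' @param angle `"shaft"` (measured, tracking-style) or `"base"` angles;
#'   identical in free space where no bending occurs.
#' @param flip_attention Mirror the selected salience map in the whisker
#'   pathway (reverses the asymmetry's sense).
#' @param rate_smooth_ms Optional extra moving-average window applied to
#'   the turn rate (ms), 0 for none.
#' @return An `hta_result` with elements `slope`, `intercept`,
#'   `correlation`, `n`, and `data` (a tibble of per-sample `t`,
#'   `asymmetry`, `turn_rate`).
#' @export
run_hta <- function(params = sim_params(), duration = 30, seed = 1L,
                    angle = c("shaft", "base"), flip_attention = FALSE,
                    rate_smooth_ms = 0) {
  angle <- match.arg(angle)
  log <- run_simulation(params, obstacles = NULL, duration = duration,
                        seed = seed, flip_attention = flip_attention,
                        log = "summary")
  fs <- 1 / params$sample_dt
  ml <- if (angle == "shaft") log$mean_meas_l else log$mean_base_l
  mr <- if (angle == "shaft") log$mean_meas_r else log$mean_base_r
  asym <- ml - mr
  rate <- lowpass_zero_phase(turn_rate_deg_ms(log$bearing_deg,
                                              params$sample_dt), fs)
  if (rate_smooth_ms > 0) {
    w <- max(1L, round(rate_smooth_ms / 1000 / params$sample_dt))
    rate <- as.numeric(stats::filter(rate, rep(1 / w, w), sides = 2))
    keep <- !is.na(rate)
    rate <- rate[keep]
    asym <- asym[keep]
    log <- log[keep, ]
  }
  if (stats::sd(rate) < 1e-12) {
    abort("turn rate has zero variance; cannot fit HTA regression",
          class = "vibrisim_analysis_error")
  }
  fit <- lm(asym ~ rate)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 correlation = cor(asym, rate),
                 n = length(asym),
                 data = tibble(t = log$t, asymmetry = asym,
                               turn_rate = rate),
                 params = params, seed = seed, duration = duration,
                 angle = angle),
            class = "hta_result")
}

#' @export
print.hta_result <- function(x, ...) {
  cat(sprintf(paste0("<hta_result> slope %.1f deg per deg/ms ",
                     "(r = %.2f, n = %d, %.3g s)\n"),
              x$slope, x$correlation, x$n, x$duration))
  invisible(x)
}

#' Contact-induced asymmetry experiment
#'
#' Runs the simulation inside a square arena, then reprises the wall-
#' interaction analysis: bilateral mean base angles and the nose (fovea)
#' position are zero-phase low-pass filtered at 2 Hz and down-sampled to
#' one sample per whisk (the sample at each oscillator tick). Whisks with
#' the nose within `near` mm of exactly one wall and at least `far` mm
#' from the others form the NEAR set; whisks at least `far` mm from every
#' wall form the FAR set, whose grand mean over both sides is the
#' unperturbed baseline. For each NEAR whisk the nearest wall point is
#' expressed nose-relative in the head frame and the relative (baseline-
#' subtracted) mean angle of the left side is accumulated in square bins;
#' right-side data are mirrored and pooled, so positive lateral bin
#' coordinates are ipsilateral to the measured side.
#'
#' @param params A [sim_params()] object.
#' @param duration Run length (s); 3600 s reprises the full one-hour
#'   exploration.
#' @param seed Integer seed.
#' @param angle `"base"` (whisker control, the informative variant) or
#'   `"shaft"` (includes physical deformation).
#' @param arena_side,wall_thickness Arena geometry (mm).
#' @param near,far NEAR/FAR distance thresholds (mm).
#' @param bin Bin size for the wall-point map (mm).
#' @param flip_attention Mirror the selected salience map in the whisker
#'   pathway.
#' @return A `cia_result` with the binned `map` tibble (`x`, `y` bin
#'   centres, mean `value` in deg relative to baseline, `n` per bin),
#'   `baseline` (deg), whisk counts `n_near` and `n_far`, and the
#'   down-sampled `whisks` tibble.
#' @export
run_cia <- function(params = sim_params(), duration = 3600, seed = 1L,
                    angle = c("base", "shaft"), arena_side = 400,
                    wall_thickness = 20, near = 25, far = 100, bin = 4,
                    flip_attention = FALSE) {
  angle <- match.arg(angle)
  walls <- arena_obstacles(arena_side, wall_thickness)
  log <- run_simulation(params, obstacles = walls, duration = duration,
                        seed = seed,
                        init_pose = arena_start_pose(arena_side,
                                                     params$fovea_neck_sep),
                        flip_attention = flip_attention, log = "summary")
  fs <- 1 / params$sample_dt
  lp <- function(x) lowpass_zero_phase(x, fs)
  ml <- lp(if (angle == "base") log$mean_base_l else log$mean_meas_l)
  mr <- lp(if (angle == "base") log$mean_base_r else log$mean_meas_r)
  fx <- lp(log$fovea_x)
  fy <- lp(log$fovea_y)
  nx <- lp(log$neck_x)
  ny <- lp(log$neck_y)
  ti <- tick_indices(log)
  nose <- cbind(fx[ti], fy[ti])
  d <- obstacle_distance(nose, walls)
  near_one <- rowSums(d < near) == 1 & rowSums(d >= far) == ncol(d) - 1
  far_all <- rowSums(d >= far) == ncol(d)
  if (!any(near_one) || !any(far_all)) {
    abort("NEAR or FAR whisk set is empty; run longer",
          class = "vibrisim_analysis_error")
  }
  baseline <- mean(c(ml[ti][far_all], mr[ti][far_all]))
  whisks <- tibble(t = log$t[ti], nose_x = nose[, 1], nose_y = nose[, 2],
                   mean_l = ml[ti], mean_r = mr[ti],
                   set = dplyr::case_when(near_one ~ "near",
                                          far_all ~ "far",
                                          TRUE ~ "neither"))
  # nose-relative wall point in head frame for each NEAR whisk
  rows <- which(near_one)
  wall_idx <- apply(d[rows, , drop = FALSE], 1, which.min)
  pw <- matrix(NA_real_, length(rows), 2)
  for (i in seq_along(rows)) {
    k <- rows[i]
    wp <- nearest_obstacle_point(nose[k, ], walls[wall_idx[i], ])
    pose <- head_pose(c(fx[ti[k]], fy[ti[k]]), c(nx[ti[k]], ny[ti[k]]))
    pw[i, ] <- frame_transform(pose)$head_from_world(wp)
  }
  pooled <- dplyr::bind_rows(
    tibble(x = pw[, 1], y = pw[, 2], value = ml[ti][rows] - baseline),
    tibble(x = pw[, 1], y = -pw[, 2], value = mr[ti][rows] - baseline)
  )
  map <- pooled |>
    dplyr::mutate(x = (floor(.data$x / bin) + 0.5) * bin,
                  y = (floor(.data$y / bin) + 0.5) * bin) |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(value = mean(.data$value), n = dplyr::n(),
                     .groups = "drop")
  structure(list(map = map, baseline = baseline,
                 n_near = sum(near_one), n_far = sum(far_all),
                 n_whisks = length(ti), whisks = whisks,
                 params = params, seed = seed, duration = duration,
                 angle = angle, bin = bin, near = near, far = far),
            class = "cia_result")
}

#' @export
print.cia_result <- function(x, ...) {
  cat(sprintf(paste0("<cia_result> %.3g s arena run: %d NEAR / %d FAR of ",
                     "%d whisks, baseline %.1f deg\n"),
              x$duration, x$n_near, x$n_far, x$n_whisks, x$baseline))
  invisible(x)
}

#' Mean relative protraction in the lateral CIA bands
#'
#' Summarises a CIA map over the lateral wall-point bins (|y| between
#' `y_range` mm): `ipsi` is the mean relative angle for walls on the
#' measured side, `contra` for walls on the opposite side. Contact-induced
#' asymmetry is `ipsi < 0 < contra`.
#'
#' @param x A `cia_result`.
#' @param y_range Lateral band (mm).
#' @return A tibble with `ipsi` and `contra` means (deg).
#' @export
cia_lateral_bias <- function(x, y_range = c(10, 25)) {
  m <- x$map
  band <- function(sgn) {
    rows <- m$y * sgn >= y_range[1] & m$y * sgn <= y_range[2]
    sum(m$value[rows] * m$n[rows]) / sum(m$n[rows])
  }
  tibble(ipsi = band(1), contra = band(-1))
}

#' Spread-reduction experiment
#'
#' Wall-approach trials: the head controller is overridden so the fovea
#' moves in a straight line towards a wall angled at random within +/- 10
#' degrees of perpendicular, at a constant speed drawn uniformly from
#' `speed_range`; whisker control stays active. Each trial contributes two
#' potential side-samples. A side-sample is selected when no whisker on
#' that side contacts during the pre-contact whisk and at least two
#' whiskers contact during the first contact whisk (and pre, first and
#' second contact whisks all exist). The angular spread (measured angle of
#' the fifth-from-rear whisker minus the rearmost) is summarised within
#' each whisk by its minimum, mean and maximum, then averaged across
#' selected side-samples by whisk type.
#'
#' @param params A [sim_params()] object.
#' @param n_trials Number of trials (each yields two potential
#'   side-samples).
#' @param seed Integer seed.
#' @param angle `"shaft"` (measured angles) or `"base"` (bending control).
#' @param speed_range Approach speed range (mm/s).
#' @param wall_angle_range Wall angle range about perpendicular (deg).
#' @param start_dist Initial nose-wall distance (mm).
#' @param stop_dist Nose-wall distance at which a trial ends (mm).
#' @return An `sr_result` with `summary` (mean min/mean/max spread per
#'   whisk type), `n_selected`, `n_potential`, and the per-side-sample
#'   `samples` tibble.
#' @export
run_sr <- function(params = sim_params(), n_trials = 100, seed = 1L,
                   angle = c("shaft", "base"), speed_range = c(10, 50),
                   wall_angle_range = c(-10, 10), start_dist = 50,
                   stop_dist = 5) {
  angle <- match.arg(angle)
  prefix <- if (angle == "shaft") "theta_meas" else "theta_base"
  set.seed(seed)
  wall_angles <- runif(n_trials, wall_angle_range[1], wall_angle_range[2])
  speeds <- runif(n_trials, speed_range[1], speed_range[2])
  trial_seeds <- sample.int(.Machine$integer.max - 1, n_trials)
  rear_idx <- 1L
  front_idx <- 5L
  samples <- purrr::map_dfr(seq_len(n_trials), function(tr) {
    wall <- approach_wall(wall_angles[tr], distance = start_dist)
    a <- wall_angles[tr] * pi / 180
    dur <- (start_dist - stop_dist) / (speeds[tr] * cos(a))
    log <- run_simulation(params, obstacles = wall, duration = dur,
                          seed = trial_seeds[tr],
                          init_pose = head_pose(c(0, 0),
                                                c(-params$fovea_neck_sep, 0)),
                          head_override = list(dir = c(1, 0),
                                               speed = speeds[tr]),
                          log = "full")
    purrr::map_dfr(c("left", "right"), function(side) {
      sc <- substr(side, 1, 1)
      wk <- segment_whisks(log, side)
      sel_rows <- wk[wk$class %in% c("pre", "first", "second"), ]
      has_all <- all(c("pre", "first", "second") %in% sel_rows$class)
      ok <- FALSE
      if (has_all) {
        pre_ok <- !sel_rows$contact[sel_rows$class == "pre"]
        first_ok <- sel_rows$n_whiskers[sel_rows$class == "first"] >= 2
        ok <- pre_ok && first_ok
      }
      spread <- log[[paste0(prefix, "_", sc, front_idx)]] -
        log[[paste0(prefix, "_", sc, rear_idx)]]
      stats <- purrr::map_dfr(c("pre", "first", "second"), function(cl) {
        row <- sel_rows[sel_rows$class == cl, ]
        if (nrow(row) == 0) {
          return(tibble(whisk = cl, min_spread = NA_real_,
                        mean_spread = NA_real_, max_spread = NA_real_))
        }
        sp <- spread[row$start:row$end]
        tibble(whisk = cl, min_spread = min(sp), mean_spread = mean(sp),
               max_spread = max(sp))
      })
      dplyr::mutate(stats, trial = tr, side = side, selected = ok,
                    wall_angle = wall_angles[tr], speed = speeds[tr])
    })
  })
  sel <- dplyr::filter(samples, .data$selected)
  summary <- sel |>
    dplyr::group_by(.data$whisk) |>
    dplyr::summarise(min_spread = mean(.data$min_spread),
                     mean_spread = mean(.data$mean_spread),
                     max_spread = mean(.data$max_spread),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$whisk, c("pre", "first", "second")))
  structure(list(summary = summary,
                 n_selected = nrow(dplyr::distinct(sel, .data$trial,
                                                   .data$side)),
                 n_potential = 2L * n_trials,
                 samples = samples, params = params, seed = seed,
                 angle = angle),
            class = "sr_result")
}

#' @export
print.sr_result <- function(x, ...) {
  cat(sprintf("<sr_result> %d of %d side-samples selected\n",
              x$n_selected, x$n_potential))
  print(x$summary)
  invisible(x)
}
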