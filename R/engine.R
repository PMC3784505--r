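#' Run a closed-loop simulation
#'
#' Runs the full sensorimotor loop for `duration` seconds at the sample
#' rate in `params` and returns a per-sample log. Within each sample the
#' engine: advances the oscillator; resolves quasistatic whisker bending
#' and contact at the current angles and pose; deposits tactile (and, at
#' ticks, stochastic "other") input blobs and updates both excitation maps
#' with pose-compensating remapping and exponential decay; at ticks updates
#' the inhibition-of-return memory, re-selects the active channel and plans
#' a new minimum-jerk foveation towards the salience peak; recomputes
#' inhibition and salience (with the coloured noise perturbing the salience
#' readout) and the salience-to-protraction transform every sample; steps
#' the whisking dynamics; and finally advances the fovea along its plan,
#' dragging the neck behind it.
#'
#' All randomness (per-cell coloured noise in both channels and the
#' stochastic "other" target location) comes from internal streams derived
#' from `seed`, so a run is exactly reproducible.
#'
#' @param params A [sim_params()] object.
#' @param obstacles An obstacle tibble (or `NULL` for free space).
#' @param duration Simulated time (s).
#' @param seed Integer seed.
#' @param init_pose Initial [head_pose()]; defaults to the fovea at the
#'   origin facing +x.
#' @param head_override `NULL` for attention-driven head movement, or a
#'   list `list(dir = c(dx, dy), speed = v)` that instead moves the fovea
#'   in a straight line at constant speed (used by the wall-approach
#'   experiment); whisker control stays active.
#' @param flip_noise Mirror the noise streams and stochastic target
#'   locations about the head midline (used with a mirrored world to test
#'   mirror equivariance).
#' @param flip_attention Mirror the selected salience map left/right in the
#'   whisker-control pathway only (the manipulation that reverses the sense
#'   of the behavioural asymmetries).
#' @param log `"full"` for per-whisker columns, `"summary"` for per-side
#'   means only (much smaller; used for long runs).
#' @return A `sim_log` tibble with one row per sample: time, fovea/neck
#'   world positions, head bearing (deg), oscillator `tick` and drive `q`,
#'   selected `channel`, bending-solver `clamped` flag, current foveation
#'   target, salience `contrast`, per-side mean base and measured angles
#'   and contact counts, and (in full mode) per-whisker commanded base
#'   angles `theta_base_*`, measured shaft angles `theta_meas_*`, maximum
#'   protraction angles `theta_max_*`, contact signals `contact_*` and
#'   contact locations. Attributes: `params`, `obstacles`, `seed`,
#'   `fields` (final field matrices).
#' @examples
#' p <- sim_params()
#' log <- run_simulation(p, duration = 1, seed = 1)
#' nrow(log) # duration / sample_dt + 1 samples
#' @export
run_simulation <- function(params, obstacles = NULL, duration = 10,
                           seed = 1L, init_pose = NULL,
                           head_override = NULL, flip_noise = FALSE,
                           flip_attention = FALSE,
                           log = c("full", "summary")) {
  stopifnot(inherits(params, "sim_params"), duration > 0)
  log <- match.arg(log)
  if (is.null(init_pose)) {
    init_pose <- head_pose(c(0, 0), c(-params$fovea_neck_sep, 0))
  }
  if (is.null(obstacles)) obstacles <- obstacle(numeric(0), numeric(0),
                                                numeric(0), numeric(0))[0, ]
  morph <- build_morphology(params)
  grid <- field_grid(params)
  tables <- proposal_tables(morph, grid, params)
  head_mode <- 0L
  head_dir <- c(1, 0)
  head_speed <- 0
  if (!is.null(head_override)) {
    head_mode <- 1L
    head_dir <- head_override$dir / sqrt(sum(head_override$dir^2))
    head_speed <- head_override$speed
  }
  raw <- sim_run_cpp(unclass(params), whisker_matrix(morph),
                     obstacle_matrix(obstacles), tables$P, tables$W2,
                     duration, as.double(seed), pose_vec(init_pose),
                     head_mode, head_dir, head_speed, flip_noise,
                     flip_attention, if (log == "full") 0L else 1L)
  out <- as_tibble(raw$core)
  out$tick <- out$tick > 0
  out$clamped <- out$clamped > 0
  out$channel <- ifelse(out$channel == 0, "tactile", "other")
  if (log == "full") {
    lab <- whisker_labels(morph)
    add_block <- function(m, prefix) {
      colnames(m) <- paste0(prefix, "_", lab)
      as_tibble(m)
    }
    out <- dplyr::bind_cols(out,
                            add_block(raw$theta_base, "theta_base"),
                            add_block(raw$theta_meas, "theta_meas"),
                            add_block(raw$theta_max, "theta_max"),
                            add_block(raw$contact, "contact"),
                            add_block(raw$contact_x, "contact_x"),
                            add_block(raw$contact_y, "contact_y"))
  }
  attr(out, "params") <- params
  attr(out, "obstacles") <- obstacles
  attr(out, "seed") <- seed
  attr(out, "fields") <- raw$fields
  attr(out, "log_mode") <- log
  class(out) <- c("sim_log", class(out))
  out
}

#' @export
print.sim_log <- function(x, ...) {
  cat(sprintf("<sim_log> %d samples, %.3g s at dt = %.4g s, seed %s\n",
              nrow(x), max(x$t), attr(x, "params")$sample_dt,
              format(attr(x, "seed"))))
  NextMethod()
}

sides_cols <- function(log, prefix, side) {
  grep(sprintf("^%s_%s[0-9]+$", prefix, side), names(log), value = TRUE)
}

#' Segment a log into whisks
#'
#' A whisk is the interval between consecutive oscillator ticks (maximum
#' protraction at the interval end). A contact whisk contains at least one
#' sample with a nonzero contact signal on the given side; the first two
#' contact whisks of the log are labelled `"first"` and `"second"` and the
#' whisk immediately before the first is `"pre"`.
#'
#' @param log A full-mode `sim_log`.
#' @param side `"left"` or `"right"`.
#' @return A tibble with one row per whisk: `whisk`, sample index range
#'   `start`/`end`, `contact` (any contact on that side), `n_whiskers`
#'   (distinct whiskers contacting) and `class`
#'   (`"pre"`/`"first"`/`"second"`/`"other"`).
#' @export
segment_whisks <- function(log, side = c("left", "right")) {
  side <- match.arg(side)
  sc <- substr(side, 1, 1)
  ticks <- which(log$tick)
  if (length(ticks) < 2) {
    return(tibble(whisk = integer(), start = integer(), end = integer(),
                  contact = logical(), n_whiskers = integer(),
                  class = character()))
  }
  cmat <- as.matrix(log[sides_cols(log, "contact", sc)])
  out <- purrr::map_dfr(seq_len(length(ticks) - 1), function(k) {
    i0 <- ticks[k] + 1L
    i1 <- ticks[k + 1L]
    sub <- cmat[i0:i1, , drop = FALSE]
    tibble(whisk = k, start = i0, end = i1,
           contact = any(sub > 0),
           n_whiskers = sum(apply(sub > 0, 2, any)))
  })
  out$class <- "other"
  ci <- which(out$contact)
  if (length(ci) >= 1) {
    out$class[ci[1]] <- "first"
    if (ci[1] > 1) out$class[ci[1] - 1] <- "pre"
    if (length(ci) >= 2) out$class[ci[2]] <- "second"
  }
  out
}
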