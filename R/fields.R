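#' Head-centric field grid specification
#'
#' All attention maps live on a head-centric grid covering 80 mm
#' longitudinally (20 mm behind the fovea to 60 mm ahead) and 120 mm
#' laterally (+/- 60 mm), at `grid_resolution` cell size. Fields are plain
#' matrices with rows indexing x (longitudinal) and columns indexing y
#' (lateral, +y to the animal's left).
#'
#' @param params A [sim_params()] object (only `grid_resolution` is used).
#' @return A `field_grid` list with `res`, `nx`, `ny`, extent origin
#'   `x0`/`y0`, and cell-centre coordinate vectors `x`, `y`.
#' @export
field_grid <- function(params = sim_params()) {
  res <- params$grid_resolution
  nx <- round(80 / res)
  ny <- round(120 / res)
  structure(list(res = res, nx = nx, ny = ny, x0 = -20, y0 = -60,
                 x = -20 + (seq_len(nx) - 0.5) * res,
                 y = -60 + (seq_len(ny) - 0.5) * res),
            class = "field_grid")
}

#' @rdname field_grid
#' @param grid A `field_grid`.
#' @export
empty_field <- function(grid) {
  matrix(0, grid$nx, grid$ny)
}

#' Deposit Gaussian blobs into a field
#'
#' Each point adds `amplitude * exp(-r^2 / (2 sigma^2))` with
#' `sigma = width / 2`; the result is clipped to at most 1. Points outside
#' the grid extent are silently ignored.
#'
#' @param field Field matrix.
#' @param grid A [field_grid()].
#' @param points n-by-2 matrix of head-frame points (mm).
#' @param amplitudes Blob amplitudes, one per point.
#' @param width Blob width (mm), interpreted as two sigma.
#' @return The updated field matrix.
#' @export
deposit_blobs <- function(field, grid, points, amplitudes, width) {
  if (width <= 0) abort("width must be positive", class = "vibrisim_field_error")
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (nrow(points) == 0) return(field)
  out <- blob_field_cpp(field, grid$res, as.matrix(points),
                        as.numeric(amplitudes), width / 2, TRUE)
  pmin(out, 1)
}

#' Remap a field across a head movement
#'
#' Dynamic remapping compensates head movement: the value at head-frame
#' location x under the new pose estimates the value at the same world
#' location under the old pose (bilinear interpolation; world locations that
#' fall outside the old grid contribute zero).
#'
#' @param field Field matrix under `pose_old`.
#' @param grid A [field_grid()].
#' @param pose_old,pose_new [head_pose()] before and after the movement.
#' @return The remapped field matrix.
#' @export
remap_field <- function(field, grid, pose_old, pose_new) {
  warp_field_cpp(field, grid$res, pose_vec(pose_old), pose_vec(pose_new))
}

#' One excitation-map update
#'
#' The excitation map is a leaky max with memory: the previous state is
#' remapped across the head movement, decayed by `decay` (modelling the
#' resampling loss of repeated remapping), combined with the fresh input
#' map by an entry-wise maximum, perturbed by coloured noise, and clipped
#' to \[0, 1\]. In the simulation engine the stored state decays with
#' `excitation_decay` and carries no noise; the coloured noise instead
#' perturbs the salience readout each sample (see the methods vignette),
#' which is equivalent to calling this with `gain = 0` and adding
#' `gain * noise` when the map is read.
#'
#' @param E Excitation field matrix (previous sample).
#' @param I Input field matrix (this sample).
#' @param grid A [field_grid()].
#' @param pose_old,pose_new Poses at the previous and current sample.
#' @param noise Coloured-noise field (unit variance), same shape as `E`,
#'   or `NULL`.
#' @param gain Noise gain.
#' @param decay Retention factor applied to the remapped state.
#' @return The updated excitation field.
#' @export
update_excitation <- function(E, I, grid, pose_old, pose_new, noise = NULL,
                              gain = 0, decay = 1) {
  warped <- decay * remap_field(E, grid, pose_old, pose_new)
  out <- pmax(warped, I)
  if (!is.null(noise) && gain != 0) out <- out + gain * noise
  pmin(pmax(out, 0), 1)
}

#' Coloured excitation noise
#'
#' Per-cell independent first-order autoregressive Gaussian noise with unit
#' stationary variance: `n' = a n + sqrt(1 - a^2) z`,
#' `a = exp(-2 pi B dt)` for bandwidth `B`.
#'
#' @param state Noise field matrix (previous state), or `NULL` to draw a
#'   stationary initial state.
#' @param grid A [field_grid()].
#' @param params A [sim_params()] object (`noise_bandwidth`, `sample_dt`).
#' @return The updated noise field (unit variance; multiply by
#'   `noise_gain` before adding to an excitation map).
#' @export
noise_step <- function(state, grid, params) {
  z <- matrix(rnorm(grid$nx * grid$ny), grid$nx, grid$ny)
  if (is.null(state)) return(z)
  a <- exp(-2 * pi * params$noise_bandwidth * params$sample_dt)
  a * state + sqrt(1 - a^2) * z
}

#' Stochastic "other" input map
#'
#' At each oscillator tick a single random location, uniform over the grid
#' extent, contributes one Gaussian blob of width `other_blob_width` and
#' amplitude `other_gain`; between ticks the input map is empty.
#'
#' @param tick Logical; is this sample an oscillator tick?
#' @param grid A [field_grid()].
#' @param params A [sim_params()] object.
#' @return The input field matrix.
#' @export
other_input <- function(tick, grid, params) {
  f <- empty_field(grid)
  if (!tick) return(f)
  p <- c(grid$x0 + runif(1) * grid$nx * grid$res,
         grid$y0 + runif(1) * grid$ny * grid$res)
  deposit_blobs(f, grid, p, params$other_gain, params$other_blob_width)
}

#' Obstacle inhibition map
#'
#' Unity activity inside obstacles and in their shadow (cells whose line of
#' sight from the fovea crosses an obstacle interior), zero elsewhere.
#' Foveation targets inside or behind obstacles are thereby vetoed.
#'
#' @param grid A [field_grid()].
#' @param pose A [head_pose()].
#' @param obstacles An obstacle tibble.
#' @return A 0/1 field matrix.
#' @export
obstacle_inhibition <- function(grid, pose, obstacles) {
  if (is.null(obstacles) || nrow(obstacles) == 0) return(empty_field(grid))
  shadow_field_cpp(grid$res, pose_vec(pose), obstacle_matrix(obstacles))
}

#' Inhibition-of-return memory
#'
#' `ior_step()` is called at each oscillator tick: it records the current
#' fovea location (world frame) and forgets locations not visited for more
#' than `ior_memory` seconds. `ior_field()` renders the memory into the
#' head frame as a sum of Gaussian blobs (width `ior_width`, amplitude
#' `ior_gain` each); the cap `ior_max` is applied later by [inhibition()].
#'
#' @param mem A tibble with columns `x`, `y`, `t` (or `NULL` for an empty
#'   memory).
#' @param fovea Current fovea world position.
#' @param t Current time (s).
#' @param params A [sim_params()] object.
#' @return `ior_step()`: the updated memory tibble. `ior_field()`: a field
#'   matrix.
#' @export
ior_step <- function(mem, fovea, t, params) {
  if (is.null(mem)) mem <- tibble(x = numeric(), y = numeric(), t = numeric())
  now <- t
  mem <- dplyr::add_row(mem, x = fovea[1], y = fovea[2], t = now)
  dplyr::filter(mem, now - .data$t <= params$ior_memory)
}

#' @rdname ior_step
#' @param grid A [field_grid()].
#' @param pose A [head_pose()].
#' @export
ior_field <- function(mem, grid, pose, params) {
  if (is.null(mem) || nrow(mem) == 0) return(empty_field(grid))
  ior_field_cpp(grid$res, pose_vec(pose), cbind(mem$x, mem$y),
                params$ior_width / 2, params$ior_gain)
}

#' Combined inhibition map
#'
#' `H = min(1, H_obs + min(H_ior, ior_max))` entry-wise: obstacle
#' inhibition is absolute, IOR inhibition is capped at `ior_max`.
#'
#' @param H_obs Obstacle inhibition field.
#' @param H_ior IOR field.
#' @param params A [sim_params()] object.
#' @return The inhibition field.
#' @export
inhibition <- function(H_obs, H_ior, params) {
  pmin(H_obs + pmin(H_ior, params$ior_max), 1)
}

#' Salience map
#'
#' `S = E * (1 - H)` entry-wise (Hadamard product with the disinhibition).
#'
#' @param E Excitation field.
#' @param H Inhibition field.
#' @return The salience field.
#' @export
salience <- function(E, H) {
  E * (1 - H)
}

#' Select the active salience channel
#'
#' The channel whose map has the higher maximum wins; on an exact tie the
#' previous channel is retained (selection is only re-evaluated at
#' oscillator ticks, and held between them).
#'
#' @param S_tactile,S_other Salience field matrices.
#' @param previous Previously selected channel (`"tactile"` or `"other"`).
#' @return The selected channel name.
#' @export
select_channel <- function(S_tactile, S_other, previous = "other") {
  mt <- max(S_tactile)
  mo <- max(S_other)
  if (mt > mo) "tactile" else if (mo > mt) "other" else previous
}

#' Write a field as plain text
#'
#' One header line (`# t=<t> channel=<channel> frame=head x0=-20 y0=-60
#' res=<res>`) followed by the matrix, rows indexing x.
#'
#' @param field Field matrix.
#' @param path Output file.
#' @param t Sample time (s).
#' @param channel Channel label.
#' @param grid A [field_grid()].
#' @export
write_field_grid <- function(field, path, t = NA, channel = "", grid = field_grid()) {
  header <- sprintf("# t=%s channel=%s frame=head x0=%g y0=%g res=%g",
                    format(t), channel, grid$x0, grid$y0, grid$res)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(field, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
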