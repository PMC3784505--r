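#' Head pose
#'
#' The head is represented by the world positions of the fovea (snout tip)
#' and the neck joint; the head bearing is the direction from neck to fovea.
#'
#' @param fovea,neck Numeric `(x, y)` world positions in mm.
#' @return A `head_pose` object.
#' @examples
#' head_pose(c(50, 0), c(0, 0)) # facing +x
#' @export
head_pose <- function(fovea, neck) {
  stopifnot(is.numeric(fovea), length(fovea) == 2,
            is.numeric(neck), length(neck) == 2)
  if (all(abs(fovea - neck) < 1e-12)) {
    abort("fovea and neck positions coincide", class = "vibrisim_pose_error")
  }
  structure(list(fovea = as.numeric(fovea), neck = as.numeric(neck)),
            class = "head_pose")
}

pose_vec <- function(pose) c(pose$fovea, pose$neck)

#' @export
print.head_pose <- function(x, ...) {
  cat(sprintf("<head_pose> fovea (%.2f, %.2f) neck (%.2f, %.2f) bearing %.1f deg\n",
              x$fovea[1], x$fovea[2], x$neck[1], x$neck[2], bearing_deg(x)))
  invisible(x)
}

#' Head bearing in degrees
#'
#' @param pose A [head_pose()].
#' @return Bearing of the neck-to-fovea direction, degrees, counterclockwise
#'   from the world +x axis.
#' @export
bearing_deg <- function(pose) {
  d <- pose$fovea - pose$neck
  atan2(d[2], d[1]) * 180 / pi
}

#' Drag the neck behind a moving fovea
#'
#' The fovea is placed at `new_fovea` and the neck moves along the line from
#' its current position towards the new fovea so that the fovea-neck
#' separation is restored exactly.
#'
#' @param pose Current [head_pose()].
#' @param new_fovea New fovea world position.
#' @param sep Fovea-neck separation (mm).
#' @return Updated `head_pose`.
#' @export
step_neck <- function(pose, new_fovea, sep) {
  d <- pose$neck - new_fovea
  n <- sqrt(sum(d^2))
  if (n < 1e-12) {
    abort("new fovea position coincides with the neck",
          class = "vibrisim_pose_error")
  }
  head_pose(new_fovea, new_fovea + sep * d / n)
}

#' World / head-frame transform
#'
#' The head frame has its origin at the fovea, +x along the head bearing and
#' +y to the animal's left.
#'
#' @param pose A [head_pose()].
#' @return A list of two functions, `world_from_head(p)` and
#'   `head_from_world(p)`, each mapping an n-by-2 matrix (or length-2
#'   vector) of points.
#' @export
frame_transform <- function(pose) {
  d <- pose$fovea - pose$neck
  n <- sqrt(sum(d^2))
  cb <- d[1] / n
  sb <- d[2] / n
  fx <- pose$fovea[1]
  fy <- pose$fovea[2]
  as_mat <- function(p) {
    if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  }
  list(
    world_from_head = function(p) {
      p <- as_mat(p)
      cbind(fx + cb * p[, 1] - sb * p[, 2],
            fy + sb * p[, 1] + cb * p[, 2])
    },
    head_from_world = function(p) {
      p <- as_mat(p)
      dx <- p[, 1] - fx
      dy <- p[, 2] - fy
      cbind(cb * dx + sb * dy, -sb * dx + cb * dy)
    }
  )
}

# --------------------------------------------------------------------------
# Obstacles
# --------------------------------------------------------------------------

#' Oriented rectangular obstacles
#'
#' @param cx,cy Centre, world frame (mm).
#' @param width,height Full extents along the rectangle's local x and y
#'   axes (mm).
#' @param angle Orientation (deg, counterclockwise).
#' @return A tibble with one row per obstacle.
#' @export
obstacle <- function(cx, cy, width, height, angle = 0) {
  if (any(width <= 0) || any(height <= 0)) {
    abort("obstacle extents must be positive", class = "vibrisim_config_error")
  }
  tibble(cx = cx, cy = cy, width = width, height = height, angle = angle)
}

#' Four walls enclosing a square arena
#'
#' The arena interior is the square `[0, side] x [0, side]`; the four walls
#' are rectangles of the given thickness placed just outside it.
#'
#' @param side Interior side length (mm).
#' @param thickness Wall thickness (mm).
#' @return An obstacle tibble (4 rows: bottom, top, left, right).
#' @export
arena_obstacles <- function(side = 400, thickness = 20) {
  long <- side + 2 * thickness
  dplyr::bind_rows(
    obstacle(side / 2, -thickness / 2, long, thickness),
    obstacle(side / 2, side + thickness / 2, long, thickness),
    obstacle(-thickness / 2, side / 2, thickness, long),
    obstacle(side + thickness / 2, side / 2, thickness, long)
  )
}

#' Default starting pose in the arena
#'
#' Centred, facing +x.
#' @param side Arena side (mm).
#' @param sep Fovea-neck separation (mm).
#' @return A [head_pose()].
#' @export
arena_start_pose <- function(side = 400, sep = 50) {
  head_pose(c(side / 2, side / 2), c(side / 2 - sep, side / 2))
}

#' A single wall ahead of the animal, for approach trials
#'
#' The wall's inner face passes through the point `distance` mm ahead of the
#' origin on the +x axis and is rotated `angle` degrees away from
#' perpendicular to the approach direction.
#'
#' @param angle Deviation from perpendicular (deg).
#' @param distance Distance from the origin to the inner face (mm).
#' @param length Wall length (mm).
#' @param thickness Wall thickness (mm).
#' @return An obstacle tibble (1 row).
#' @export
approach_wall <- function(angle = 0, distance = 50, length = 400,
                          thickness = 20) {
  a <- angle * pi / 180
  obstacle(distance + (thickness / 2) * cos(a),
           (thickness / 2) * sin(a),
           width = thickness, height = length, angle = angle)
}

obstacle_matrix <- function(obstacles) {
  if (is.null(obstacles) || nrow(obstacles) == 0) {
    return(matrix(numeric(0), ncol = 5))
  }
  cbind(obstacles$cx, obstacles$cy, obstacles$width / 2,
        obstacles$height / 2, obstacles$angle * pi / 180)
}

obstacles_from_config <- function(lst) {
  dplyr::bind_rows(lapply(lst, function(o) {
    obstacle(o$cx_mm, o$cy_mm, o$width_mm, o$height_mm,
             if (is.null(o$angle_deg)) 0 else o$angle_deg)
  }))
}

obstacles_to_config <- function(obstacles) {
  lapply(seq_len(nrow(obstacles)), function(i) {
    list(cx_mm = obstacles$cx[i], cy_mm = obstacles$cy[i],
         width_mm = obstacles$width[i], height_mm = obstacles$height[i],
         angle_deg = obstacles$angle[i])
  })
}

#' Mirror obstacles about the world x axis
#'
#' @param obstacles An obstacle tibble.
#' @return The mirrored tibble (same row order).
#' @export
mirror_obstacles <- function(obstacles) {
  dplyr::mutate(obstacles, cy = -.data$cy, angle = -.data$angle)
}

#' Distance from points to each obstacle
#'
#' @param points n-by-2 matrix (or length-2 vector) of world points.
#' @param obstacles An obstacle tibble.
#' @return n-by-m matrix of distances (0 for points inside an obstacle).
#' @export
obstacle_distance <- function(points, obstacles) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  obstacle_distance_cpp(as.matrix(points), obstacle_matrix(obstacles))
}

nearest_obstacle_point <- function(points, obst_row) {
  # clamp the point into the rectangle's local frame
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  a <- obst_row$angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  dx <- points[, 1] - obst_row$cx
  dy <- points[, 2] - obst_row$cy
  qx <- pmin(pmax(ca * dx + sa * dy, -obst_row$width / 2), obst_row$width / 2)
  qy <- pmin(pmax(-sa * dx + ca * dy, -obst_row$height / 2), obst_row$height / 2)
  cbind(obst_row$cx + ca * qx - sa * qy,
        obst_row$cy + sa * qx + ca * qy)
}

# --------------------------------------------------------------------------
# Whisker morphology
# --------------------------------------------------------------------------

# mystacial pad arc: an ellipse in head frame with its rostral tip at the
# fovea, semi-axes 30 mm (longitudinal) x 12 mm (lateral); bases are evenly
# spaced in ellipse parameter between 75 deg (caudal) and 15 deg (rostral)
PAD_A <- 30
PAD_B <- 12
PAD_U <- c(75, 15)

#' Build the whisker array morphology
#'
#' Seven whiskers per side, mirror-symmetric about the head midline. Bases
#' lie on the mystacial pad arc (an ellipse along the snout outline with its
#' rostral tip at the fovea); lengths, rest curvatures, nominal protraction
#' angles and whisk amplitudes interpolate linearly from caudal (whisker 1)
#' to rostral.
#'
#' @param params A [sim_params()] object.
#' @return A tibble with one row per whisker: `side` ("left"/"right"),
#'   `index` (1 = most caudal), head-frame `base_x`, `base_y`,
#'   `base_tangent_deg` (local pad-arc tangent), `length`, `curvature`,
#'   `gain` (contact-signal gain), `theta_nom` and `amplitude`.
#' @export
build_morphology <- function(params) {
  n <- params$n_whiskers_per_side
  u <- seq(PAD_U[1], PAD_U[2], length.out = n) * pi / 180
  bx <- -PAD_A + PAD_A * cos(u)
  by <- PAD_B * sin(u)
  tangent <- atan2(PAD_B * cos(u), -PAD_A * sin(u)) * 180 / pi
  len <- per_whisker(params$whisker_length_range, n)
  kap <- per_whisker(params$whisker_curvature_range, n)
  nom <- per_whisker(params$theta_nom_range, n)
  amp <- per_whisker(params$amplitude_range, n)
  gain <- params$sensing_gain_scale * sqrt(len)
  left <- tibble(side = "left", index = seq_len(n), base_x = bx, base_y = by,
                 base_tangent_deg = tangent, length = len, curvature = kap,
                 gain = gain, theta_nom = nom, amplitude = amp)
  right <- dplyr::mutate(left, side = "right", base_y = -.data$base_y,
                         base_tangent_deg = -.data$base_tangent_deg)
  dplyr::bind_rows(left, right)
}

whisker_matrix <- function(morph) {
  cbind(ifelse(morph$side == "left", 1, -1), morph$base_x, morph$base_y,
        morph$length, morph$curvature, morph$gain, morph$theta_nom,
        morph$amplitude)
}

whisker_labels <- function(morph) {
  paste0(ifelse(morph$side == "left", "l", "r"), morph$index)
}

#' Constant-curvature whisker arc as a polyline
#'
#' The shaft leaves the base at the protraction angle (measured from the
#' caudal direction of the head midline, increasing rostrally) and follows a
#' circular arc of the given curvature; positive curvature bends the shaft
#' rostrally on either side.
#'
#' @param morph One row of [build_morphology()] (or a list with `side`,
#'   `base_x`, `base_y`, `length`).
#' @param base_angle Protraction angle at the base (deg).
#' @param curvature Arc curvature (1/mm); defaults to the rest curvature.
#' @param step Maximum vertex spacing (mm).
#' @return An n-by-2 matrix of head-frame vertices from base to tip.
#' @export
arc_polyline <- function(morph, base_angle, curvature = morph$curvature,
                         step = 1) {
  if (step <= 0) abort("step must be positive", class = "vibrisim_geom_error")
  side <- if (morph$side == "left") 1L else -1L
  arc_points_cpp(morph$base_x, morph$base_y, side, base_angle, curvature,
                 morph$length, step)
}

#' Resolve quasistatic whisker bending against obstacles
#'
#' Each whisker's curvature is adjusted increasingly caudally (by bisection
#' on a caudal curvature offset) until the shaft just clears every obstacle.
#' The contact signal saturates the bending deviation `delta`, measured at
#' arc length `deformation_dist` from the base, through
#' `tanh(gain * delta)`.
#'
#' @param morph Whisker morphology tibble ([build_morphology()]), or a
#'   subset of its rows.
#' @param base_angles Protraction angles (deg), one per row of `morph`.
#' @param pose A [head_pose()].
#' @param obstacles An obstacle tibble (may be empty).
#' @param params A [sim_params()] object.
#' @return A tibble with per-whisker `kappa_p` (perturbed curvature),
#'   `delta` (mm), `contact_signal` in \[0, 1\], `contact` (logical),
#'   world-frame `contact_x`, `contact_y` (NA when no contact), `clamped`
#'   (deep-penetration flag) and `theta_meas` (measured shaft angle, deg).
#' @export
resolve_bending <- function(morph, base_angles, pose, obstacles, params) {
  m <- bend_whiskers_cpp(whisker_matrix(morph), base_angles, pose_vec(pose),
                         obstacle_matrix(obstacles), params$deformation_dist)
  out <- as_tibble(m)
  out$contact <- out$contact > 0
  out$clamped <- out$clamped > 0
  out$contact_x[!out$contact] <- NA_real_
  out$contact_y[!out$contact] <- NA_real_
  dplyr::bind_cols(morph[, c("side", "index")], out)
}

#' Measured whisker shaft angle
#'
#' The protraction angle recovered the way video tracking does it: the angle
#' between the head midline and the chord from the whisker base to the point
#' two thirds of the way along the (possibly bent) shaft. For a circular
#' arc this is the base angle plus `curvature * length / 3` radians.
#'
#' @param base_angle Base protraction angle (deg).
#' @param curvature Shaft curvature (1/mm), perturbed if bent.
#' @param length Whisker length (mm).
#' @return Measured angle (deg).
#' @export
measured_angle <- function(base_angle, curvature, length) {
  base_angle + (curvature * length / 3) * 180 / pi
}
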