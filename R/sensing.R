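# Ray geometry shared by the proximity sensors and the camera. Reference
# implementation in plain R; the compiled trial loop repeats the same
# arithmetic and the two are property-tested for agreement.

# First non-negative ray parameter at which origin + t*(dx,dy) meets the
# circle centred at (cx,cy) (relative to the origin) of radius r; -1 on miss.
# An origin inside the circle reports t = 0 (contact).
rayCircleR <- function(cx, cy, r, dx, dy) {
  b <- cx * dx + cy * dy
  c2 <- cx * cx + cy * cy
  disc <- b * b - c2 + r * r
  if (disc < 0) return(-1)
  t <- b - sqrt(disc)
  if (t >= 0) return(t)
  if (c2 < r * r) return(0)
  -1
}

# Distance from (x, y) to the nearest arena wall along (dx, dy).
rayWallR <- function(x, y, dx, dy, config) {
  t <- Inf
  if (dx > 0) t <- min(t, (config$arena_width - x) / dx)
  else if (dx < 0) t <- min(t, -x / dx)
  if (dy > 0) t <- min(t, (config$arena_height - y) / dy)
  else if (dy < 0) t <- min(t, -y / dy)
  t
}

# Obstacle circles seen by robot `ri` (1 or 2): the other robot first
# (type 1 = hunter), then the prey (2 = boar, 3 = stag).
obstacleCircles <- function(world, ri, config) {
  oi <- 3L - ri
  list(cx = c(world$rx[oi], world$px) - world$rx[ri],
       cy = c(world$ry[oi], world$py) - world$ry[ri],
       r = c(config$robot_radius, rep(config$prey_radius, length(world$px))),
       type = c(1L, 2L + world$kind))
}

#' Proximity-sensor activations
#'
#' Casts the 12 proximity rays of one robot: rays at 30-degree increments
#' starting at the heading, each with a fixed range (40 units by default),
#' measuring the distance from the body surface to the nearest obstacle
#' (wall, prey, or the other robot) along the ray. Activation is
#' `1 - d/range`: 1 when the body is directly in contact with the obstacle,
#' 0 when nothing lies within the range.
#'
#' @param world A `WorldState`.
#' @param robot Robot index, 1 (hunter A) or 2 (hunter B).
#' @param config A [worldConfig()].
#' @return Numeric vector of 12 activations in \[0,1\].
#' @export
castProximity <- function(world, robot, config) {
  x <- world$rx[robot]; y <- world$ry[robot]; th <- world$rth[robot]
  cth <- cos(th); sth <- sin(th)
  obs <- obstacleCircles(world, robot, config)
  out <- numeric(12)
  for (k in 0:11) {
    a <- k * 30 * pi / 180
    ox <- cos(a); oy <- sin(a)
    dx <- cth * ox - sth * oy
    dy <- sth * ox + cth * oy
    t <- rayWallR(x, y, dx, dy, config)
    for (j in seq_along(obs$r)) {
      reach <- config$prox_range + config$robot_radius + obs$r[j]
      if (obs$cx[j]^2 + obs$cy[j]^2 > reach^2) next
      tc <- rayCircleR(obs$cx[j], obs$cy[j], obs$r[j], dx, dy)
      if (tc >= 0 && tc < t) t <- tc
    }
    d <- max(t - config$robot_radius, 0)
    out[k + 1] <- if (d <= config$prox_range) 1 - d / config$prox_range else 0
  }
  out
}

#' Typed camera rays
#'
#' Casts the 12 camera rays of one robot: the 90-degree field of view is
#' divided into 12 equal 7.5-degree sectors spanning heading +/- 45 degrees,
#' with one ray at each sector centre. Each ray reports the nearest agent it
#' intersects — the other hunter, a boar, or a stag; walls are invisible to
#' the camera — as a two-bit type code (none 00, hunter 01, boar 10, stag 11)
#' plus a proximity `1 - d/D` where `d` is the distance from the robot centre
#' to the agent surface and `D` the arena diagonal. The camera range is
#' unlimited within the arena; the nearer of two agents on the same ray
#' occludes the farther.
#'
#' @inheritParams castProximity
#' @return A 12 x 3 matrix with columns `b1`, `b2` (type bits) and
#'   `proximity`; all-zero rows are empty rays.
#' @export
castCamera <- function(world, robot, config) {
  x <- world$rx[robot]; y <- world$ry[robot]; th <- world$rth[robot]
  cth <- cos(th); sth <- sin(th)
  diag <- sqrt(config$arena_width^2 + config$arena_height^2)
  obs <- obstacleCircles(world, robot, config)
  out <- matrix(0, 12, 3, dimnames = list(NULL, c("b1", "b2", "proximity")))
  for (k in 0:11) {
    a <- (-45 + 3.75 + 7.5 * k) * pi / 180
    ox <- cos(a); oy <- sin(a)
    dx <- cth * ox - sth * oy
    dy <- sth * ox + cth * oy
    best <- Inf; type <- 0L
    for (j in seq_along(obs$r)) {
      tc <- rayCircleR(obs$cx[j], obs$cy[j], obs$r[j], dx, dy)
      if (tc >= 0 && tc < best) { best <- tc; type <- obs$type[j] }
    }
    if (type > 0L) {
      out[k + 1, 1] <- bitwAnd(bitwShiftR(type, 1L), 1L)
      out[k + 1, 2] <- bitwAnd(type, 1L)
      out[k + 1, 3] <- max(1 - best / diag, 0)
    }
  }
  out
}

#' Assemble a sensor frame
#'
#' @inheritParams castProximity
#' @return An object of class `SensorFrame`: `proximity` (12 activations),
#'   `camera` (12 x 3 matrix) and `bias` (always 1).
#' @export
senseRobot <- function(world, robot, config) {
  structure(list(proximity = castProximity(world, robot, config),
                 camera = castCamera(world, robot, config),
                 bias = 1),
            class = "SensorFrame")
}

#' Encode a sensor frame as the 49 controller inputs
#'
#' Concatenates the 12 proximity activations, the 12 camera rays (each as
#' type bit 1, type bit 2, proximity), and the constant bias input, in that
#' order: 12 + 36 + 1 = 49 activations.
#'
#' @param frame A `SensorFrame` from [senseRobot()].
#' @return Numeric vector of length 49; element 49 is always 1.
#' @export
encodeInputs <- function(frame) {
  if (!inherits(frame, "SensorFrame") ||
      length(frame$proximity) != 12 ||
      !is.matrix(frame$camera) || !all(dim(frame$camera) == c(12, 3)))
    stop("malformed sensor frame", call. = FALSE)
  c(frame$proximity, as.vector(t(frame$camera)), 1)
}
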