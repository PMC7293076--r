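#' @useDynLib staghunt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rbinom sd median quantile pnorm setNames
#' @importFrom utils combn head read.table write.table packageVersion
NULL

PREY_KINDS <- c("boar", "stag")

#' Initialize a hunting-trial world
#'
#' Places the two hunters next to each other at the top of the arena (facing
#' into it) and scatters `n_boars + n_stags` immobile prey uniformly at
#' random, keeping every prey disc fully inside the walls. All capture
#' counters start at zero.
#'
#' Coordinates: origin at the bottom-left corner, x rightward, y upward,
#' headings in radians counter-clockwise from +x. The "top of the arena" is
#' the max-y edge; both robots start at height `arena_height - 2 *
#' robot_radius`, offset symmetrically about the vertical midline, heading
#' `-pi/2`.
#'
#' @param config A [worldConfig()] object.
#' @param seed Optional integer seed (calls `set.seed()` before drawing prey
#'   positions).
#' @return An object of class `WorldState`: robot poses, prey table, capture
#'   counters, contact-streak bookkeeping, the simulation clock, accumulated
#'   rewards and the capture-event log.
#' @examples
#' w <- initWorld(worldConfig(), seed = 1)
#' w
#' @export
initWorld <- function(config, seed = NULL) {
  validateWorldConfig(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_boars + config$n_stags
  px <- numeric(n); py <- numeric(n)
  for (i in seq_len(n)) {
    px[i] <- config$prey_radius + runif(1) * (config$arena_width  - 2 * config$prey_radius)
    py[i] <- config$prey_radius + runif(1) * (config$arena_height - 2 * config$prey_radius)
  }
  structure(list(
    rx = c(config$arena_width / 2 - 1.5 * config$robot_radius,
           config$arena_width / 2 + 1.5 * config$robot_radius),
    ry = rep(config$arena_height - 2 * config$robot_radius, 2),
    rth = rep(-pi / 2, 2),
    px = px, py = py,
    kind = as.integer(c(rep(0L, config$n_boars), rep(1L, config$n_stags))),
    counter = integer(n),
    streak_a = rep(-1L, n), streak_b = rep(-1L, n),
    step = 0L,
    rewards = c(A = 0, B = 0),
    ev_step = integer(0), ev_kind = integer(0),
    ev_coop = integer(0), ev_first = integer(0),
    touches = integer(4)), class = "WorldState")
}

#' @export
print.WorldState <- function(x, ...) {
  cat(sprintf("<WorldState> step %d, %d prey (%d boar/%d stag), rewards A = %g B = %g, %d capture event(s)\n",
              x$step, length(x$px), sum(x$kind == 0L), sum(x$kind == 1L),
              x$rewards[1], x$rewards[2], length(x$ev_step)))
  invisible(x)
}

#' Capture-event log of a world state or trial result
#'
#' @param x A `WorldState` or `TrialResult`.
#' @return A data frame with one row per resolved capture: `step`, `prey`
#'   (`"boar"` or `"stag"`), `cooperative`, and `first_arriver` (`"A"` or
#'   `"B"`, the hunter whose unbroken contact streak with the prey began
#'   earliest; ties go to A).
#' @export
captureEvents <- function(x) {
  data.frame(step = as.integer(x$ev_step),
             prey = PREY_KINDS[x$ev_kind + 1L],
             cooperative = as.logical(x$ev_coop),
             first_arriver = c("A", "B")[x$ev_first + 1L],
             stringsAsFactors = FALSE)
}

clamp01 <- function(v, what = "wheel commands") {
  if (any(v < 0 | v > 1)) {
    warning(what, " outside [0, 1] clamped", call. = FALSE)
    v <- pmin(pmax(v, 0), 1)
  }
  v
}

#' Construct a robot pose
#'
#' @param x,y Position of the body centre.
#' @param heading Heading in radians, counter-clockwise from +x.
#' @param id `"A"` or `"B"`.
#' @return An object of class `RobotState`.
#' @export
robotState <- function(x, y, heading, id = "A") {
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 heading = as.numeric(heading), id = match.arg(id, c("A", "B"))),
            class = "RobotState")
}

#' Apply wheel commands to one robot (differential-drive kinematics)
#'
#' Each wheel command c in \[0,1\] maps linearly to a wheel velocity
#' (2c - 1) * `wheel_speed_max`: minimal activity is full backward, maximal
#' is full forward, 0.5 is standstill. The body advances by the mean wheel
#' velocity along the current heading, then the heading changes by
#' (v_right - v_left) / `axle_length`. The position is clamped so the body
#' stays fully inside the walls. Commands outside \[0,1\] are clamped with a
#' warning.
#'
#' @param robot A [robotState()].
#' @param commands Length-2 numeric, left and right wheel commands in \[0,1\].
#' @param config A [worldConfig()].
#' @return The updated `RobotState`.
#' @examples
#' r <- robotState(400, 400, 0)
#' actuate(r, c(1, 1), worldConfig())$x - r$x   # full speed ahead
#' @export
actuate <- function(robot, commands, config) {
  commands <- clamp01(as.numeric(commands))
  stopifnot(length(commands) == 2)
  vl <- (2 * commands[1] - 1) * config$wheel_speed_max
  vr <- (2 * commands[2] - 1) * config$wheel_speed_max
  lin <- 0.5 * (vl + vr)
  r <- config$robot_radius
  robot$x <- min(max(robot$x + lin * cos(robot$heading), r), config$arena_width - r)
  robot$y <- min(max(robot$y + lin * sin(robot$heading), r), config$arena_height - r)
  robot$heading <- robot$heading + (vr - vl) / config$axle_length
  if (robot$heading > pi) robot$heading <- robot$heading - 2 * pi
  else if (robot$heading < -pi) robot$heading <- robot$heading + 2 * pi
  robot
}

# Symmetric minimal push-apart of the two (mutually solid) robot bodies,
# re-clamped to the walls afterwards.
pushApart <- function(world, config) {
  dx <- world$rx[2] - world$rx[1]
  dy <- world$ry[2] - world$ry[1]
  d2 <- dx * dx + dy * dy
  lim <- 2 * config$robot_radius
  if (d2 >= lim * lim) return(world)
  d <- sqrt(d2)
  if (d < 1e-9) { ux <- 1; uy <- 0; d <- 0 } else { ux <- dx / d; uy <- dy / d }
  half <- 0.5 * (lim - d)
  r <- config$robot_radius
  world$rx[1] <- min(max(world$rx[1] - half * ux, r), config$arena_width - r)
  world$ry[1] <- min(max(world$ry[1] - half * uy, r), config$arena_height - r)
  world$rx[2] <- min(max(world$rx[2] + half * ux, r), config$arena_width - r)
  world$ry[2] <- min(max(world$ry[2] + half * uy, r), config$arena_height - r)
  world
}

#' Update capture counters and resolve timed captures
#'
#' For every prey: if at least one hunter body overlaps the prey disc this
#' step the capture counter increments, otherwise it resets to zero. When the
#' counter reaches `capture_steps` the prey resolves: if both hunters are in
#' contact at that step the capture is cooperative and each hunter gains the
#' prey's cooperative payoff; otherwise it is a solo capture paying the
#' `solo` reward to the lone hunter. The resolved prey is removed and
#' respawned immediately at a uniform-random position (prey density is
#' constant), and a capture event is logged with the first arriver: the
#' hunter whose current unbroken contact streak began earlier (ties go to A).
#'
#' @param world A `WorldState`.
#' @param payoffs A [payoffScheme()].
#' @param config A [worldConfig()].
#' @return The updated `WorldState`.
#' @export
updateCaptures <- function(world, payoffs, config) {
  lim2 <- (config$robot_radius + config$prey_radius)^2
  for (i in seq_along(world$px)) {
    cA <- (world$rx[1] - world$px[i])^2 + (world$ry[1] - world$py[i])^2 <= lim2
    cB <- (world$rx[2] - world$px[i])^2 + (world$ry[2] - world$py[i])^2 <= lim2
    if (cA) {
      if (world$streak_a[i] < 0L) {
        world$streak_a[i] <- world$step
        ti <- 1L + 2L * world$kind[i]
        world$touches[ti] <- world$touches[ti] + 1L
      }
    } else world$streak_a[i] <- -1L
    if (cB) {
      if (world$streak_b[i] < 0L) {
        world$streak_b[i] <- world$step
        ti <- 2L + 2L * world$kind[i]
        world$touches[ti] <- world$touches[ti] + 1L
      }
    } else world$streak_b[i] <- -1L
    world$counter[i] <- if (cA || cB) world$counter[i] + 1L else 0L
    if (world$counter[i] >= config$capture_steps) {
      coop <- cA && cB
      first <- if (coop) {
        if (world$streak_a[i] <= world$streak_b[i]) 0L else 1L
      } else if (cA) 0L else 1L
      if (coop) {
        pay <- if (world$kind[i] == 0L) payoffs$boar_coop else payoffs$stag_coop
        world$rewards <- world$rewards + pay
      } else {
        world$rewards[first + 1L] <- world$rewards[first + 1L] + payoffs$solo
      }
      world$ev_step <- c(world$ev_step, world$step)
      world$ev_kind <- c(world$ev_kind, world$kind[i])
      world$ev_coop <- c(world$ev_coop, as.integer(coop))
      world$ev_first <- c(world$ev_first, first)
      world$px[i] <- config$prey_radius + runif(1) * (config$arena_width  - 2 * config$prey_radius)
      world$py[i] <- config$prey_radius + runif(1) * (config$arena_height - 2 * config$prey_radius)
      world$counter[i] <- 0L
      world$streak_a[i] <- -1L
      world$streak_b[i] <- -1L
    }
  }
  world
}

#' Advance the world by one time step
#'
#' Both robots are actuated simultaneously from the pre-step state, overlap
#' between the two bodies is resolved by a symmetric minimal push-apart,
#' captures are updated, and the clock advances. This is the readable
#' reference implementation; [runTrial()] runs the same update in compiled
#' code.
#'
#' @param world A `WorldState`.
#' @param commandsA,commandsB Length-2 wheel commands in \[0,1\] for hunters
#'   A and B.
#' @param config A [worldConfig()].
#' @param payoffs A [payoffScheme()].
#' @return The updated `WorldState`.
#' @export
stepWorld <- function(world, commandsA, commandsB, config,
                      payoffs = payoffScheme()) {
  if (world$step >= config$trial_steps)
    stop("cannot step a finished trial (step ", world$step, " of ",
         config$trial_steps, ")", call. = FALSE)
  commandsA <- clamp01(as.numeric(commandsA))
  commandsB <- clamp01(as.numeric(commandsB))
  for (ri in 1:2) {
    cmd <- if (ri == 1) commandsA else commandsB
    vl <- (2 * cmd[1] - 1) * config$wheel_speed_max
    vr <- (2 * cmd[2] - 1) * config$wheel_speed_max
    lin <- 0.5 * (vl + vr)
    r <- config$robot_radius
    world$rx[ri] <- min(max(world$rx[ri] + lin * cos(world$rth[ri]), r),
                        config$arena_width - r)
    world$ry[ri] <- min(max(world$ry[ri] + lin * sin(world$rth[ri]), r),
                        config$arena_height - r)
    world$rth[ri] <- world$rth[ri] + (vr - vl) / config$axle_length
    if (world$rth[ri] > pi) world$rth[ri] <- world$rth[ri] - 2 * pi
    else if (world$rth[ri] < -pi) world$rth[ri] <- world$rth[ri] + 2 * pi
  }
  world <- pushApart(world, config)
  world <- updateCaptures(world, payoffs, config)
  world$step <- world$step + 1L
  world
}
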