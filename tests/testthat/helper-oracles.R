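# Independent brute-force oracles and scene builders shared across tests.

# A bare WorldState with hand-set robot poses and prey (no RNG).
sceneWorld <- function(config, rx, ry, rth, px = numeric(0), py = numeric(0),
                       kind = integer(0), counter = integer(length(px))) {
  w <- initWorld(config, seed = 1)
  w$rx <- as.numeric(rx); w$ry <- as.numeric(ry); w$rth <- as.numeric(rth)
  w$px <- as.numeric(px); w$py <- as.numeric(py)
  w$kind <- as.integer(kind)
  w$counter <- as.integer(counter)
  n <- length(px)
  w$streak_a <- rep(-1L, n); w$streak_b <- rep(-1L, n)
  w
}

# Random scene for sensing property tests: both robots and a few prey at
# uniform positions (bodies inside the walls), random headings.
randomScene <- function(config, n_prey = 3) {
  rr <- config$robot_radius
  w <- sceneWorld(config,
                  rx = runif(2, rr, config$arena_width - rr),
                  ry = runif(2, rr, config$arena_height - rr),
                  rth = runif(2, -pi, pi),
                  px = runif(n_prey, 0, config$arena_width),
                  py = runif(n_prey, 0, config$arena_height),
                  kind = sample(0:1, n_prey, replace = TRUE))
  # keep the two robot bodies from overlapping (the simulator never
  # produces overlapping bodies, so sensors need not handle that case)
  while (sum((w$rx[1] - w$rx[2])^2 + (w$ry[1] - w$ry[2])^2) < (2 * rr)^2) {
    w$rx[2] <- runif(1, rr, config$arena_width - rr)
    w$ry[2] <- runif(1, rr, config$arena_height - rr)
  }
  w
}

# Brute-force ray march from `origin` along `dir`: the first sampled
# parameter t (step `eps`) at which the point lies inside any obstacle
# circle or beyond a wall. Overestimates the true distance by < eps.
bruteRayDistance <- function(world, config, robot, dir, maxd, eps,
                             walls = TRUE, circles = NULL) {
  ox <- world$rx[robot]; oy <- world$ry[robot]
  t <- seq(0, maxd, by = eps)
  x <- ox + t * dir[1]; y <- oy + t * dir[2]
  inside <- rep(FALSE, length(t))
  if (walls)
    inside <- x < 0 | x > config$arena_width | y < 0 | y > config$arena_height
  if (is.null(circles)) {
    oi <- 3 - robot
    circles <- list(cx = c(world$rx[oi], world$px),
                    cy = c(world$ry[oi], world$py),
                    r = c(config$robot_radius,
                          rep(config$prey_radius, length(world$px))),
                    type = c(1L, 2L + world$kind))
  }
  hit_type <- 0L
  first_circle <- Inf
  for (j in seq_along(circles$r)) {
    d2 <- (x - circles$cx[j])^2 + (y - circles$cy[j])^2
    hit <- which(d2 <= circles$r[j]^2)
    if (length(hit) && t[hit[1]] < first_circle) {
      first_circle <- t[hit[1]]
      hit_type <- circles$type[j]
    }
  }
  first_wall <- if (any(inside)) t[which(inside)[1]] else Inf
  if (first_circle <= first_wall) list(t = first_circle, type = hit_type)
  else list(t = first_wall, type = -1L)
}

# Unit direction of proximity ray k (1..12) for a robot heading.
proxRayDir <- function(heading, k) {
  a <- heading + (k - 1) * 30 * pi / 180
  c(cos(a), sin(a))
}

# Unit direction of camera ray k (1..12).
camRayDir <- function(heading, k) {
  a <- heading + (-45 + 3.75 + (k - 1) * 7.5) * pi / 180
  c(cos(a), sin(a))
}

# Independent Mann-Whitney U: count of (a, b) pairs with a > b, plus half
# the ties -- deliberately not the rank formulation used by the package.
bruteU <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact one-tailed p by enumeration of all group labelings.
bruteExactP <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  idx <- combn(length(pooled), m)
  u_obs <- bruteU(a, b)
  us <- apply(idx, 2, function(i) bruteU(pooled[i], pooled[-i]))
  mean(us >= u_obs - 1e-9)
}
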