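test_that("initWorld places robots and prey per configuration", {
  cfg <- worldConfig()
  w <- initWorld(cfg, seed = 11)
  expect_equal(length(w$px), 2L)          # simple environment: 1 boar + 1 stag
  expect_equal(sum(w$kind == 0L), 1L)
  expect_equal(sum(w$kind == 1L), 1L)
  # robots adjacent at the top edge midline, facing into the arena
  expect_equal(w$ry, rep(800 - 2 * cfg$robot_radius, 2))
  expect_equal(w$rx, c(400 - 15, 400 + 15))
  expect_equal(w$rth, rep(-pi / 2, 2))
  expect_true(all(w$counter == 0L) && all(w$rewards == 0))

  w9 <- initWorld(worldConfig(n_boars = 9, n_stags = 9), seed = 2)
  expect_equal(length(w9$px), 18L)        # complex environment: 9 + 9
  expect_equal(sum(w9$kind == 0L), 9L)
  # prey discs fully inside the walls
  expect_true(all(w9$px >= 20 & w9$px <= 780))
  expect_true(all(w9$py >= 20 & w9$py <= 780))

  expect_identical(initWorld(cfg, seed = 5), initWorld(cfg, seed = 5))
  expect_error(worldConfig(arena_width = 30), "arena")
  expect_error(worldConfig(n_boars = 0), "> 0")
})

test_that("actuate implements differential-drive kinematics", {
  cfg <- worldConfig()
  r <- robotState(400, 400, 0.7)
  # midpoint commands map to zero wheel velocity
  expect_equal(actuate(r, c(0.5, 0.5), cfg)[c("x", "y", "heading")],
               r[c("x", "y", "heading")])
  # symmetric maximal forward: straight-line advance of wheel_speed_max
  r2 <- actuate(r, c(1, 1), cfg)
  expect_equal(r2$x, r$x + 2 * cos(0.7))
  expect_equal(r2$y, r$y + 2 * sin(0.7))
  expect_equal(r2$heading, r$heading)
  # opposite extremes: in-place arc with heading change -2*vmax/axle
  r3 <- actuate(r, c(1, 0), cfg)
  expect_equal(c(r3$x, r3$y), c(r$x, r$y))
  expect_equal(r3$heading, 0.7 - 2 * 2 / 20)
  # general commands against a fine-step numerical integration of the
  # continuous differential-drive kinematics (one Euler step discretizes
  # the arc, so the position tolerance scales with the turn magnitude)
  for (cmd in list(c(0.9, 0.6), c(0.2, 0.8), c(0, 1))) {
    vl <- (2 * cmd[1] - 1) * 2; vr <- (2 * cmd[2] - 1) * 2
    nsub <- 4000
    x <- r$x; y <- r$y; th <- r$heading
    for (i in seq_len(nsub)) {
      x <- x + (vl + vr) / 2 / nsub * cos(th)
      y <- y + (vl + vr) / 2 / nsub * sin(th)
      th <- th + (vr - vl) / 20 / nsub
    }
    got <- actuate(r, cmd, cfg)
    expect_equal(got$heading, th, tolerance = 1e-9)
    expect_lt(sqrt((got$x - x)^2 + (got$y - y)^2),
              abs(vr - vl) / 20 * 2 + 1e-9)
  }
  # out-of-range commands are clamped with a warning
  expect_warning(r4 <- actuate(r, c(1.4, -2), cfg), "clamped")
  expect_equal(r4$heading, r3$heading)
  # wall clamping keeps the body inside
  edge <- robotState(cfg$arena_width - cfg$robot_radius, 400, 0)
  expect_equal(actuate(edge, c(1, 1), cfg)$x, cfg$arena_width - cfg$robot_radius)
})

test_that("updateCaptures implements the timed capture/payoff rule", {
  cfg <- worldConfig()
  pay <- payoffScheme()
  onPrey <- function(kind, both, counter, streak_a = 0L, streak_b = 0L) {
    w <- sceneWorld(cfg, rx = c(400, if (both) 420 else 100),
                    ry = c(400, 400), rth = c(0, 0),
                    px = 415, py = 400, kind = kind, counter = counter)
    w$step <- 1000L
    w$streak_a <- streak_a; w$streak_b <- streak_b
    w
  }
  # both hunters on a stag at the resolving step: +250 each, cooperative
  w <- updateCaptures(onPrey(1L, both = TRUE, counter = 799L), pay, cfg)
  expect_equal(unname(w$rewards), c(250, 250))
  expect_equal(w$ev_coop, 1L)
  expect_false(w$px == 415 && w$py == 400)  # respawned elsewhere (a.s.)
  expect_equal(w$counter, 0L)
  # one hunter alone on a boar for the full count: 0 payoff, still an event
  w <- updateCaptures(onPrey(0L, both = FALSE, counter = 799L), pay, cfg)
  expect_equal(unname(w$rewards), c(0, 0))
  expect_equal(w$ev_kind, 0L)
  expect_equal(w$ev_coop, 0L)
  expect_equal(w$ev_first, 0L)
  # contact broken just before the count completes: counter resets, no event
  w0 <- onPrey(0L, both = FALSE, counter = 799L)
  w0$rx[1] <- 100  # nobody in contact this step
  w <- updateCaptures(w0, pay, cfg)
  expect_equal(w$counter, 0L)
  expect_length(w$ev_step, 0)
  # degenerate limit: capture_steps = 1 resolves on the first contact step
  cfg1 <- worldConfig(capture_steps = 1)
  w <- updateCaptures(onPrey(1L, both = TRUE, counter = 0L,
                             streak_a = -1L, streak_b = -1L), pay, cfg1)
  expect_equal(unname(w$rewards), c(250, 250))
  # first arriver is the hunter whose contact streak began earlier; tie -> A
  w <- updateCaptures(onPrey(1L, both = TRUE, counter = 799L,
                             streak_a = 500L, streak_b = 400L), pay, cfg)
  expect_equal(w$ev_first, 1L)  # B arrived first
  w <- updateCaptures(onPrey(1L, both = TRUE, counter = 799L,
                             streak_a = 400L, streak_b = 400L), pay, cfg)
  expect_equal(w$ev_first, 0L)  # tie -> A
})

test_that("world invariants hold under random stepping", {
  cfg <- worldConfig(trial_steps = 400L)
  pay <- payoffScheme()
  set.seed(99)
  w <- initWorld(cfg)
  n0 <- length(w$px)
  rew_prev <- w$rewards
  for (s in 1:400) {
    w <- stepWorld(w, runif(2), runif(2), cfg, pay)
    expect_length(w$px, n0)  # prey density constant (respawn-on-capture)
    dr <- sum(w$rewards - rew_prev)
    if (dr != 0) expect_true(dr %in% c(2 * 125, 2 * 250))
    rew_prev <- w$rewards
  }
  expect_true(all(w$rx >= 10 & w$rx <= 790 & w$ry >= 10 & w$ry <= 790))
  expect_equal(w$step, 400L)
  expect_error(stepWorld(w, c(.5, .5), c(.5, .5), cfg, pay), "finished")
})

test_that("stepWorld with idle commands only advances the clock", {
  cfg <- worldConfig()
  w <- sceneWorld(cfg, rx = c(200, 600), ry = c(200, 600), rth = c(0, 1),
                  px = 400, py = 400, kind = 0L)
  w2 <- stepWorld(w, c(0.5, 0.5), c(0.5, 0.5), cfg, payoffScheme())
  expect_equal(w2$step, w$step + 1L)
  w2$step <- w$step
  expect_identical(w2, w)
})
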