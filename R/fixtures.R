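# Hand-built test fixtures: a deterministic world scene, and hand-wired
# perceptron controllers (a boar hunter and a leader/follower pair) used as
# cheap stand-ins for pre-evolved genotypes in screens and drift protocols.

# Gene index of the weight from input i (1..49) to hidden unit j (1..8).
gIH <- function(i, j) (i - 1L) * 8L + j
# Gene index of the weight from hidden unit h (1..9, 9 = bias) to output o.
gHO <- function(h, o) 392L + (h - 1L) * 2L + o
# Input indices: proximity ray k is k; camera ray k contributes three
# consecutive inputs starting at camB1(k); input 49 is the bias.
camB1 <- function(k) 12L + 3L * (k - 1L) + 1L
camB2 <- function(k) camB1(k) + 1L
camPx <- function(k) camB1(k) + 2L

# A steer-and-park boar-hunting controller. Hidden units:
#   h1  boar in the left camera half  -> turn left
#   h2  boar in the right camera half -> turn right
#   h3  boar dead ahead and touching  -> cancel the drive (park on it)
#   h4, h5 (follower variant) hunter left / right -> weak following pull
# Camera rays 1..6 lie right of the heading, 7..12 left; the type-bit
# score b1 - b2 is +1 for a boar, 0 for a stag, -1 for a hunter (b2 - b1
# scores hunters for the following pull). The park detector combines the
# front proximity ray (touch), the two central camera rays' type bits (it
# is a boar, not a wall or the partner), and their camera proximities (it
# is the close agent, not a distant sighting past a nearer touch). Output
# biases give a gentle roaming arc that sweeps the camera across the whole
# arena when nothing is in view.
steerParkWeights <- function(turn_gain = 2.5, detect_gain = 8,
                             bias_l = 2.2, bias_r = 1.2,
                             park_prox = 20, park_bits = 6, park_cam = 30,
                             park_threshold = 88, follow_gain = 0) {
  w <- numeric(GENOME_LENGTH)
  detect <- function(hidden, rays, b1, b2) {
    for (k in rays) {
      w[gIH(camB1(k), hidden)] <<- b1
      w[gIH(camB2(k), hidden)] <<- b2
    }
    w[gIH(49L, hidden)] <<- -detect_gain / 2
  }
  detect(1L, 7:12, detect_gain, -detect_gain)   # h1: boar left
  detect(2L, 1:6, detect_gain, -detect_gain)    # h2: boar right
  w[gIH(1L, 3L)] <- park_prox                   # h3: touching, boar centred
  for (k in 6:7) {
    w[gIH(camB1(k), 3L)] <- park_bits
    w[gIH(camB2(k), 3L)] <- -park_bits
    w[gIH(camPx(k), 3L)] <- park_cam
  }
  w[gIH(49L, 3L)] <- -park_threshold
  # outputs: roam biases, differential turn, park cancellation
  w[gHO(9L, 1L)] <- bias_l
  w[gHO(9L, 2L)] <- bias_r
  w[gHO(1L, 1L)] <- -turn_gain; w[gHO(1L, 2L)] <- turn_gain   # boar left
  w[gHO(2L, 1L)] <- turn_gain;  w[gHO(2L, 2L)] <- -turn_gain  # boar right
  w[gHO(3L, 1L)] <- -bias_l;    w[gHO(3L, 2L)] <- -bias_r     # park
  if (follow_gain > 0) {
    detect(4L, 7:12, -detect_gain, detect_gain) # h4: hunter left
    detect(5L, 1:6, -detect_gain, detect_gain)  # h5: hunter right
    w[gHO(4L, 1L)] <- -follow_gain; w[gHO(4L, 2L)] <- follow_gain
    w[gHO(5L, 1L)] <- follow_gain;  w[gHO(5L, 2L)] <- -follow_gain
  }
  w
}

boarHunterWeights <- function() steerParkWeights()
# The follower hunts boars too, but a weak attraction towards the other
# hunter makes it tail the leader and park on the prey the leader chose.
followerWeights <- function() steerParkWeights(follow_gain = 1.2)

#' Hand-built test fixtures
#'
#' Three deterministic fixtures used throughout the test suite and the
#' screening protocols:
#' \describe{
#'   \item{world_scene}{a fixed, seed-independent scene (two robots, one
#'     boar, one stag at hand-placed positions) for sensing and capture
#'     tests; returns a list with `world` and `config`.}
#'   \item{boar_hunter_stub}{a hand-wired controller genome that steers
#'     towards the nearest boar seen by the camera and parks on it — a
#'     cheap, deterministic stand-in for a pre-evolved boar-hunting
#'     genotype.}
#'   \item{dual_network_stub}{a genome with two distinct hand-wired
#'     networks: a boar-hunting leader and a hunter-following follower,
#'     exercising the role-asymmetry machinery.}
#' }
#'
#' @param kind Fixture name.
#' @return See the descriptions above; the stubs are [genome()]s.
#' @examples
#' makeFixture("dual_network_stub")
#' @export
makeFixture <- function(kind = c("world_scene", "boar_hunter_stub",
                                 "dual_network_stub")) {
  kind <- match.arg(kind)
  switch(kind,
    world_scene = {
      config <- worldConfig(trial_steps = 1000L)
      world <- initWorld(config, seed = 1)
      # overwrite the random placements with a hand-built scene
      world$rx <- c(400, 200)
      world$ry <- c(400, 600)
      world$rth <- c(0, pi / 2)
      world$px <- c(455, 600)   # boar ahead of robot A, inside sensor range
      world$py <- c(400, 200)
      world$kind <- c(0L, 1L)
      list(world = world, config = config)
    },
    boar_hunter_stub = genome(boarHunterWeights(), lineage_id = "boar_stub"),
    dual_network_stub = genome(list(boarHunterWeights(), followerWeights()),
                               lineage_id = "dual_stub"))
}
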