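#' Payoff scheme for the stag-hunt capture rule
#'
#' Rewards paid to each hunter when a prey is captured cooperatively, by prey
#' type, and the payoff of a solo capture. Defaults follow the canonical
#' stag-hunt payoff matrix used throughout the package: 125 per hunter for a
#' cooperatively captured boar, 250 for a stag, and 0 for hunting alone.
#'
#' @param boar_coop Reward units each hunter receives for a cooperative boar
#'   capture.
#' @param stag_coop Reward units each hunter receives for a cooperative stag
#'   capture.
#' @param solo Reward units for a solo capture (paid to the lone hunter).
#' @return An object of class `PayoffScheme`.
#' @examples
#' payoffScheme()                 # regular payoffs
#' payoffScheme(stag_coop = 0)   # pre-evolution payoffs: stags yield nothing
#' @export
payoffScheme <- function(boar_coop = 125, stag_coop = 250, solo = 0) {
  stopifnot(is.numeric(boar_coop), is.numeric(stag_coop), is.numeric(solo))
  if (boar_coop < 0 || stag_coop < 0 || solo < 0)
    stop("payoffs must be non-negative", call. = FALSE)
  structure(list(boar_coop = as.numeric(boar_coop),
                 stag_coop = as.numeric(stag_coop),
                 solo = as.numeric(solo)),
            class = "PayoffScheme")
}

#' Arena and trial configuration
#'
#' Geometry and timing of one hunting trial: an `arena_width` by
#' `arena_height` arena with four solid walls, a fixed census of immobile
#' boars and stags (captured prey respawn immediately at a random position so
#' prey density stays constant), and the timed capture rule: a prey resolves
#' after `capture_steps` consecutive time steps with at least one hunter in
#' body contact, and the capture is cooperative only if both hunters are in
#' contact at the resolving step.
#'
#' Robot bodies and prey are discs; "contact" means overlap of the two discs.
#' The body radius, prey radius, axle length and wheel speed are not part of
#' the game definition and are free parameters of the embodiment; the
#' defaults are chosen so that the 40-unit proximity-sensor range spans about
#' two body diameters and a robot can cross the arena many times per trial.
#'
#' @param arena_width,arena_height Arena dimensions in length units.
#' @param n_boars,n_stags Number of boars / stags present at all times.
#' @param trial_steps Number of time steps per trial.
#' @param capture_steps Consecutive contact steps required to resolve a prey.
#' @param robot_radius,prey_radius Body radii in length units.
#' @param wheel_speed_max Maximal wheel velocity magnitude, length units per
#'   step; a wheel command c in \[0,1\] maps to velocity (2c-1) times this.
#' @param axle_length Distance between the two wheels; defaults to the robot
#'   body diameter.
#' @param prox_range Range of the proximity sensors in length units.
#' @return An object of class `WorldConfig`.
#' @examples
#' worldConfig()                          # simple environment: 1 boar, 1 stag
#' worldConfig(n_boars = 9, n_stags = 9)  # complex environment
#' @export
worldConfig <- function(arena_width = 800, arena_height = 800,
                        n_boars = 1, n_stags = 1,
                        trial_steps = 20000, capture_steps = 800,
                        robot_radius = 10, prey_radius = 20,
                        wheel_speed_max = 2,
                        axle_length = 2 * robot_radius,
                        prox_range = 40) {
  cfg <- structure(list(arena_width = as.numeric(arena_width),
                        arena_height = as.numeric(arena_height),
                        n_boars = as.integer(n_boars),
                        n_stags = as.integer(n_stags),
                        trial_steps = as.integer(trial_steps),
                        capture_steps = as.integer(capture_steps),
                        robot_radius = as.numeric(robot_radius),
                        prey_radius = as.numeric(prey_radius),
                        wheel_speed_max = as.numeric(wheel_speed_max),
                        axle_length = as.numeric(axle_length),
                        prox_range = as.numeric(prox_range)),
                   class = "WorldConfig")
  validateWorldConfig(cfg)
  cfg
}

validateWorldConfig <- function(cfg) {
  counts <- c(n_boars = cfg$n_boars, n_stags = cfg$n_stags,
              trial_steps = cfg$trial_steps, capture_steps = cfg$capture_steps)
  bad <- names(counts)[counts <= 0]
  if (length(bad))
    stop("world configuration: ", paste(bad, collapse = ", "),
         " must be > 0", call. = FALSE)
  if (cfg$robot_radius <= 0 || cfg$prey_radius <= 0)
    stop("world configuration: radii must be > 0", call. = FALSE)
  if (cfg$arena_width <= 4 * cfg$robot_radius ||
      cfg$arena_height <= 4 * cfg$robot_radius)
    stop("world configuration: arena dimensions must exceed 4 x robot_radius",
         call. = FALSE)
  if (cfg$arena_width <= 2 * cfg$prey_radius ||
      cfg$arena_height <= 2 * cfg$prey_radius)
    stop("world configuration: arena too small to place a prey disc",
         call. = FALSE)
  if (cfg$wheel_speed_max <= 0 || cfg$axle_length <= 0 || cfg$prox_range <= 0)
    stop("world configuration: wheel_speed_max, axle_length and prox_range must be > 0",
         call. = FALSE)
  invisible(cfg)
}

#' Mutation and network-duplication configuration
#'
#' Gaussian mutation: each gene independently receives additive noise of
#' standard deviation `sd` with probability `per_gene_prob`. When duplication
#' is enabled, a single-network genome gains an identical second network copy
#' with probability `duplication_prob` per generation, and a dual-network
#' genome loses a uniformly chosen copy with probability `deletion_prob`.
#'
#' @param per_gene_prob Per-gene mutation probability (default 5e-3).
#' @param sd Standard deviation of the Gaussian mutation operator (default 0.2).
#' @param duplication_prob Per-generation probability of network duplication.
#' @param deletion_prob Per-generation probability of network deletion.
#' @param duplication_enabled Whether the duplication/deletion operator runs
#'   at all; disabled by default and switched on only in the asymmetric
#'   (division-of-labor) treatment.
#' @return An object of class `MutationConfig`.
#' @export
mutationConfig <- function(per_gene_prob = 5e-3, sd = 2e-1,
                           duplication_prob = 5e-2, deletion_prob = 5e-3,
                           duplication_enabled = FALSE) {
  probs <- c(per_gene_prob = per_gene_prob, duplication_prob = duplication_prob,
             deletion_prob = deletion_prob)
  if (any(probs < 0 | probs > 1))
    stop("mutation configuration: probabilities must lie in [0, 1]",
         call. = FALSE)
  if (sd <= 0)
    stop("mutation configuration: sd must be > 0", call. = FALSE)
  structure(list(per_gene_prob = as.numeric(per_gene_prob),
                 sd = as.numeric(sd),
                 duplication_prob = as.numeric(duplication_prob),
                 deletion_prob = as.numeric(deletion_prob),
                 duplication_enabled = isTRUE(duplication_enabled)),
            class = "MutationConfig")
}

#' Evolutionary algorithm configuration
#'
#' A population of `population_size` genomes is evaluated socially: each
#' focal individual is paired with `n_partners` distinct random partners and
#' plays `trials_per_pair` independent trials with each, its fitness being
#' the mean of its own cumulative reward across those trials. Selection is
#' either elitist (the best `n_elites` individuals survive unchanged and the
#' rest are mutants of uniformly chosen elites) or Wright-Fisher
#' (fitness-proportionate resampling of the whole population).
#'
#' @param population_size Number of individuals (default 20).
#' @param n_elites Number of elites kept under the elitist scheme (default 10).
#' @param n_partners Distinct evaluation partners per focal individual.
#' @param trials_per_pair Independent trials per pairing.
#' @param scheme `"elitist"` or `"wright_fisher"`.
#' @param mutation A [mutationConfig()] object.
#' @param eval_seed Optional integer; when set, every generation is evaluated
#'   with this fixed seed (frozen evaluation: identical pairings and world
#'   seeds each generation, making elite fitness deterministic). Default
#'   `NULL` draws fresh evaluation randomness each generation.
#' @return An object of class `EvolutionConfig`.
#' @export
evolutionConfig <- function(population_size = 20, n_elites = 10,
                            n_partners = 5, trials_per_pair = 5,
                            scheme = c("elitist", "wright_fisher"),
                            mutation = mutationConfig(),
                            eval_seed = NULL) {
  scheme <- match.arg(scheme)
  population_size <- as.integer(population_size)
  n_elites <- as.integer(n_elites)
  n_partners <- as.integer(n_partners)
  trials_per_pair <- as.integer(trials_per_pair)
  if (population_size < 2)
    stop("evolution configuration: population_size must be >= 2", call. = FALSE)
  if (scheme == "elitist" && (n_elites < 1 || n_elites >= population_size))
    stop("evolution configuration: n_elites must satisfy 1 <= n_elites < population_size",
         call. = FALSE)
  if (n_partners < 1 || n_partners >= population_size)
    stop("evolution configuration: n_partners must satisfy 1 <= n_partners < population_size",
         call. = FALSE)
  if (trials_per_pair < 1)
    stop("evolution configuration: trials_per_pair must be >= 1", call. = FALSE)
  stopifnot(inherits(mutation, "MutationConfig"))
  if (!is.null(eval_seed)) eval_seed <- as.integer(eval_seed)
  structure(list(population_size = population_size, n_elites = n_elites,
                 n_partners = n_partners, trials_per_pair = trials_per_pair,
                 scheme = scheme, mutation = mutation, eval_seed = eval_seed),
            class = "EvolutionConfig")
}

# Flat named list consumed by the C++ core.
cppConfig <- function(world, payoffs) {
  c(unclass(world), unclass(payoffs))
}

#' @export
print.WorldConfig <- function(x, ...) {
  cat(sprintf("<WorldConfig> %gx%g arena, %d boar(s) + %d stag(s), %d steps/trial, capture after %d contact steps\n",
              x$arena_width, x$arena_height, x$n_boars, x$n_stags,
              x$trial_steps, x$capture_steps))
  invisible(x)
}

#' @export
print.PayoffScheme <- function(x, ...) {
  cat(sprintf("<PayoffScheme> boar %g / stag %g / solo %g\n",
              x$boar_coop, x$stag_coop, x$solo))
  invisible(x)
}

#' @export
print.EvolutionConfig <- function(x, ...) {
  cat(sprintf("<EvolutionConfig> %s, pop %d (k = %d), %d partners x %d trials, mutation p = %g sd = %g, duplication %s\n",
              x$scheme, x$population_size, x$n_elites, x$n_partners,
              x$trials_per_pair, x$mutation$per_gene_prob, x$mutation$sd,
              if (x$mutation$duplication_enabled) "on" else "off"))
  invisible(x)
}
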