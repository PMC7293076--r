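#' Run one hunting trial
#'
#' Deterministic given (genomes, configuration, seed): the world is
#' initialized, network copies are assigned ([assignRoles()]), and for
#' `trial_steps` steps each robot senses the pre-step world, maps the 49
#' activations through its expressed perceptron, and the world advances
#' synchronously. The caller's random-number stream is left untouched; all
#' trial randomness (prey placement, respawns, role coin) derives from
#' `seed`.
#'
#' @param genome_A,genome_B [genome()]s for hunters A and B.
#' @param world A [worldConfig()].
#' @param payoffs A [payoffScheme()].
#' @param seed Integer trial seed.
#' @param recordTrajectory If `TRUE`, also return a `trial_steps` x 6 matrix
#'   of per-step robot poses (xA, yA, headingA, xB, yB, headingB).
#' @return An object of class `TrialResult`: `rewards` (per-hunter cumulative
#'   reward), `events` (capture-event data frame, see [captureEvents()]),
#'   `touches` (2 x 2 matrix of contact-streak onsets by robot and prey
#'   type), `steps_run`, `roles` (expressed copy per robot), and optionally
#'   `trajectory`.
#' @examples
#' stub <- makeFixture("boar_hunter_stub")
#' r <- runTrial(stub, stub, worldConfig(trial_steps = 5000), payoffScheme(),
#'               seed = 7)
#' r$rewards
#' @export
runTrial <- function(genome_A, genome_B, world, payoffs, seed,
                     recordTrajectory = FALSE) {
  stopifnot(inherits(genome_A, "Genome"), inherits(genome_B, "Genome"))
  validateWorldConfig(world)
  keep <- get0(".Random.seed", globalenv())
  on.exit(restoreRNG(keep), add = TRUE)
  set.seed(as.integer(seed))
  roles <- assignRoles(genome_A, genome_B)
  res <- cppRunTrial(genome_A$networks[[roles[1]]],
                     genome_B$networks[[roles[2]]],
                     cppConfig(world, payoffs), recordTrajectory)
  out <- list(rewards = c(A = res$rewards[1], B = res$rewards[2]),
              events = captureEvents(res),
              touches = matrix(res$touches, nrow = 2,
                               dimnames = list(c("A", "B"), PREY_KINDS)),
              steps_run = res$steps_run,
              roles = roles,
              seed = as.integer(seed))
  if (recordTrajectory) out$trajectory <- res$trajectory
  structure(out, class = "TrialResult")
}

#' @export
print.TrialResult <- function(x, ...) {
  cat(sprintf("<TrialResult> %d steps, rewards A = %g B = %g, %d capture(s) (%d cooperative)\n",
              x$steps_run, x$rewards[1], x$rewards[2], nrow(x$events),
              sum(x$events$cooperative)))
  invisible(x)
}

#' Define one evolutionary phase
#'
#' @param generations Number of generations in this phase.
#' @param world A [worldConfig()].
#' @param payoffs A [payoffScheme()] (use `payoffScheme(stag_coop = 0)` for
#'   boar-hunter pre-evolution).
#' @param evolution An [evolutionConfig()].
#' @return An object of class `Phase`.
#' @export
phase <- function(generations, world, payoffs, evolution) {
  stopifnot(inherits(world, "WorldConfig"), inherits(payoffs, "PayoffScheme"),
            inherits(evolution, "EvolutionConfig"))
  generations <- as.integer(generations)
  if (generations < 0) stop("generations must be >= 0", call. = FALSE)
  structure(list(generations = generations, world = world, payoffs = payoffs,
                 evolution = evolution), class = "Phase")
}

#' Define a multi-phase replicate protocol
#'
#' A protocol is an ordered list of phases executed on a single population
#' (carried across phase boundaries), a replicate count, and a base seed
#' from which each replicate derives its own independent seed
#' (`bitwXor(base_seed, replicate_index)`).
#'
#' @param phases List of [phase()] objects (at least one with
#'   `generations > 0`).
#' @param n_replicates Number of independent replicates.
#' @param base_seed Integer base seed.
#' @param initial_population Optional list of [genome()]s seeding every
#'   replicate (e.g. clonal seeding with a pre-evolved genotype); default
#'   `NULL` initializes genes uniformly in \[0, 1\].
#' @return An object of class `Protocol`.
#' @export
protocol <- function(phases, n_replicates = 30, base_seed = 1,
                     initial_population = NULL) {
  if (inherits(phases, "Phase")) phases <- list(phases)
  stopifnot(length(phases) >= 1, all(vapply(phases, inherits, TRUE, "Phase")))
  if (sum(vapply(phases, `[[`, 1L, "generations")) < 1)
    stop("protocol must contain at least one generation", call. = FALSE)
  if (!is.null(initial_population))
    stopifnot(all(vapply(initial_population, inherits, TRUE, "Genome")))
  structure(list(phases = phases, n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 initial_population = initial_population),
            class = "Protocol")
}

#' @export
print.Protocol <- function(x, ...) {
  gens <- vapply(x$phases, `[[`, 1L, "generations")
  cat(sprintf("<Protocol> %d phase(s) (%s generations), %d replicate(s), base seed %d%s\n",
              length(x$phases), paste(gens, collapse = " + "),
              x$n_replicates, x$base_seed,
              if (is.null(x$initial_population)) "" else ", seeded population"))
  invisible(x)
}

#' Run one replicate of a protocol
#'
#' Executes the protocol's phases in order on a single population,
#' deterministic given `base_seed` and `replicate_index`. Each generation is
#' evaluated ([evaluatePopulation()]), summarized, and stepped with the
#' phase's selection scheme. The per-generation record tracks the best and
#' mean fitness, the best individual's capture-type breakdown (from its own
#' evaluation trials), and the census of one- vs two-network genomes.
#'
#' @param protocol A [protocol()].
#' @param replicate_index 1-based replicate number.
#' @return An object of class `ReplicateHistory`: `records` (one data-frame
#'   row per generation), `final_population`, `replicate`, `seed`.
#' @export
runReplicate <- function(protocol, replicate_index = 1) {
  seed <- bitwXor(protocol$base_seed, as.integer(replicate_index))
  set.seed(seed)
  pop <- if (is.null(protocol$initial_population)) {
    n <- protocol$phases[[1]]$evolution$population_size
    initPopulation(n, prefix = sprintf("r%d.g", replicate_index))
  } else protocol$initial_population
  rows <- vector("list", sum(vapply(protocol$phases, `[[`, 1L, "generations")))
  gen <- 0L
  for (pi in seq_along(protocol$phases)) {
    ph <- protocol$phases[[pi]]
    if (length(pop) != ph$evolution$population_size)
      stop("population size does not match phase ", pi, " configuration",
           call. = FALSE)
    for (g in seq_len(ph$generations)) {
      gen <- gen + 1L
      ev <- evaluatePopulation(pop, ph$world, ph$payoffs, ph$evolution)
      best <- which.max(ev$fitness)  # ties -> lowest index
      bd <- ev$breakdown[best, ]
      rows[[gen]] <- data.frame(
        generation = gen, phase = pi,
        best_fitness = ev$fitness[best], mean_fitness = mean(ev$fitness),
        best_boar_solo = bd[["boar_solo"]], best_boar_coop = bd[["boar_coop"]],
        best_stag_solo = bd[["stag_solo"]], best_stag_coop = bd[["stag_coop"]],
        best_coop_first_A = bd[["coop_first_A"]], best_events = bd[["events"]],
        n_dual = sum(vapply(pop, function(g) length(g$networks), 1L) == 2L))
      pop <- switch(ph$evolution$scheme,
                    elitist = elitistStep(pop, ev$fitness, ph$evolution),
                    wright_fisher = wrightFisherStep(pop, ev$fitness, ph$evolution))
    }
  }
  structure(list(records = do.call(rbind, rows), final_population = pop,
                 replicate = as.integer(replicate_index), seed = seed),
            class = "ReplicateHistory")
}

#' @export
print.ReplicateHistory <- function(x, ...) {
  last <- x$records[nrow(x$records), ]
  cat(sprintf("<ReplicateHistory> replicate %d: %d generation(s), final best fitness %.1f, final best capture mix b%d/B%d/s%d/S%d (solo/coop)\n",
              x$replicate, nrow(x$records), last$best_fitness,
              last$best_boar_solo, last$best_boar_coop,
              last$best_stag_solo, last$best_stag_coop))
  invisible(x)
}

#' Run all replicates of a protocol
#'
#' Replicates are mutually independent: each derives its seed as
#' `bitwXor(base_seed, replicate_index)`, so re-running any subset (in any
#' order) reproduces identical histories.
#'
#' @param protocol A [protocol()].
#' @param n_replicates Number of replicates; defaults to the protocol's.
#' @return A list of [runReplicate()] histories.
#' @export
runStudy <- function(protocol, n_replicates = protocol$n_replicates) {
  lapply(seq_len(n_replicates), function(i) runReplicate(protocol, i))
}

#' Ready-made study protocols
#'
#' The four study designs, at two problem scales:
#' \describe{
#'   \item{simple}{1 boar + 1 stag; boar-hunter pre-evolution (stag reward 0)
#'     followed by evolution with regular payoffs under elitist (10+10)
#'     selection.}
#'   \item{complex}{as `simple` but with 9 boars and 9 stags.}
#'   \item{complex-asym}{as `complex`, with the network-duplication operator
#'     enabled.}
#'   \item{wright-fisher}{single phase with regular payoffs under
#'     fitness-proportionate selection; meant to be seeded via
#'     `initial_population` with a pre-evolved boar-hunting genotype.}
#' }
#'
#' The `"paper"` scale uses 20,000-step trials, 5 partners x 5 trials,
#' 3000 + 6000 generations (12,000 for Wright-Fisher) and 30 replicates.
#' The `"desk"` scale keeps the model identical but shrinks the compute
#' budget so a study runs on one desktop core in minutes, trading
#' statistical power for turnaround; per condition:
#' \itemize{
#'   \item simple: 300 + 500 generations, 4000-step trials, 2 partners x
#'     2 trials, 5 replicates;
#'   \item complex / complex-asym: 100 + 150 generations, 2000-step trials,
#'     2 partners x 1 trial, 5 replicates (the richer prey field makes
#'     encounters much more frequent, so shorter trials still allow several
#'     captures);
#'   \item wright-fisher: 2000 generations (drift needs generations more
#'     than it needs evaluation precision), 2000-step trials, 1 partner x
#'     1 trial, 5 replicates.
#' }
#'
#' At paper scale populations start from random genomes (genes uniform in
#' \[0, 1\]) and pre-evolution has the budget to discover hunting from
#' scratch. The desk budget cannot: tens of specific weight changes separate
#' a random saturated controller from any capture-capable one, and with no
#' fitness gradient until the first cooperative capture the bootstrap phase
#' alone would consume far more than the whole desk budget. Desk-scale
#' presets therefore seed every replicate clonally with the hand-wired
#' boar-hunter stub (the dual leader/follower stub for `complex-asym`,
#' whose asymmetric pre-evolution reliably produces two-network
#' individuals), so that pre-evolution starts from an established
#' boar-hunting equilibrium and the study measures what the full-scale
#' design measures: whether stag hunting can invade it.
#'
#' @param name One of `"simple"`, `"complex"`, `"complex-asym"`,
#'   `"wright-fisher"`.
#' @param scale `"desk"` (default) or `"paper"`.
#' @param base_seed Integer base seed.
#' @param initial_population Optional seeding population (see [protocol()]);
#'   overrides the desk-scale stub seeding.
#' @return A [protocol()].
#' @examples
#' protocolPreset("simple", scale = "desk")
#' @export
protocolPreset <- function(name = c("simple", "complex", "complex-asym",
                                    "wright-fisher"),
                           scale = c("desk", "paper"), base_seed = 1,
                           initial_population = NULL) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  desk <- scale == "desk"
  nrep <- if (desk) 5L else 30L
  if (desk && is.null(initial_population)) {
    seed_stub <- makeFixture(if (name == "complex-asym") "dual_network_stub"
                             else "boar_hunter_stub")
    initial_population <- rep(list(seed_stub), 20L)
  }
  if (name == "wright-fisher") {
    wf_world <- worldConfig(trial_steps = if (desk) 2000L else 20000L)
    wf_evo <- evolutionConfig(n_partners = if (desk) 1L else 5L,
                              trials_per_pair = if (desk) 1L else 5L,
                              scheme = "wright_fisher")
    return(protocol(phase(if (desk) 2000L else 12000L, wf_world,
                          payoffScheme(), wf_evo),
                    n_replicates = if (desk) 5L else 12L,
                    base_seed = base_seed,
                    initial_population = initial_population))
  }
  simple <- name == "simple"
  n_prey <- if (simple) 1L else 9L
  dup <- name == "complex-asym"
  steps <- if (!desk) 20000L else if (simple) 4000L else 2000L
  wcfg <- worldConfig(n_boars = n_prey, n_stags = n_prey, trial_steps = steps)
  ecfg <- evolutionConfig(
    n_partners = if (desk) 2L else 5L,
    trials_per_pair = if (!desk) 5L else if (simple) 2L else 1L,
    scheme = "elitist",
    mutation = mutationConfig(duplication_enabled = dup))
  pre_gens <- if (!desk) 3000L else if (simple) 300L else 100L
  post_gens <- if (!desk) 6000L else if (simple) 500L else 150L
  protocol(list(phase(pre_gens, wcfg, payoffScheme(stag_coop = 0), ecfg),
                phase(post_gens, wcfg, payoffScheme(), ecfg)),
           n_replicates = nrep, base_seed = base_seed,
           initial_population = initial_population)
}
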