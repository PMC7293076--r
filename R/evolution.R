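#' Initialize a random population
#'
#' Every gene is initialized with a random value sampled uniformly in
#' \[0, 1\]; all individuals start with a single network. A `centered`
#' alternative (uniform on \[-0.5, 0.5\]) is available for sensitivity
#' checks but is not the default.
#'
#' @param n Population size.
#' @param init `"uniform01"` (default) or `"centered"`.
#' @param prefix Lineage-id prefix.
#' @return A list of [genome()]s.
#' @export
initPopulation <- function(n, init = c("uniform01", "centered"), prefix = "g") {
  init <- match.arg(init)
  lapply(seq_len(n), function(i) {
    v <- runif(GENOME_LENGTH)
    if (init == "centered") v <- v - 0.5
    genome(v, lineage_id = paste0(prefix, i))
  })
}

#' Gaussian mutation operator
#'
#' Each gene of every network in the genome independently receives, with
#' probability `cfg$per_gene_prob`, additive Gaussian noise of standard
#' deviation `cfg$sd`. Weights are not clipped afterwards (the initial range
#' \[0,1\] is not an invariant of evolution).
#'
#' @param genome A [genome()].
#' @param cfg A [mutationConfig()].
#' @return The mutated `Genome`.
#' @export
mutateGenome <- function(genome, cfg) {
  genome$networks <- lapply(genome$networks, function(v) {
    hit <- runif(length(v)) < cfg$per_gene_prob
    nh <- sum(hit)
    if (nh > 0) v[hit] <- v[hit] + rnorm(nh, 0, cfg$sd)
    v
  })
  genome
}

#' Network duplication / deletion operator
#'
#' When enabled: a single-network genome gains an identical second copy of
#' its network with probability `cfg$duplication_prob`; a dual-network
#' genome loses a uniformly chosen copy with probability
#' `cfg$deletion_prob`; otherwise the genome is unchanged. Applied at the
#' same point of the life cycle as mutation (duplication first, so a fresh
#' copy can immediately diverge by mutation).
#'
#' @inheritParams mutateGenome
#' @return The possibly modified `Genome`.
#' @export
applyDuplication <- function(genome, cfg) {
  if (!cfg$duplication_enabled) return(genome)
  if (length(genome$networks) == 1L) {
    if (runif(1) < cfg$duplication_prob)
      genome$networks <- list(genome$networks[[1]], genome$networks[[1]])
  } else {
    if (runif(1) < cfg$deletion_prob) {
      drop <- if (runif(1) < 0.5) 1L else 2L
      genome$networks <- genome$networks[-drop]
    }
  }
  genome
}

# Offspring pipeline: duplication/deletion, then mutation.
makeOffspring <- function(parent, mcfg) {
  mutateGenome(applyDuplication(parent, mcfg), mcfg)
}

# Internal trial runner used by the evaluation loop: same semantics as
# runTrial() but returns the raw compiled-core result (no event data frame),
# keeping per-trial overhead negligible against the step loop.
rawTrial <- function(genome_A, genome_B, cppcfg, seed) {
  keep <- get0(".Random.seed", globalenv())
  on.exit(restoreRNG(keep), add = TRUE)
  set.seed(seed)
  roles <- assignRoles(genome_A, genome_B)
  cppRunTrial(genome_A$networks[[roles[1]]], genome_B$networks[[roles[2]]],
              cppcfg, FALSE)
}

#' Evaluate a population by random pairing
#'
#' Each focal individual is matched with `n_partners` distinct partners
#' sampled uniformly from the rest of the population and plays
#' `trials_per_pair` independent trials with each (the focal always sits in
#' the hunter-A slot). Its fitness is the mean of its own cumulative reward
#' over those trials; the partner's rewards in a focal's trials do not count
#' towards the partner. With the default configuration this is 5 partners x
#' 5 trials = 25 independent trials per individual per generation.
#'
#' @param population List of [genome()]s.
#' @param world A [worldConfig()].
#' @param payoffs A [payoffScheme()].
#' @param cfg An [evolutionConfig()].
#' @return A list with `fitness` (numeric), `n_trials` (trials consumed per
#'   individual), and `breakdown`: an n x 6 matrix of capture-event counts
#'   from each focal's trials (`boar_solo`, `boar_coop`, `stag_solo`,
#'   `stag_coop`, `coop_first_A`, `events`).
#' @export
evaluatePopulation <- function(population, world, payoffs, cfg) {
  n <- length(population)
  if (n < cfg$n_partners + 1L)
    stop("population smaller than n_partners + 1", call. = FALSE)
  if (!is.null(cfg$eval_seed)) {
    keep <- get0(".Random.seed", globalenv())
    on.exit(restoreRNG(keep), add = TRUE)
    set.seed(cfg$eval_seed)
  }
  fitness <- numeric(n)
  nt <- cfg$n_partners * cfg$trials_per_pair
  cppcfg <- cppConfig(world, payoffs)
  breakdown <- matrix(0L, n, 6,
                      dimnames = list(NULL, c("boar_solo", "boar_coop",
                                              "stag_solo", "stag_coop",
                                              "coop_first_A", "events")))
  for (i in seq_len(n)) {
    partners <- sample.int(n - 1L, cfg$n_partners)
    partners <- ifelse(partners >= i, partners + 1L, partners)
    seeds <- sample.int(2147483647L, nt)
    total <- 0
    k <- 0L
    for (j in partners) {
      for (t in seq_len(cfg$trials_per_pair)) {
        k <- k + 1L
        res <- rawTrial(population[[i]], population[[j]], cppcfg, seeds[k])
        total <- total + res$rewards[1]
        if (length(res$ev_kind)) {
          stag <- res$ev_kind == 1L
          coop <- res$ev_coop == 1L
          breakdown[i, 1] <- breakdown[i, 1] + sum(!stag & !coop)
          breakdown[i, 2] <- breakdown[i, 2] + sum(!stag & coop)
          breakdown[i, 3] <- breakdown[i, 3] + sum(stag & !coop)
          breakdown[i, 4] <- breakdown[i, 4] + sum(stag & coop)
          breakdown[i, 5] <- breakdown[i, 5] + sum(coop & res$ev_first == 0L)
          breakdown[i, 6] <- breakdown[i, 6] + length(stag)
        }
      }
    }
    fitness[i] <- total / nt
  }
  list(fitness = fitness, n_trials = rep(nt, n), breakdown = breakdown)
}

restoreRNG <- function(saved) {
  if (is.null(saved)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", saved, envir = globalenv())
}

#' Elitist (k + k) selection step
#'
#' Ranks the evaluated population by fitness (descending, ties broken by
#' lower index), keeps the best `n_elites` unchanged, and fills the
#' remaining slots with mutants, each generated from a single uniformly
#' chosen elite parent by duplication/deletion followed by Gaussian
#' mutation. With the defaults this is the (10 + 10) algorithm.
#'
#' @param population List of [genome()]s.
#' @param fitness Fitness vector from [evaluatePopulation()].
#' @param cfg An [evolutionConfig()].
#' @return The next-generation population (elites first).
#' @export
elitistStep <- function(population, fitness, cfg) {
  stopifnot(length(population) == length(fitness))
  ord <- order(-fitness, seq_along(fitness))
  elites <- population[ord[seq_len(cfg$n_elites)]]
  n_new <- cfg$population_size - cfg$n_elites
  mutants <- lapply(seq_len(n_new), function(m) {
    parent <- elites[[sample.int(cfg$n_elites, 1L)]]
    makeOffspring(parent, cfg$mutation)
  })
  c(elites, mutants)
}

#' Wright-Fisher (fitness-proportionate) selection step
#'
#' Non-overlapping generations with strong drift: each of the
#' `population_size` offspring draws its parent independently with
#' probability proportional to fitness (uniformly when total fitness is
#' zero), then passes through duplication/deletion and mutation. No elitism.
#'
#' @inheritParams elitistStep
#' @return The next-generation population.
#' @export
wrightFisherStep <- function(population, fitness, cfg) {
  stopifnot(length(population) == length(fitness))
  if (any(fitness < 0)) stop("negative fitness", call. = FALSE)
  tot <- sum(fitness)
  prob <- if (tot > 0) fitness / tot else rep(1 / length(fitness), length(fitness))
  parents <- sample.int(length(population), cfg$population_size,
                        replace = TRUE, prob = prob)
  lapply(parents, function(p) makeOffspring(population[[p]], cfg$mutation))
}
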