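#' Hunting-strategy profile from capture events
#'
#' Summarizes what a hunter (or pair) actually hunted: the fraction of
#' capture events targeting a stag (the realized mixed strategy P), the
#' fraction of captures that were cooperative, the fraction of all captures
#' that were cooperative stag hunts, and the leadership index — the fraction
#' of cooperative captures in which hunter A arrived first (values near 0 or
#' 1 indicate a leader-follower role asymmetry, near 0.5 a symmetric
#' strategy).
#'
#' @param x A capture-event data frame ([captureEvents()]), a `TrialResult`,
#'   or a `ReplicateHistory` (which uses the best individual's capture
#'   breakdown at the final generation).
#' @return An object of class `StrategyProfile` with fields `stag_fraction`,
#'   `coop_fraction`, `coop_stag_fraction`, `leadership_index`, `n_events`,
#'   `n_coop`. With zero capture events all fractions are `NA` and the
#'   profile is flagged undefined.
#' @export
huntProportions <- function(x) {
  if (inherits(x, "ReplicateHistory")) {
    last <- x$records[nrow(x$records), ]
    counts <- c(boar_solo = last$best_boar_solo, boar_coop = last$best_boar_coop,
                stag_solo = last$best_stag_solo, stag_coop = last$best_stag_coop)
    firstA <- last$best_coop_first_A
  } else {
    ev <- if (inherits(x, "TrialResult")) x$events else x
    stopifnot(is.data.frame(ev))
    counts <- c(boar_solo = sum(ev$prey == "boar" & !ev$cooperative),
                boar_coop = sum(ev$prey == "boar" & ev$cooperative),
                stag_solo = sum(ev$prey == "stag" & !ev$cooperative),
                stag_coop = sum(ev$prey == "stag" & ev$cooperative))
    firstA <- sum(ev$cooperative & ev$first_arriver == "A")
  }
  n <- sum(counts)
  ncoop <- counts[["boar_coop"]] + counts[["stag_coop"]]
  structure(list(
    stag_fraction = if (n > 0) (counts[["stag_solo"]] + counts[["stag_coop"]]) / n else NA_real_,
    coop_fraction = if (n > 0) ncoop / n else NA_real_,
    coop_stag_fraction = if (n > 0) counts[["stag_coop"]] / n else NA_real_,
    leadership_index = if (ncoop > 0) firstA / ncoop else NA_real_,
    n_events = as.integer(n), n_coop = as.integer(ncoop),
    defined = n > 0), class = "StrategyProfile")
}

#' @export
print.StrategyProfile <- function(x, ...) {
  if (!x$defined) cat("<StrategyProfile> undefined (no capture events)\n")
  else cat(sprintf("<StrategyProfile> %d event(s): P(stag) = %.3f, coop = %.3f, coop-stag = %.3f, leadership = %s\n",
                   x$n_events, x$stag_fraction, x$coop_fraction,
                   x$coop_stag_fraction,
                   if (is.na(x$leadership_index)) "NA" else sprintf("%.3f", x$leadership_index)))
  invisible(x)
}

#' Has the population escaped to the stag-hunting equilibrium?
#'
#' A replicate counts as transitioned when cooperative stag captures account
#' for strictly more than 50% of all prey hunted.
#'
#' @param profile A [huntProportions()] profile (must be defined, i.e. at
#'   least one capture event).
#' @return `TRUE` or `FALSE`.
#' @export
detectTransition <- function(profile) {
  stopifnot(inherits(profile, "StrategyProfile"))
  if (!profile$defined)
    stop("transition is undefined without capture events", call. = FALSE)
  profile$coop_stag_fraction > 0.5
}

#' Coordination-failure probability of two independent mixed strategists
#'
#' If both players independently hunt the stag with probability `P`, they
#' miscoordinate (one picks the stag, the other the boar) with probability
#' `2 P (1 - P)` — maximal at P = 0.5, zero at the two pure strategies.
#'
#' @param P Probability (vectorized) in \[0, 1\].
#' @return `2 * P * (1 - P)`.
#' @examples
#' coordinationFailureProb(c(0, 0.5, 1))
#' @export
coordinationFailureProb <- function(P) {
  if (any(!is.finite(P)) || any(P < 0 | P > 1))
    stop("P must lie in [0, 1]", call. = FALSE)
  2 * P * (1 - P)
}

#' Classify a pair as leader-follower
#'
#' Operationalizes role asymmetry: a leadership index at or beyond 0.2 / 0.8
#' over at least `min_coop` cooperative captures.
#'
#' @param profile A [huntProportions()] profile.
#' @param min_coop Minimum number of cooperative captures required.
#' @return `TRUE`, `FALSE`, or `NA` when there are too few cooperative
#'   captures to judge.
#' @export
isLeaderFollower <- function(profile, min_coop = 20) {
  stopifnot(inherits(profile, "StrategyProfile"))
  if (profile$n_coop < min_coop) return(NA)
  profile$leadership_index <= 0.2 || profile$leadership_index >= 0.8
}

#' One-tailed Mann-Whitney U test
#'
#' Rank-sum U with midrank tie handling, testing the one-sided alternative
#' that `sample_a` tends to exceed `sample_b`. For combined sample sizes up
#' to `exact_max` (12 by default) the p-value is computed by exact
#' enumeration of all group labelings of the pooled values (valid under
#' ties); beyond that, by normal approximation with tie correction and
#' continuity correction. The degenerate case of zero rank variance (all
#' pooled values identical) returns p = 0.5: no evidence in either
#' direction.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param exact_max Largest combined size for exact enumeration.
#' @return An object of class `TestResult`: `U` (for sample A), `p_value`,
#'   `tail = "one_tailed"`, `method`.
#' @examples
#' mannWhitneyOneTailed(c(5, 6, 7, 8), c(1, 2, 3, 4))  # complete separation
#' @export
mannWhitneyOneTailed <- function(sample_a, sample_b, exact_max = 12) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty", call. = FALSE)
  stopifnot(is.numeric(sample_a), is.numeric(sample_b),
            all(is.finite(sample_a)), all(is.finite(sample_b)))
  m <- length(sample_a); n <- length(sample_b); N <- m + n
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(pooled)
  if (length(ties) == 1L) {
    method <- "degenerate"
    p <- 0.5
  } else if (N <= exact_max) {
    method <- "exact"
    idx <- combn(N, m)
    Uperm <- colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2
    p <- mean(Uperm >= U - 1e-9)
  } else {
    method <- "normal"
    tie_term <- sum(ties^3 - ties)
    sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    z <- (U - m * n / 2 - 0.5) / sqrt(sigma2)
    p <- pnorm(z, lower.tail = FALSE)
  }
  structure(list(U = U, p_value = p, tail = "one_tailed", method = method),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("<TestResult> one-tailed Mann-Whitney U = %g, p = %.4g (%s)\n",
              x$U, x$p_value, x$method))
  invisible(x)
}

#' Screen random mutants of a resident genotype for stag preference
#'
#' Generates `n_mutants` random mutants of a resident genotype with the
#' standard mutation operator and assesses each mutant's realized hunting
#' preference: the mutant (hunter A) is paired with the resident (hunter B)
#' for `probe_trials` independent trials and its stag preference is
#' estimated as the stag fraction of the capture events; when no capture
#' occurs the estimate falls back to the stag fraction of the mutant's
#' first-contact (streak-onset) events, and is `NA` if the mutant never
#' touched any prey. The mutant is probed against the resident, not
#' clonally, because the quantity of interest is the behavior of a rare
#' mutant inside a resident population.
#'
#' @param resident A [genome()] (typically a well-optimized boar hunter).
#' @param n_mutants Number of random mutants to generate.
#' @param threshold Preference threshold for the selected subset.
#' @param world A [worldConfig()].
#' @param payoffs A [payoffScheme()].
#' @param mutation A [mutationConfig()].
#' @param probe_trials Trials per mutant.
#' @return A data frame (class `MutantScreen`) with one row per mutant:
#'   `mutant`, `p_stag`, `n_events`, `fallback`, `selected`
#'   (`p_stag > threshold`). The threshold is stored as an attribute.
#' @export
mutantScreen <- function(resident, n_mutants = 100000, threshold = 0.01,
                         world = worldConfig(), payoffs = payoffScheme(),
                         mutation = mutationConfig(), probe_trials = 25) {
  stopifnot(inherits(resident, "Genome"))
  p_stag <- numeric(n_mutants)
  n_events <- integer(n_mutants)
  fallback <- logical(n_mutants)
  for (i in seq_len(n_mutants)) {
    mut <- mutateGenome(resident, mutation)
    seeds <- sample.int(2147483647L, probe_trials)
    stag <- 0L; tot <- 0L; t_stag <- 0L; t_tot <- 0L
    for (k in seq_len(probe_trials)) {
      res <- runTrial(mut, resident, world, payoffs, seed = seeds[k])
      tot <- tot + nrow(res$events)
      stag <- stag + sum(res$events$prey == "stag")
      t_tot <- t_tot + sum(res$touches["A", ])
      t_stag <- t_stag + res$touches["A", "stag"]
    }
    if (tot > 0) {
      p_stag[i] <- stag / tot
    } else if (t_tot > 0) {
      p_stag[i] <- t_stag / t_tot
      fallback[i] <- TRUE
    } else {
      p_stag[i] <- NA_real_
    }
    n_events[i] <- tot
  }
  out <- data.frame(mutant = seq_len(n_mutants), p_stag = p_stag,
                    n_events = n_events, fallback = fallback,
                    selected = !is.na(p_stag) & p_stag > threshold)
  attr(out, "threshold") <- threshold
  class(out) <- c("MutantScreen", "data.frame")
  out
}

#' Summarize a study (one condition, many replicates)
#'
#' Per replicate, from the best individual at the final generation: final
#' best and mean fitness, strategy profile fractions, leadership index,
#' dual-network census, and whether the replicate transitioned to majority
#' cooperative stag hunting ([detectTransition()]; a replicate whose best
#' individual captured nothing counts as not transitioned).
#'
#' @param histories List of [runReplicate()] histories.
#' @return An object of class `StudySummary`: a per-replicate data frame
#'   with attribute `n_transitioned`.
#' @export
summarizeStudy <- function(histories) {
  stopifnot(length(histories) >= 1,
            all(vapply(histories, inherits, TRUE, "ReplicateHistory")))
  rows <- lapply(histories, function(h) {
    last <- h$records[nrow(h$records), ]
    pr <- huntProportions(h)
    data.frame(replicate = h$replicate,
               best_fitness = last$best_fitness,
               mean_fitness = last$mean_fitness,
               n_events = pr$n_events,
               stag_fraction = pr$stag_fraction,
               coop_fraction = pr$coop_fraction,
               coop_stag_fraction = pr$coop_stag_fraction,
               leadership_index = pr$leadership_index,
               n_dual = last$n_dual,
               transitioned = pr$defined && detectTransition(pr))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_transitioned") <- sum(out$transitioned)
  class(out) <- c("StudySummary", "data.frame")
  out
}

#' @export
print.StudySummary <- function(x, ...) {
  cat(sprintf("<StudySummary> %d replicate(s), %d transitioned to majority cooperative stag hunting\n",
              nrow(x), attr(x, "n_transitioned")))
  print.data.frame(x, digits = 3)
  invisible(x)
}
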