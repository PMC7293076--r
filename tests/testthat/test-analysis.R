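mkEvents <- function(boar_solo = 0, boar_coop = 0, stag_solo = 0,
                     stag_coop = 0, firstA_frac = 1) {
  n <- boar_solo + boar_coop + stag_solo + stag_coop
  coop <- c(rep(FALSE, boar_solo), rep(TRUE, boar_coop),
            rep(FALSE, stag_solo), rep(TRUE, stag_coop))
  nc <- sum(coop)
  first <- rep("B", n)
  first[which(coop)[seq_len(round(firstA_frac * nc))]] <- "A"
  data.frame(step = seq_len(n) * 800L,
             prey = c(rep("boar", boar_solo + boar_coop),
                      rep("stag", stag_solo + stag_coop)),
             cooperative = coop, first_arriver = first,
             stringsAsFactors = FALSE)
}

test_that("huntProportions summarizes capture events", {
  p <- huntProportions(mkEvents(boar_coop = 4))
  expect_equal(p$stag_fraction, 0)
  expect_equal(p$coop_fraction, 1)
  expect_equal(p$coop_stag_fraction, 0)
  p2 <- huntProportions(mkEvents(boar_coop = 1, stag_coop = 3))
  expect_equal(p2$stag_fraction, 0.75)
  p3 <- huntProportions(mkEvents(boar_solo = 2, stag_solo = 2))
  expect_equal(p3$coop_fraction, 0)
  expect_true(is.na(p3$leadership_index))
  # leadership index over cooperative captures only
  p4 <- huntProportions(mkEvents(boar_coop = 10, stag_solo = 3,
                                 firstA_frac = 0.8))
  expect_equal(p4$leadership_index, 0.8)
  # no events: undefined profile
  p0 <- huntProportions(mkEvents())
  expect_false(p0$defined)
  expect_true(is.na(p0$stag_fraction))
})

test_that("transition detection uses a strict majority of cooperative stag hunts", {
  expect_true(detectTransition(huntProportions(
    mkEvents(boar_coop = 49, stag_coop = 51))))
  expect_false(detectTransition(huntProportions(
    mkEvents(boar_coop = 50, stag_coop = 50))))
  # stag hunts that were not cooperative do not count
  expect_false(detectTransition(huntProportions(
    mkEvents(stag_solo = 60, boar_coop = 40))))
  expect_error(detectTransition(huntProportions(mkEvents())), "undefined")
})

test_that("coordination failure of two mixed strategists is 2P(1-P)", {
  expect_equal(coordinationFailureProb(0), 0)
  expect_equal(coordinationFailureProb(1), 0)
  expect_equal(coordinationFailureProb(0.5), 0.5)
  P <- seq(0, 1, by = 0.05)
  f <- coordinationFailureProb(P)
  expect_equal(f, rev(f))                      # symmetric about 1/2
  expect_equal(which.max(f), which(P == 0.5))  # maximized at 1/2
  expect_error(coordinationFailureProb(1.2), "\\[0, 1\\]")
  # Monte-Carlo cross-check: two independent choosers at P = 0.3
  set.seed(10)
  n <- 1e5
  fail <- mean((runif(n) < 0.3) != (runif(n) < 0.3))
  se <- sqrt(0.42 * 0.58 / n)
  expect_equal(fail, coordinationFailureProb(0.3), tolerance = 3 * se / 0.42)
})

test_that("leader-follower classification needs enough cooperative hunts", {
  lf <- huntProportions(mkEvents(boar_coop = 30, firstA_frac = 0.9))
  expect_true(isLeaderFollower(lf))
  sym <- huntProportions(mkEvents(boar_coop = 30, firstA_frac = 0.5))
  expect_false(isLeaderFollower(sym))
  few <- huntProportions(mkEvents(boar_coop = 5, firstA_frac = 1))
  expect_true(is.na(isLeaderFollower(few)))
})

test_that("one-tailed Mann-Whitney matches exact enumeration and wilcox.test", {
  # complete separation, n = 4 vs 4: p = 1 / choose(8, 4)
  r <- mannWhitneyOneTailed(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(r$U, 16)
  expect_equal(r$p_value, 1 / 70)
  expect_equal(r$method, "exact")
  # identical constant samples carry no evidence either way
  expect_equal(mannWhitneyOneTailed(rep(3, 5), rep(3, 4))$p_value, 0.5)
  # random small samples against an independent enumeration oracle,
  # with and without ties
  set.seed(40)
  for (i in 1:12) {
    a <- sample(1:6, sample(3:6, 1), replace = TRUE)
    b <- sample(1:6, sample(3:6, 1), replace = TRUE)
    r <- mannWhitneyOneTailed(a, b)
    expect_equal(r$U, bruteU(a, b))
    if (length(unique(c(a, b))) > 1)
      expect_equal(r$p_value, bruteExactP(a, b))
  }
  # tie-free: wilcox.test's exact one-sided p as an independent cross-check
  for (i in 1:8) {
    a <- rnorm(sample(4:6, 1)); b <- rnorm(sample(4:6, 1), mean = 0.5)
    expect_equal(mannWhitneyOneTailed(a, b)$p_value,
                 wilcox.test(a, b, alternative = "greater", exact = TRUE)$p.value)
  }
  # normal approximation tracks the exact p for moderate samples
  set.seed(41)
  for (i in 1:8) {
    a <- rnorm(6); b <- rnorm(6, mean = 0.3)
    pe <- mannWhitneyOneTailed(a, b)$p_value
    pn <- mannWhitneyOneTailed(a, b, exact_max = 0)$p_value
    expect_equal(pn, pe, tolerance = 0.012)
  }
  # larger samples use the tie-corrected normal approximation
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(mannWhitneyOneTailed(a, b)$method, "normal")
  expect_error(mannWhitneyOneTailed(numeric(0), 1:3), "non-empty")
})

test_that("mutant screening estimates stag preference against the resident", {
  set.seed(90)
  stub <- makeFixture("boar_hunter_stub")
  wc <- worldConfig(trial_steps = 2500L)
  scr <- mutantScreen(stub, n_mutants = 20, threshold = 0.01, world = wc,
                      probe_trials = 2)
  expect_equal(nrow(scr), 20)
  expect_true(all(c("p_stag", "n_events", "fallback", "selected") %in% names(scr)))
  # mutants of a stag-avoiding resident concentrate near zero preference
  expect_lte(median(scr$p_stag, na.rm = TRUE), 0.1)
  expect_gt(mean(scr$n_events > 0), 0.5)  # probes do produce captures
  # threshold = 0 selects exactly the mutants with any stag evidence
  scr0 <- scr
  scr0$selected <- !is.na(scr0$p_stag) & scr0$p_stag > 0
  set.seed(90)
  expect_identical(mutantScreen(stub, n_mutants = 20, threshold = 0,
                                world = wc, probe_trials = 2)$selected,
                   scr0$selected)
})

test_that("summarizeStudy counts transitioned replicates", {
  mkHist <- function(rep, bs, bc, ss, sc, firstA = bc + sc, dual = 0) {
    rec <- data.frame(generation = 1:2, phase = c(1, 2),
                      best_fitness = c(0, 100), mean_fitness = c(0, 50),
                      best_boar_solo = c(0, bs), best_boar_coop = c(0, bc),
                      best_stag_solo = c(0, ss), best_stag_coop = c(0, sc),
                      best_coop_first_A = c(0, firstA),
                      best_events = c(0, bs + bc + ss + sc),
                      n_dual = c(0, dual))
    structure(list(records = rec, final_population = list(),
                   replicate = rep, seed = rep), class = "ReplicateHistory")
  }
  hs <- list(mkHist(1, 0, 10, 0, 0),      # pure boar hunter
             mkHist(2, 0, 2, 0, 8),       # transitioned
             mkHist(3, 1, 4, 1, 4))       # stag share 4/10: no
  s <- summarizeStudy(hs)
  expect_equal(attr(s, "n_transitioned"), 1L)
  expect_equal(s$transitioned, c(FALSE, TRUE, FALSE))
  expect_equal(s$stag_fraction, c(0, 0.8, 0.5))
  expect_equal(s$coop_stag_fraction, c(0, 0.8, 0.4))
  s1 <- summarizeStudy(hs[1])
  expect_equal(attr(s1, "n_transitioned"), 0L)
})
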