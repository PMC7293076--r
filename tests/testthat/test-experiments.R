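test_that("runTrial is deterministic and leaves the caller's RNG alone", {
  stub <- makeFixture("boar_hunter_stub")
  cfg <- worldConfig(trial_steps = 3000L)
  pay <- payoffScheme()
  set.seed(1); rng_before <- .Random.seed
  r1 <- runTrial(stub, stub, cfg, pay, seed = 9)
  expect_identical(.Random.seed, rng_before)
  r2 <- runTrial(stub, stub, cfg, pay, seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$steps_run, 3000L)
  # rewards equal the payoff sum implied by the logged events
  implied <- sum(ifelse(r1$events$cooperative,
                        ifelse(r1$events$prey == "stag", 250, 125), 0))
  expect_equal(unname(r1$rewards), rep(implied, 2))
  # pre-evolution payoffs: a cooperative capture can pay 0 but is logged
  r3 <- runTrial(stub, stub, cfg, payoffScheme(boar_coop = 0, stag_coop = 0),
                 seed = 9)
  expect_identical(r3$events, r1$events)
  expect_equal(unname(r3$rewards), c(0, 0))
})

test_that("compiled trials reproduce the pure-R pipeline exactly", {
  cfg <- worldConfig(trial_steps = 250L)
  pay <- payoffScheme()
  stub <- makeFixture("boar_hunter_stub")
  set.seed(2)
  wild <- genome(rnorm(410, sd = 1.2))
  for (case in list(list(a = stub, b = stub, seed = 41),
                    list(a = wild, b = stub, seed = 42))) {
    got <- runTrial(case$a, case$b, cfg, pay, case$seed,
                    recordTrajectory = TRUE)
    # replay the identical trial through the R reference implementations
    set.seed(case$seed)
    roles <- assignRoles(case$a, case$b)
    expect_identical(roles, got$roles)
    wA <- decodeGenome(case$a$networks[[roles[1]]])
    wB <- decodeGenome(case$b$networks[[roles[2]]])
    w <- initWorld(cfg)
    for (s in 1:250) {
      cA <- forwardNetwork(wA, encodeInputs(senseRobot(w, 1, cfg)))
      cB <- forwardNetwork(wB, encodeInputs(senseRobot(w, 2, cfg)))
      w <- stepWorld(w, cA, cB, cfg, pay)
      expect_identical(unname(c(got$trajectory[s, 1:2], got$trajectory[s, 4:5])),
                       c(w$rx[1], w$ry[1], w$rx[2], w$ry[2]))
    }
    expect_identical(unname(got$rewards), unname(w$rewards))
    expect_identical(got$events, captureEvents(w))
  }
})

test_that("replicates execute phases in order and are reproducible", {
  wc <- worldConfig(trial_steps = 150L)
  ec <- evolutionConfig(population_size = 4, n_elites = 2, n_partners = 1,
                        trials_per_pair = 1)
  proto <- protocol(list(phase(2, wc, payoffScheme(stag_coop = 0), ec),
                         phase(3, wc, payoffScheme(), ec)),
                    n_replicates = 2, base_seed = 5)
  h <- runReplicate(proto, 1)
  expect_s3_class(h, "ReplicateHistory")
  expect_equal(nrow(h$records), 5)
  expect_equal(h$records$phase, c(1, 1, 2, 2, 2))
  expect_equal(h$records$generation, 1:5)
  expect_length(h$final_population, 4)
  expect_identical(runReplicate(proto, 1), h)
  # a zero-generation phase changes nothing
  proto0 <- protocol(list(phase(2, wc, payoffScheme(stag_coop = 0), ec),
                          phase(0, wc, payoffScheme(stag_coop = 0), ec)),
                     n_replicates = 1, base_seed = 5)
  protoRef <- protocol(phase(2, wc, payoffScheme(stag_coop = 0), ec),
                       n_replicates = 1, base_seed = 5)
  h0 <- runReplicate(proto0, 1)
  hr <- runReplicate(protoRef, 1)
  expect_identical(h0$records, hr$records)
  expect_identical(h0$final_population, hr$final_population)
})

test_that("study replicates are mutually independent", {
  wc <- worldConfig(trial_steps = 120L)
  ec <- evolutionConfig(population_size = 4, n_elites = 2, n_partners = 1,
                        trials_per_pair = 1)
  proto <- protocol(phase(2, wc, payoffScheme(), ec),
                    n_replicates = 3, base_seed = 77)
  study <- runStudy(proto)
  expect_length(study, 3)
  # any replicate rerun in isolation reproduces its history bit-identically
  expect_identical(runReplicate(proto, 2), study[[2]])
  expect_identical(runReplicate(proto, 3), study[[3]])
  expect_length(runStudy(proto, n_replicates = 1), 1)
  seeds <- vapply(study, `[[`, 1L, "seed")
  expect_equal(seeds, bitwXor(77L, 1:3))
})

test_that("protocol presets encode the study designs", {
  p <- protocolPreset("simple", scale = "paper")
  expect_equal(vapply(p$phases, `[[`, 1L, "generations"), c(3000L, 6000L))
  expect_equal(p$phases[[1]]$world$trial_steps, 20000L)
  expect_equal(p$phases[[1]]$world$n_boars, 1L)
  expect_equal(p$phases[[1]]$payoffs$stag_coop, 0)   # pre-evolution
  expect_equal(p$phases[[2]]$payoffs$stag_coop, 250) # reinstated
  expect_equal(p$phases[[1]]$evolution$n_partners, 5L)
  expect_equal(p$phases[[1]]$evolution$trials_per_pair, 5L)
  expect_equal(p$n_replicates, 30L)
  expect_null(p$initial_population)

  pc <- protocolPreset("complex", scale = "paper")
  expect_equal(pc$phases[[1]]$world$n_boars, 9L)
  expect_equal(pc$phases[[1]]$world$n_stags, 9L)
  expect_false(pc$phases[[1]]$evolution$mutation$duplication_enabled)
  pa <- protocolPreset("complex-asym", scale = "paper")
  expect_true(pa$phases[[1]]$evolution$mutation$duplication_enabled)
  pw <- protocolPreset("wright-fisher", scale = "paper")
  expect_equal(pw$phases[[1]]$evolution$scheme, "wright_fisher")
  expect_equal(pw$phases[[1]]$generations, 12000L)
  expect_equal(pw$n_replicates, 12L)

  # desk presets seed clonally with the stub fixtures
  d <- protocolPreset("simple", scale = "desk")
  expect_length(d$initial_population, 20)
  expect_length(d$initial_population[[1]]$networks, 1)
  da <- protocolPreset("complex-asym", scale = "desk")
  expect_length(da$initial_population[[1]]$networks, 2)
})
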