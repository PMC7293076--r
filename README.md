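# staghunt

Agent-based simulations of equilibrium selection in a two-player stag-hunt
coordination game played by *embodied* agents. The package is for
researchers in evolutionary game theory, social evolution and evolutionary
robotics who want a mechanistic, reproducible testbed for questions that
stylized matrix-game models cannot ask: when hunters must physically find,
approach and jointly hold a prey, can behavioral coordination strategies —
and the indirect genetic effects they create — dissolve the evolutionary
trap that locks populations into the inefficient equilibrium?

## The model

Two hunters play the payoff matrix

|          | Boar | Stag |
|----------|------|------|
| **Boar** | 125  | 0    |
| **Stag** | 0    | 250  |

with two strict Nash equilibria (both hunt boars, both hunt stags); the
stag equilibrium is payoff-dominant, but a boar-hunting population is an
evolutionary trap: a rare stag-preferring mutant miscoordinates with the
resident majority and earns nothing. Two independent mixed strategists who
hunt the stag with probability *P* fail to coordinate with probability
2*P*(1−*P*).

The players are differential-drive robots in an 800 × 800 arena with
immobile, respawning prey. Each robot senses through 12 proximity rays
(range 40) and a 12-ray typed camera (90° field of view reporting
hunter/boar/stag plus distance), and is driven by a sigmoid multilayer
perceptron — 49 inputs, 8 hidden units, 2 wheel outputs, 410 connection
weights that constitute the genome. Capturing a prey requires 800
consecutive time steps of body contact, with both hunters present at the
final step for the capture to pay. Populations of 20 genomes evolve under
either elitist (10+10) selection or a Wright–Fisher (fitness-proportionate)
scheme, with per-gene Gaussian mutation (rate 5×10⁻³, SD 0.2) and an
optional network-duplication operator that gives an individual two
independently evolving controller copies — paired dual-network individuals
always express different copies, the substrate for leader–follower
division of labor.

## Worked example

A hand-wired boar-hunting controller (`makeFixture("boar_hunter_stub")`)
paired with its clone, for a quarter-length trial:

```r
library(staghunt)
stub  <- makeFixture("boar_hunter_stub")
trial <- runTrial(stub, stub, worldConfig(trial_steps = 5000),
                  payoffScheme(), seed = 42)
trial
#> <TrialResult> 5000 steps, rewards A = 500 B = 500, 4 capture(s) (4 cooperative)
trial$events
#>   step prey cooperative first_arriver
#> 1 1332 boar        TRUE             B
#> 2 2498 boar        TRUE             B
#> 3 3587 boar        TRUE             B
#> 4 4866 boar        TRUE             A
huntProportions(trial)
#> <StrategyProfile> 4 event(s): P(stag) = 0.000, coop = 1.000, coop-stag = 0.000, leadership = 0.250
```

Both hunters converge on the single boar, hold it for the 800-step count,
and collect 125 each per capture — four cooperative boar captures, 500
reward units apiece, and a realized stag probability of 0: a pure
boar-hunting pair. The analysis layer provides the closed form for
miscoordination of mixed strategists and a one-tailed Mann–Whitney U test
with exact small-sample enumeration:

```r
coordinationFailureProb(c(0, 0.25, 0.5, 1))
#> [1] 0.000 0.375 0.500 0.000
mannWhitneyOneTailed(c(5, 6, 7, 8), c(1, 2, 3, 4))
#> <TestResult> one-tailed Mann-Whitney U = 16, p = 0.01429 (exact)
```

Whole studies run through protocols: `protocolPreset("simple")` is
boar-hunter pre-evolution (stag reward 0) followed by evolution with the
regular payoffs; `"complex"` uses 9 prey of each type, `"complex-asym"`
additionally enables network duplication, and `"wright-fisher"` swaps in
fitness-proportionate selection. `runStudy()` executes independent seeded
replicates and `summarizeStudy()` reports, per replicate, the final best
individual's strategy profile and whether cooperative stag hunting came to
dominate. See the vignette (`vignettes/stag-hunt-simulations.Rmd`) for the
full model description and the desk-vs-paper problem scales, and
`inst/scripts/staghunt-evolve.R` for a command-line front end
(`evolve` / `replay` / `analyze`).

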