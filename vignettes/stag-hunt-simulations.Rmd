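---
title: "Embodied stag-hunt simulations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embodied stag-hunt simulations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staghunt)
```

## The game and why it is embodied

Two hunters play a stag hunt: the arena holds two kinds of immobile prey,
poorly nutritious *boars* and highly nutritious *stags*. Capturing a prey
cooperatively pays each hunter 125 reward units for a boar and 250 for a
stag; hunting alone pays 0. The game therefore has two strict equilibria —
both hunt boars, or both hunt stags — with the stag equilibrium
payoff-dominant. A population fixed on boar hunting is an *evolutionary
trap*: a rare stag-preferring mutant is paired with boar-hunting residents,
fails to coordinate, earns nothing, and is eliminated. Two independent
mixed strategists who each hunt the stag with probability $P$ miscoordinate
with probability $2P(1-P)$ (`coordinationFailureProb()`).

Rather than treating strategies as abstract coin flips, the package embodies
the players: each hunter is a differential-drive robot whose behavior is
produced, step by step, by a sigmoid multilayer perceptron mapping 49 sensor
activations to two wheel commands. Whether two hunters "agree on the stag"
is then a mechanical question about trajectories, sensing and timing — which
is exactly what lets behavioral coordination strategies (turning,
leader–follower) change the evolutionary character of the game through
indirect genetic effects: one individual's genes alter, via behavior, the
realized phenotype of its partner.

## World model

* **Arena**: 800 × 800 length units, four solid walls; origin bottom-left,
  headings in radians counter-clockwise from +x. Both robots start adjacent
  at the top-edge midline (x = 400 ∓ 15, y = 780) facing into the arena.
* **Bodies**: robots are discs of radius 10, prey discs of radius 20. These
  sizes are free embodiment parameters (config fields), chosen so the
  40-unit proximity-sensor range spans about two body diameters. The axle
  length equals the body diameter (20), and the maximal wheel speed is 2
  units/step, so a trial of 20,000 steps can cross the arena dozens of
  times.
* **Kinematics**: a wheel command $c \in [0,1]$ maps to wheel velocity
  $(2c-1) \cdot v_{\max}$; the body advances by the mean wheel velocity
  along the pre-step heading, then the heading changes by
  $(v_R - v_L)/\text{axle}$ — one explicit Euler step of the continuous
  differential-drive kinematics. Positions are clamped so bodies stay
  inside the walls; there is no momentum or friction. Robots are mutually
  solid (overlap is resolved by a symmetric minimal push-apart); prey are
  not solid.
* **Capture rule**: a prey's capture counter increments on every step in
  which *at least one* hunter's body overlaps the prey disc and resets on a
  zero-contact step. When the counter reaches 800 the prey resolves: if
  both hunters are in contact at that step, the capture is cooperative and
  each receives the prey's payoff; otherwise it is a solo capture paying 0.
  The resolved prey immediately respawns at a uniform-random position
  (constant prey density). This reconciles "hunting alone is possible"
  with the requirement that both hunters be present at the end of the
  count; a solo-maintained count also resolves (and respawns the prey),
  which keeps prey turnover simple — the alternative (solo contact never
  resolving) would let one robot permanently "pin" a prey.
* **First arriver**: per prey and robot we track the step at which the
  current unbroken contact streak began; the cooperative capture's first
  arriver is the robot whose streak started earlier, ties going to robot A.
  When a parked pair jostles (push-apart), both streaks often restart on
  the same step, so ties — and hence robot A — dominate the annotation for
  tightly parked pairs; the leadership index should be read with this in
  mind.

## Sensors and controller

Each robot carries 12 proximity rays (30° apart, starting at the heading,
range 40, activation $1 - d/40$ with $d$ measured from the body surface;
walls, prey and the other robot all register) and a camera: a 90° field of
view split into 12 equal 7.5° sectors with one ray at each sector centre.
A camera ray reports the nearest *agent* it intersects — hunter, boar or
stag; walls are invisible to the camera — as a two-bit type code (none 00,
hunter 01, boar 10, stag 11) plus a proximity $1 - d/D$ with $D$ the arena
diagonal. The camera has unlimited range and linear proximity because no
range or saturation is part of the model definition; the proximity sensors
carry the short-range information. The 49 controller inputs are the 12
proximity activations, the 12 camera rays as (bit, bit, proximity)
triples, and a constant bias of 1.

The controller is a fully connected perceptron with one hidden layer of 8
units and logistic-sigmoid activations (slope 1). The 410 connection
weights (49×8 input→hidden plus 9×2 (hidden + hidden-layer bias)→output)
are the genome, laid out input-major with the output block last; the
hidden-layer bias lives in the output stage because 410 = 49·8 + 9·2
leaves no room for per-hidden biases. Outputs are the wheel commands.

A genome may carry one or two networks. The duplication operator copies
the single network (probability 5×10⁻²/generation when enabled); deletion
removes a uniformly chosen copy (5×10⁻³). When two dual-network
individuals are paired, a fair coin decides which robot expresses copy 1
and the other expresses copy 2 — they never express the same copy index,
which is what allows the two loci to specialize into leader and follower
roles. A dual individual paired with a single-network partner expresses a
uniformly chosen copy (the model does not specify this case; the uniform
choice adds no bias).

## Evolution

A population of 20 genomes evolves. Each generation, every focal
individual is paired with `n_partners` distinct random partners for
`trials_per_pair` independent trials each (5 × 5 = 25 at full scale);
fitness is the mean of the focal's own cumulative reward — partners are
props in the focal's trials, avoiding double counting. Genes are
initialized uniformly in [0, 1] (a deliberately uncentred choice that is
part of the model definition; `initPopulation(init = "centered")` exists
for sensitivity checks). Mutation adds Gaussian noise of SD 0.2 to each
gene independently with probability 5×10⁻³; weights are not clipped.

Two selection schemes:

* **Elitist (10+10)**: the 10 best individuals (ties broken by lower
  index) survive unchanged; 10 mutants are generated, each from one
  uniformly chosen elite, by duplication/deletion then mutation. This
  scheme suppresses drift.
* **Wright–Fisher** (fitness-proportionate): each of 20 offspring draws
  its parent with probability proportional to fitness (uniformly when all
  fitnesses are 0), then passes through the same operators. At population
  size 20 this drifts strongly.

Elites are re-evaluated every generation (noisy social fitness, the
standard in evolutionary robotics); `evolutionConfig(eval_seed = )`
freezes the evaluation randomness for determinism experiments. Note that
because fitness is social, even frozen seeds make an elite's fitness
depend on who else is in the population; strict monotonicity of the best
fitness holds only with clonal offspring.

Reproducibility: one base seed per protocol; replicate $i$ runs on
`bitwXor(base_seed, i)`; every trial draws its own 32-bit seed from the
replicate stream and `runTrial()` restores the caller's RNG state, so any
trial can be replayed in isolation from a checkpoint
(`writeGenomes()`/`readGenomes()` serialize at 17 significant digits,
which round-trips doubles exactly).

## Study protocols and problem scales

`protocolPreset()` encodes the four designs: **simple** (1 boar + 1 stag),
**complex** (9 + 9), **complex-asym** (9 + 9 with duplication enabled) —
each as boar-hunter pre-evolution with the stag reward set to 0, followed
by evolution under the regular payoffs — and **wright-fisher** (single
phase, regular payoffs, meant to be seeded with a pre-evolved boar-hunting
genotype).

Full ("paper") scale is 20,000-step trials, 5 partners × 5 trials,
3000 + 6000 generations (12,000 for Wright–Fisher) and 30 replicates
(12 for Wright–Fisher) — of the order of 10¹¹ simulation steps per
condition, a cluster-scale computation. The "desk" scale keeps every model
constant (payoffs, mutation, capture rule, sensors, population size)
identical and shrinks only the budget so that one condition runs in
minutes on one core:

| condition | generations | steps/trial | partners × trials | replicates |
|---|---|---|---|---|
| simple | 300 + 500 | 4000 | 2 × 2 | 5 |
| complex, complex-asym | 100 + 150 | 2000 | 2 × 1 | 5 |
| wright-fisher | 2000 | 2000 | 1 × 1 | 5 |

The simple-condition scale is the reference desk configuration; the
complex conditions use shorter trials because 18 prey make encounters
roughly an order of magnitude more frequent, and the Wright–Fisher design
spends its budget on generations (drift needs time more than it needs
evaluation precision).

**Seeding at desk scale.** At full scale, pre-evolution bootstraps hunting
from random genomes. The desk budget cannot do that: uniform-[0,1]
genomes saturate the sigmoids towards full-forward driving, tens of
coordinated weight changes separate them from any controller that can hold
an 800-step contact, and the fitness landscape is exactly flat until the
first cooperative capture (we verified this directly: 800 desk generations
from random initialization produce zero cooperative captures). Desk
presets therefore seed every replicate clonally with the hand-wired
boar-hunter stub (`makeFixture("boar_hunter_stub")`; the dual
leader/follower stub for complex-asym, mirroring the asymmetric
pre-evolution outcome). The desk study then measures what the full-scale
design measures — whether stag hunting can invade an established
boar-hunting equilibrium — instead of the unaffordable bootstrap.

## The stub fixtures

`makeFixture("boar_hunter_stub")` is a hand-wired genome, not an evolved
one: three hidden units implement "boar left → turn left", "boar right →
turn right", and a park detector (front proximity ray saturated *and* the
central camera rays report a close boar) whose output weights exactly
cancel the roaming drive, so the robot brakes onto the boar and creeps
across it slowly enough to hold the 800-step contact. The follower variant
adds a weaker attraction towards the other hunter, so it tails the leader
and parks on the prey the leader chose; a clonal leader/follower pair
roughly doubles cooperative captures in the complex environment relative
to two independent boar hunters. Both stubs ignore stags by construction
(the type-bit score b1 − b2 is zero for a stag).

Because the stub's logic lives in weights of magnitude ≈ 8 (about 40 SDs
of the mutation kernel), its type preference is far more mutation-rigid
than a genotype at mutation–selection balance would be. This matters for
the invasion dynamics seeded from it, and is a known limitation: passing
desk-scale tests seeded with stubs demonstrates the machinery (operators,
selection, measurement) and the stability of the boar equilibrium, not the
full-scale transition rates.

## What the desk-scale results do and do not show

The package's own acceptance checks (in `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`) compute, at desk scale: the evolutionary-trap
outcome in the simple environment (best-individual stag proportion across
replicates after payoff reinstatement — the headline quantity), the
cross-condition transition ordering, operator calibrations
(mutated-gene count 410 × 0.005 = 2.05, delta SD 0.2, Wright–Fisher
proportionality, the 2P(1−P) closed form against Monte-Carlo), and the
drift design. Two caveats the desk scale imposes:

* Transitions to stag hunting are rare-event outcomes. Scaling the paper
  design's observed rates by generation count predicts only a ~9% chance
  of seeing ≥1 transition among 5 complex-asym desk replicates and ~34%
  for the drift design, so desk runs will usually show zero transitions
  even though the machinery is correct. Our drift runs do show the
  precursor: probing the final Wright–Fisher populations reveals
  replicates whose prey-approach behavior is heavily mixed towards stags
  (up to ~half of contact onsets) without yet converting into 800-step
  stag captures.
* The best individual's capture breakdown is measured from its own
  evaluation trials (no extra probe trials), so with 1 × 1 desk
  evaluation the per-replicate strategy readout rests on one trial's
  events and is correspondingly coarse.

## Numerical and implementation notes

The trial loop is compiled (Rcpp); every operation it performs — ray
casting, input encoding, the perceptron, actuation, push-apart, captures —
also exists as a plain-R reference implementation, and a property test
replays whole trials through both paths demanding bit-identical
trajectories, rewards and event logs. Keeping the two paths bit-equal
dictates a few choices: the perceptron accumulates in two fixed
even/odd-input chains (mirrored exactly in R, where `colSums()` could not
be used because it accumulates in extended precision), compiled angular
culls are conservative with an explicit margin so boundary rays always
fall through to the exact intersection test, and fused multiply-add
contraction is disabled. All randomness flows through R's RNG (also from
compiled code), so `set.seed()` governs everything and there is no global
state of our own.

Degenerate inputs are pinned by tests: `capture_steps = 1` resolves on the
first contact step; commands outside [0, 1] are clamped with a warning;
a camera ray grazing a disc tangentially uses the same discriminant test
in both paths; an empty event log yields an explicitly undefined strategy
profile (and `detectTransition()` refuses it rather than returning
`FALSE`).

The one-tailed Mann–Whitney U uses midranks, exact enumeration of all
labelings for combined n ≤ 12 (valid under ties), a tie-corrected normal
approximation with continuity correction beyond that, and returns p = 0.5
for the degenerate zero-variance case. `stats::wilcox.test` serves as an
independent cross-check in the tests, not as the implementation, because
it refuses exact p-values under ties.

## Worked example

```{r example}
stub <- makeFixture("boar_hunter_stub")
trial <- runTrial(stub, stub, worldConfig(trial_steps = 5000), payoffScheme(),
                  seed = 42)
trial
trial$events
huntProportions(trial)
```

```{r study, eval = FALSE}
# A desk-scale trap study (about 12 minutes on one core):
study <- runStudy(protocolPreset("simple", scale = "desk", base_seed = 1))
summarizeStudy(study)
```
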